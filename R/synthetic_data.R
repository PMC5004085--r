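# Synthetic alternating-bursting trace pairs, a phenomenological
# grid -> activity response for building labeled databases with known family
# structure, and the packaged census fixture tables.

#' Specify a synthetic burst pattern
#'
#' Parameters of a stereotyped alternating-bursting trace pair: cell B's
#' burst midpoints lag cell A's by `phase * period`.  Spikes are narrow
#' Gaussian waveforms riding on a depolarized burst plateau; they cross the
#' -20 mV detection threshold only when `spike_peak` exceeds it.
#'
#' @param period Burst period (s).
#' @param duty Duty cycle (% of period occupied by the burst).
#' @param spike_freq Within-burst spike frequency (Hz); 0 produces spikeless
#'   plateaus.
#' @param phase Phase lag of cell B relative to cell A, in [0, 1).
#' @param spike_peak Spike peak voltage (mV).
#' @param burst_base Plateau voltage during a burst (mV).
#' @param inter_base Interburst baseline voltage (mV).
#' @param noise_sd Additive Gaussian voltage noise, standard deviation (mV).
#' @param seed Integer seed for the noise generator (mandatory; the
#'   generator never touches global RNG state).
#' @param dt Sample interval (s).
#' @param duration Trace length (s).
#' @param spike_width Gaussian spike half-width parameter (s).
#' @return An object of class `hco_burst_spec`.
#' @examples
#' burst_spec(period = 10, duty = 60, spike_freq = 15, seed = 1)
#' @export
burst_spec <- function(period = 10, duty = 60, spike_freq = 15, phase = 0.5,
                       spike_peak = 0, burst_base = -45, inter_base = -60,
                       noise_sd = 0, seed, dt = 0.001, duration = 60,
                       spike_width = 0.004) {
  if (missing(seed)) abort("`seed` is required for burst_spec().")
  if (period <= 0) abort("`period` must be positive.")
  if (duty <= 0 || duty >= 100) abort("`duty` must be in (0, 100).")
  if (spike_freq < 0) abort("`spike_freq` must be non-negative.")
  if (phase < 0 || phase >= 1) abort("`phase` must be in [0, 1).")
  if (dt <= 0 || duration <= 0) abort("`dt` and `duration` must be positive.")
  structure(list(period = period, duty = duty, spike_freq = spike_freq,
                 phase = phase, spike_peak = spike_peak,
                 burst_base = burst_base, inter_base = inter_base,
                 noise_sd = noise_sd, seed = as.integer(seed), dt = dt,
                 duration = duration, spike_width = spike_width),
            class = "hco_burst_spec")
}

# Spike times of one cell: burst centers at offset + k*period, spikes evenly
# spaced across the burst so the span equals the nominal burst duration and
# the middle spike sits at the burst center.
synth_cell_events <- function(spec, offset) {
  burst_dur <- spec$duty / 100 * spec$period
  centers <- if (offset > spec$duration) numeric(0)
  else seq(offset, spec$duration, by = spec$period)
  centers <- centers[centers - burst_dur / 2 >= spec$dt &
                       centers + burst_dur / 2 <= spec$duration - spec$dt]
  n_spikes <- round(spec$spike_freq * burst_dur)
  if (spec$spike_freq > 0) {
    if (n_spikes < 3 || burst_dur < 3 * spec$spike_width) {
      abort("Burst too short to honor at least three spikes per burst.")
    }
  }
  spike_times <- if (n_spikes > 0) {
    as.vector(vapply(centers, function(c0) {
      seq(c0 - burst_dur / 2, c0 + burst_dur / 2, length.out = n_spikes)
    }, numeric(n_spikes)))
  } else numeric(0)
  list(centers = centers, burst_dur = burst_dur,
       spike_times = sort(spike_times))
}

synth_cell_voltage <- function(spec, events, times) {
  v <- rep(spec$inter_base, length(times))
  half <- events$burst_dur / 2
  for (c0 in events$centers) {
    i <- which(times >= c0 - half & times <= c0 + half)
    v[i] <- spec$burst_base
  }
  w <- spec$spike_width
  amp <- spec$spike_peak - spec$burst_base
  for (ts in events$spike_times) {
    i0 <- max(1L, ceiling((ts - 6 * w) / spec$dt) + 1L)
    i1 <- min(length(times), floor((ts + 6 * w) / spec$dt) + 1L)
    i <- i0:i1
    v[i] <- v[i] + amp * exp(-((times[i] - ts)^2) / (2 * w^2))
  }
  v
}

#' Synthesize an alternating-bursting trace pair
#'
#' Deterministic given the seed.  The number of spikes per burst is
#' `round(spike_freq x burst duration)`, spikes are evenly spaced so the
#' spike span equals the nominal burst duration, and only bursts lying fully
#' inside the trace are emitted.  Errors if the burst is too short to hold
#' three spikes (unless `spike_freq` is zero).
#'
#' @param spec A [burst_spec()].
#' @return A tibble of class `hco_trace_pair` with columns `time`, `v_a`,
#'   `v_b`; ground-truth spike times are attached as attributes
#'   `spikes_a` and `spikes_b`.
#' @examples
#' tr <- synthesize_trace_pair(burst_spec(seed = 42, duration = 30))
#' trace_pair_characteristics(tr)
#' @export
synthesize_trace_pair <- function(spec) {
  stopifnot(inherits(spec, "hco_burst_spec"))
  times <- seq(0, spec$duration, by = spec$dt)
  ev_a <- synth_cell_events(spec, offset = spec$period / 2)
  ev_b <- synth_cell_events(spec, offset = spec$period / 2 +
                              spec$phase * spec$period)
  v_a <- synth_cell_voltage(spec, ev_a, times)
  v_b <- synth_cell_voltage(spec, ev_b, times)
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed, stats::rnorm(2 * length(times),
                                                      sd = spec$noise_sd))
    v_a <- v_a + noise[seq_along(times)]
    v_b <- v_b + noise[length(times) + seq_along(times)]
  }
  out <- tibble(time = times, v_a = v_a, v_b = v_b)
  attr(out, "spikes_a") <- ev_a$spike_times
  attr(out, "spikes_b") <- ev_b$spike_times
  class(out) <- c("hco_trace_pair", class(out))
  out
}

# ---- phenomenological grid response ----------------------------------------

#' Phenomenological grid-to-activity response model
#'
#' A rule set mapping a grid point to an activity label and burst
#' characteristics, used to build labeled synthetic databases with known
#' family structure.  The linear coefficients encode the monotone parameter
#' dependencies of the bursting branch: period falls with `x_h`, `x_K2` and
#' `x_Leak` and rises with `x_CaS`, `x_P` and `x_SynS`; spike frequency
#' rises with `x_h`, `x_CaS` and `x_P` and falls with `x_K2`, `x_Leak` and
#' `x_SynS`; the graded synapse has negligible effect.
#'
#' @param period0,freq0,duty0 Characteristics at the canonical point (all
#'   fractions 1, `e_leak` -60 mV): 10 s, 15 Hz, 60%.
#' @param period_coef,freq_coef Named coefficient vectors (per unit
#'   fraction, relative scale).
#' @param noise_sd Optional Gaussian jitter (relative, applied to period and
#'   frequency by [make_synthetic_db()]); default 0.
#' @return An object of class `hco_response_model`.
#' @export
response_model <- function(period0 = 10, freq0 = 15, duty0 = 60,
                           period_coef = c(x_CaS = 0.30, x_P = 0.50,
                                           x_SynS = 0.25, x_h = -0.35,
                                           x_K2 = -0.20, x_Leak = -0.15,
                                           e_leak = -0.01),
                           freq_coef = c(x_CaS = 0.30, x_P = 0.40,
                                         x_h = 0.15, x_K2 = -0.10,
                                         x_Leak = -0.15, x_SynS = -0.05),
                           noise_sd = 0) {
  structure(list(period0 = period0, freq0 = freq0, duty0 = duty0,
                 period_coef = period_coef, freq_coef = freq_coef,
                 noise_sd = noise_sd),
            class = "hco_response_model")
}

response_linear <- function(points, base, coef) {
  dev <- rep(0, nrow(points))
  for (p in names(coef)) {
    centered <- if (p == "e_leak") points[[p]] + 60 else points[[p]] - 1
    dev <- dev + coef[[p]] * centered
  }
  base * (1 + dev)
}

#' Evaluate the phenomenological response on grid points
#'
#' Applies the rule set in order: (1) `x_P < 0.25` is silent; (2) with both
#' synapses absent, a burster when `x_CaS >= 0.5` and `x_h >= 0.25`, else
#' spiking; (3) `x_K2 = 0` is plateau; (4) both synapses below 0.5 is
#' spiking; (5) `x_CaS < 0.75` is asymmetric; (6) otherwise bursting, with
#' period/frequency/duty from the linear response (period clipped to
#' [1, 40] s, duty to [20, 90]%, phase 0.5) and the realistic/functional
#' split applied by the physiological ranges.  Bursters get characteristics
#' from the same linear response and become realistic bursters when period
#' and frequency are in range.
#'
#' @param points Tibble of grid points.
#' @param model A [response_model()].
#' @return Tibble of instance records: the points plus `label`, `period_s`,
#'   `spike_freq_hz`, `duty_pct`, `phase`, `cv_period`, `cv_amp`,
#'   `fail_flags`.
#' @examples
#' canonical <- tibble::tibble(x_P = 1, x_K2 = 1, x_Leak = 1, x_CaS = 1,
#'                             x_h = 1, x_SynS = 1, x_SynG = 1, e_leak = -60)
#' grid_response(canonical, response_model())
#' @export
grid_response <- function(points, model = response_model()) {
  check_point_columns(points)
  n <- nrow(points)
  period <- pmin(pmax(response_linear(points, model$period0,
                                      model$period_coef), 1), 40)
  freq <- response_linear(points, model$freq0, model$freq_coef)
  duty <- pmin(pmax(model$duty0 - 10 * (points$x_SynS - 1) +
                      5 * (points$x_h - 1), 20), 90)

  synfree <- points$x_SynS == 0 & points$x_SynG == 0
  label <- rep(NA_character_, n)
  label[points$x_P < 0.25] <- "silent"
  todo <- is.na(label)
  label[todo & synfree &
          !(points$x_CaS >= 0.5 & points$x_h >= 0.25)] <- "spiking"
  label[todo & synfree & points$x_CaS >= 0.5 & points$x_h >= 0.25] <- "burster"
  todo <- is.na(label)
  label[todo & points$x_K2 == 0] <- "plateau"
  todo <- is.na(label)
  label[todo & points$x_SynS < 0.5 & points$x_SynG < 0.5] <- "spiking"
  todo <- is.na(label)
  label[todo & points$x_CaS < 0.75] <- "asymmetric"
  todo <- is.na(label)

  realistic <- period >= 5 & period <= 15 & freq >= 8 & freq <= 25 &
    duty >= 50 & duty <= 70
  label[todo & realistic] <- "rHCO"
  label[todo & !realistic] <- "fHCO"
  real_burst <- label == "burster" & period >= 5 & period <= 15 &
    freq >= 8 & freq <= 25
  label[real_burst] <- "realistic_burster"

  bursting <- label %in% c("rHCO", "fHCO", "burster", "realistic_burster")
  out <- as_tibble(points)
  out$label <- label
  out$period_s <- ifelse(bursting, period, NA_real_)
  out$spike_freq_hz <- ifelse(bursting, freq, NA_real_)
  out$duty_pct <- ifelse(bursting, duty, NA_real_)
  out$phase <- ifelse(label %in% c("rHCO", "fHCO"), 0.5, NA_real_)
  out$cv_period <- ifelse(bursting, 0.02, NA_real_)
  out$cv_amp <- ifelse(bursting, 0.03, NA_real_)
  flags <- rep(NA_character_, n)
  fh <- label == "fHCO"
  if (any(fh)) {
    flags[fh] <- realistic_flags(period[fh], freq[fh], duty[fh])$mask
  }
  flags[label == "rHCO"] <- "---"
  out$fail_flags <- flags
  out
}

#' Build a synthetic instance database
#'
#' One instance record per grid point, labeled by the phenomenological
#' response.  Deterministic given the seed; when the model carries a nonzero
#' `noise_sd`, multiplicative Gaussian jitter is applied to period and
#' frequency before classification thresholds are re-applied.
#'
#' @param spec A [grid_spec()] (use a small toy grid at desk scale).
#' @param model A [response_model()].
#' @param seed Integer seed (mandatory).
#' @return Tibble of instance records, one row per grid point.
#' @examples
#' db <- make_synthetic_db(grid_spec(fractions = c(0, 0.75, 1.5),
#'                                   e_leak_levels = c(-65, -55)),
#'                         seed = 7)
#' dplyr::count(db, label)
#' @export
make_synthetic_db <- function(spec, model = response_model(), seed) {
  if (missing(seed)) abort("`seed` is required for make_synthetic_db().")
  points <- enumerate_grid(spec)
  if (model$noise_sd > 0) {
    jitter <- withr::with_seed(as.integer(seed), {
      list(p = stats::rnorm(nrow(points), 1, model$noise_sd),
           f = stats::rnorm(nrow(points), 1, model$noise_sd))
    })
    out <- grid_response(points, model)
    bursting <- !is.na(out$period_s)
    out$period_s[bursting] <- out$period_s[bursting] * jitter$p[bursting]
    out$spike_freq_hz[bursting] <- out$spike_freq_hz[bursting] *
      jitter$f[bursting]
    hco <- out$label %in% c("rHCO", "fHCO")
    realistic <- hco & out$period_s >= 5 & out$period_s <= 15 &
      out$spike_freq_hz >= 8 & out$spike_freq_hz <= 25 &
      out$duty_pct >= 50 & out$duty_pct <= 70
    out$label[hco] <- ifelse(realistic[hco], "rHCO", "fHCO")
    fh <- out$label == "fHCO"
    out$fail_flags[fh] <- realistic_flags(out$period_s[fh],
                                          out$spike_freq_hz[fh],
                                          out$duty_pct[fh])$mask
    out$fail_flags[out$label == "rHCO"] <- "---"
    out
  } else {
    grid_response(points, model)
  }
}

# ---- packaged census fixture tables ----------------------------------------

#' Load the packaged family-census fixture tables
#'
#' Three fixed tabulations of the full-database realistic-HCO census, shipped
#' as tab-separated package data with an md5 checksum file: family counts by
#' defining parameter and size (with the noninterrupted split), counts of
#' missing h-family members with functional bursting by failed physiological
#' criterion, and counts of h-family period-sensitivity classes by family
#' size.
#'
#' @return A list of tibbles `table1` (`param`, `size`, `total`,
#'   `noninterrupted`), `table2` (`size`, `category`, `count`) and `table3`
#'   (`size`, `class`, `count`).
#' @examples
#' fx <- load_fixture_tables()
#' dplyr::filter(fx$table1, param == "h", size == 8)
#' @export
load_fixture_tables <- function() {
  dir <- system.file("extdata", package = "hcofam", mustWork = TRUE)
  files <- c(table1 = "census_family_sizes.tsv",
             table2 = "census_missing_fhco.tsv",
             table3 = "census_sensitivity.tsv")
  sums <- readr::read_tsv(file.path(dir, "census_checksums.tsv"),
                          col_types = "cc", progress = FALSE)
  out <- imap(files, function(f, nm) {
    path <- file.path(dir, f)
    expected <- sums$md5[sums$file == f]
    actual <- unname(tools::md5sum(path))
    if (!length(expected) || expected != actual) {
      abort(paste0("Checksum mismatch for fixture ", f))
    }
    readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  })
  out$table1$noninterrupted <- as.integer(out$table1$noninterrupted)
  out
}
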