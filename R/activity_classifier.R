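# Activity labels and realistic-criteria failure flags.

.realistic_ranges <- list(period = c(5, 15), freq = c(8, 25), duty = c(50, 70))

in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]

#' Realistic-criteria failure flags
#'
#' Range checks of the three physiological criteria that separate realistic
#' from merely functional HCO bursting: period 5-15 s, average spike
#' frequency 8-25 Hz, duty cycle 50-70% (all closed intervals).  The
#' category names the nonempty subset of failed criteria; an instance
#' failing none has no category (it is realistic) and mask `"---"`.
#'
#' @param period_s,spike_freq_hz,duty_pct Numeric vectors of burst
#'   characteristics (must be defined; this is an HCO-class check).
#' @return Tibble with logical columns `fail_period`, `fail_freq`,
#'   `fail_duty`, a `category` string (e.g. `"duty_cycle"`,
#'   `"spike_frequency_duty_cycle"`, `NA` when nothing fails) and a
#'   three-character `mask` (positions period/frequency/duty, e.g. `"P-D"`).
#' @examples
#' realistic_flags(4, 10, 60)
#' realistic_flags(10, 30, 40)
#' @export
realistic_flags <- function(period_s, spike_freq_hz, duty_pct) {
  if (any(is.na(period_s) | is.na(spike_freq_hz) | is.na(duty_pct))) {
    abort("realistic_flags() needs defined characteristics (HCO-class instances).")
  }
  fp <- !in_range(period_s, .realistic_ranges$period)
  ff <- !in_range(spike_freq_hz, .realistic_ranges$freq)
  fd <- !in_range(duty_pct, .realistic_ranges$duty)
  parts <- pmap(list(fp, ff, fd), function(p, f, d) {
    c("period", "spike_frequency", "duty_cycle")[c(p, f, d)]
  })
  category <- map_chr(parts, function(x) {
    if (length(x) == 0) NA_character_ else paste(x, collapse = "_")
  })
  mask <- paste0(ifelse(fp, "P", "-"), ifelse(ff, "F", "-"),
                 ifelse(fd, "D", "-"))
  tibble(fail_period = fp, fail_freq = ff, fail_duty = fd,
         category = category, mask = mask)
}

#' Failure category from a stored fail-flags mask
#' @noRd
mask_to_category <- function(mask) {
  map_chr(mask, function(m) {
    if (is.na(m)) return(NA_character_)
    parts <- c(if (substr(m, 1, 1) == "P") "period",
               if (substr(m, 2, 2) == "F") "spike_frequency",
               if (substr(m, 3, 3) == "D") "duty_cycle")
    if (length(parts) == 0) NA_character_ else paste(parts, collapse = "_")
  })
}

burst_qualified <- function(cell, cv_amp_max = 0.07, cv_period_max = 0.05) {
  !is.na(cell$n_bursts_40) & cell$n_bursts_40 >= 2 &
    !is.na(cell$cv_amp) & cell$cv_amp < cv_amp_max &
    !is.na(cell$cv_period) & cell$cv_period < cv_period_max
}

#' Classify an instance from per-cell summaries
#'
#' Assigns the activity label from the two cells' burst summaries, the joint
#' phase and the synaptic fractions of the grid point.  An HCO requires both
#' cells to have at least two complete bursts in the evaluation window,
#' spike-amplitude CV below 0.07 in every burst, period CV below 0.05, phase
#' in [0.45, 0.55], and at least one synapse present; it is realistic
#' (`rHCO`) when period, spike frequency and duty cycle are all inside the
#' physiological ranges, otherwise functional (`fHCO`).  With both synapses
#' absent the same regularity criteria define `burster` /
#' `realistic_burster` (duty cycle is not required for bursters).  `silent`
#' means no spikes in either cell; `plateau` a sustained supra-threshold
#' depolarization of at least 1 s without three spikes; `spiking` spikes
#' without qualifying bursts; `asymmetric` cells that differ or alternate
#' without meeting the phase/CV criteria.
#'
#' @param cell_a,cell_b One-row tibbles (or lists) with fields `n_spikes`,
#'   `n_bursts_40` (complete bursts whose middle spike lies in the
#'   evaluation window), `cv_amp`, `cv_period`, `period_s`,
#'   `spike_freq_hz`, `duty_pct`, `plateau` (logical).
#' @param phase Joint phase (may be `NA`).
#' @param x_syns,x_syng Synaptic scale fractions of the grid point.
#' @return A single activity label string.
#' @export
classify_instance <- function(cell_a, cell_b, phase, x_syns, x_syng) {
  syn_present <- x_syns != 0 | x_syng != 0
  qa <- burst_qualified(cell_a)
  qb <- burst_qualified(cell_b)

  if (cell_a$n_spikes == 0 && cell_b$n_spikes == 0) {
    if (isTRUE(cell_a$plateau) || isTRUE(cell_b$plateau)) return("plateau")
    return("silent")
  }

  period <- mean(c(cell_a$period_s, cell_b$period_s))
  freq <- mean(c(cell_a$spike_freq_hz, cell_b$spike_freq_hz))
  duty <- mean(c(cell_a$duty_pct, cell_b$duty_pct))

  if (!syn_present) {
    if (qa && qb) {
      ok <- in_range(period, .realistic_ranges$period) &&
        in_range(freq, .realistic_ranges$freq)
      return(if (ok) "realistic_burster" else "burster")
    }
  } else if (qa && qb) {
    if (!is.na(phase) && phase >= 0.45 && phase <= 0.55) {
      ok <- in_range(period, .realistic_ranges$period) &&
        in_range(freq, .realistic_ranges$freq) &&
        in_range(duty, .realistic_ranges$duty)
      return(if (ok) "rHCO" else "fHCO")
    }
    return("asymmetric")
  }

  if (xor(qa, qb)) return("asymmetric")
  if ((isTRUE(cell_a$plateau) && !qa) || (isTRUE(cell_b$plateau) && !qb)) {
    return("plateau")
  }
  if ((cell_a$n_spikes > 0 && cell_b$n_spikes == 0) ||
      (cell_b$n_spikes > 0 && cell_a$n_spikes == 0)) {
    return("asymmetric")
  }
  if (cell_a$n_spikes > 0 && cell_b$n_spikes > 0) return("spiking")
  "other"
}

plateau_present <- function(time, v, threshold = -20, min_dur = 1,
                            n_spikes = 0) {
  if (n_spikes >= 3) return(FALSE)
  above <- v > threshold
  if (!any(above)) return(FALSE)
  r <- rle(above)
  dt <- mean(diff(time))
  any(r$values & r$lengths * dt >= min_dur)
}

cell_summary <- function(time, v, window_40, threshold = -20) {
  spikes <- detect_spikes(time, v, threshold)
  train <- segment_bursts(spikes, window = range(time))
  ch <- cell_characteristics(train)
  n40 <- if (nrow(train)) sum(train$mid >= window_40[1] &
                                train$mid <= window_40[2]) else 0L
  tibble(n_spikes = nrow(spikes), n_bursts_40 = n40,
         cv_amp = ch$cv_amp, cv_period = ch$cv_period,
         period_s = ch$period_s, spike_freq_hz = ch$spike_freq_hz,
         duty_pct = ch$duty_pct,
         plateau = plateau_present(time, v, threshold,
                                   n_spikes = nrow(spikes)),
         train = list(train))
}

#' Classify a voltage trace pair
#'
#' Runs the full per-cell pipeline (spike detection at -20 mV, burst
#' segmentation, characteristics) and applies [classify_instance()].  The
#' "two bursts in a 40 s interval" criterion is evaluated over the final
#' 40 s of the recording (or the whole trace when shorter).
#'
#' @param pair A trace pair tibble (`time`, `v_a`, `v_b`).
#' @param point One-row tibble with at least `x_SynS` and `x_SynG`.
#' @return One-row tibble: `label`, instance-level `period_s`,
#'   `spike_freq_hz`, `duty_pct`, `phase`, `cv_period`, `cv_amp` and
#'   `fail_flags` (mask for HCO-class labels, `NA` otherwise).
#' @examples
#' tr <- synthesize_trace_pair(burst_spec(seed = 1, duration = 60))
#' classify_trace_pair(tr, tibble::tibble(x_SynS = 1, x_SynG = 1))
#' @export
classify_trace_pair <- function(pair, point) {
  t1 <- max(pair$time)
  window_40 <- c(max(min(pair$time), t1 - 40), t1)
  a <- cell_summary(pair$time, pair$v_a, window_40)
  b <- cell_summary(pair$time, pair$v_b, window_40)
  phase <- phase_between(a$train[[1]], b$train[[1]])
  label <- classify_instance(a, b, phase, point$x_SynS, point$x_SynG)
  hco_class <- label %in% c("rHCO", "fHCO")
  period <- mean(c(a$period_s, b$period_s))
  freq <- mean(c(a$spike_freq_hz, b$spike_freq_hz))
  duty <- mean(c(a$duty_pct, b$duty_pct))
  flags <- if (hco_class) realistic_flags(period, freq, duty)$mask
  else NA_character_
  tibble(label = label, period_s = period, spike_freq_hz = freq,
         duty_pct = duty, phase = phase,
         cv_period = max(a$cv_period, b$cv_period),
         cv_amp = max(a$cv_amp, b$cv_amp), fail_flags = flags)
}
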