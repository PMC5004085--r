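# Spike detection, burst segmentation and burst-characteristic formulas.

#' Detect spikes in a voltage trace
#'
#' A spike is one contiguous excursion of the membrane potential above the
#' threshold; its time is the local maximum of the excursion and its
#' amplitude the peak voltage.  The trace must be uniformly sampled.
#'
#' @param time Numeric vector of sample times (s), uniformly spaced.
#' @param v Numeric vector of membrane potential (mV), same length.
#' @param threshold Spike threshold (mV); default -20.
#' @return Tibble with columns `time` (s) and `amplitude` (mV), one row per
#'   spike, ordered in time.
#' @examples
#' tr <- synthesize_trace_pair(burst_spec(seed = 1, duration = 30))
#' detect_spikes(tr$time, tr$v_a)
#' @export
detect_spikes <- function(time, v, threshold = -20) {
  if (length(time) != length(v)) abort("`time` and `v` lengths differ.")
  if (length(time) < 2) return(tibble(time = double(), amplitude = double()))
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * stats::median(dt)) {
    abort("Trace must be uniformly sampled with strictly increasing times.")
  }
  above <- v > threshold
  if (!any(above)) return(tibble(time = double(), amplitude = double()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  idx <- map_int(keep, function(k) {
    i <- starts[k]:ends[k]
    i[which.max(v[i])]
  })
  tibble(time = time[idx], amplitude = v[idx])
}

#' Segment spike trains into bursts
#'
#' Bursts are maximal runs of spikes whose inter-spike gaps are strictly less
#' than `min_gap`; a gap of exactly `min_gap` terminates a burst.  Runs with
#' fewer than `min_spikes` spikes are discarded, as are runs that touch the
#' recording edges (within `min_gap` of a window boundary) and may therefore
#' be truncated.
#'
#' @param spikes Tibble from [detect_spikes()] (columns `time`, `amplitude`),
#'   or a numeric vector of sorted spike times.
#' @param min_spikes Minimum spikes per burst (default 3).
#' @param min_gap Minimum interburst interval in seconds (default 1).
#' @param window Optional recording window `c(t0, t1)`; when supplied, bursts
#'   whose first or last spike lies within `min_gap` of a boundary are
#'   dropped as incomplete.
#' @return A burst-train tibble with one row per burst: `burst`, `start`,
#'   `end`, `mid` (middle-spike time, lower median for even counts),
#'   `duration` (s), `n_spikes`, and list-columns `spike_times`,
#'   `amplitudes`.
#' @examples
#' segment_bursts(c(0, 0.1, 0.2, 3.0, 3.1, 3.2))
#' @export
segment_bursts <- function(spikes, min_spikes = 3, min_gap = 1,
                           window = NULL) {
  if (is.numeric(spikes)) spikes <- tibble(time = spikes, amplitude = NA_real_)
  times <- spikes$time
  if (is.unsorted(times)) abort("Spike times must be sorted.")
  empty <- tibble(burst = integer(), start = double(), end = double(),
                  mid = double(), duration = double(), n_spikes = integer(),
                  spike_times = list(), amplitudes = list())
  if (length(times) == 0) return(empty)
  grp <- cumsum(c(1, as.integer(diff(times) >= min_gap)))
  runs <- tibble(time = times, amplitude = spikes$amplitude, grp = grp) |>
    group_by(.data$grp) |>
    summarise(start = min(.data$time), end = max(.data$time),
              n_spikes = n(),
              mid = .data$time[[floor((n() - 1) / 2) + 1]],
              spike_times = list(.data$time),
              amplitudes = list(.data$amplitude),
              .groups = "drop")
  runs <- filter(runs, .data$n_spikes >= min_spikes)
  if (!is.null(window)) {
    runs <- filter(runs,
                   .data$start - window[1] >= min_gap,
                   window[2] - .data$end >= min_gap)
  }
  runs |>
    mutate(duration = .data$end - .data$start,
           burst = seq_len(n())) |>
    select("burst", "start", "end", "mid", "duration", "n_spikes",
           "spike_times", "amplitudes")
}

cell_characteristics <- function(train, threshold = -20) {
  if (nrow(train) == 0) {
    return(tibble(n_bursts = 0L, period_s = NA_real_, cv_period = NA_real_,
                  duty_pct = NA_real_, spike_freq_hz = NA_real_,
                  spike_freq_printed = NA_real_, cv_amp = NA_real_,
                  period_defined = FALSE))
  }
  periods <- diff(train$mid)
  period <- if (length(periods)) mean(periods) else NA_real_
  cv_period <- if (length(periods) >= 2) {
    stats::sd(periods) / mean(periods)
  } else if (length(periods) == 1) 0 else NA_real_
  mean_dur <- mean(train$duration)
  burst_freqs <- train$n_spikes / train$duration
  # Spike-amplitude CV per burst, with amplitude measured as the spike
  # height above the detection threshold so the scale is well defined even
  # when peaks straddle 0 mV.
  cv_amp <- max(map_dbl(train$amplitudes, function(a) {
    a <- a[!is.na(a)] - threshold
    if (length(a) < 2) return(0)
    stats::sd(a) / abs(mean(a))
  }))
  tibble(
    n_bursts = nrow(train),
    period_s = period,
    cv_period = cv_period,
    duty_pct = if (!is.na(period)) 100 * mean_dur / period else NA_real_,
    # Normative neuron-level spike frequency: mean spikes per burst over mean
    # burst duration.  The printed variant (mean of per-burst frequencies over
    # mean duration) is dimensionally odd but kept for comparison.
    spike_freq_hz = mean(train$n_spikes) / mean_dur,
    spike_freq_printed = mean(burst_freqs) / mean_dur,
    cv_amp = cv_amp,
    period_defined = length(periods) >= 1
  )
}

phase_between <- function(train_a, train_b) {
  if (nrow(train_a) < 2 || nrow(train_b) < 1) return(NA_real_)
  mids_a <- train_a$mid
  vals <- map_dbl(train_b$mid, function(mb) {
    prec <- max(which(mids_a <= mb), -Inf)
    if (!is.finite(prec) || prec >= length(mids_a)) return(NA_real_)
    (mb - mids_a[prec]) / (mids_a[prec + 1] - mids_a[prec])
  })
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) NA_real_ else mean(vals)
}

#' Burst characteristics of one or two cells
#'
#' Computes the per-cell characteristics and, when two burst trains are
#' given, the joint phase.  Period is the mean interval between middle
#' spikes of consecutive bursts; duty cycle is 100 x mean burst duration /
#' mean period; neuron spike frequency is mean spikes-per-burst over mean
#' burst duration; `cv_period` is sd/mean of the per-cycle periods and
#' `cv_amp` the maximum over bursts of the within-burst spike-amplitude CV,
#' with amplitude measured as spike height above the -20 mV detection
#' threshold (so the ratio stays well defined when peaks sit near 0 mV).  Phase per B burst is the delay of its middle spike from the
#' preceding A middle spike, normalized by the enclosing A cycle, averaged
#' over bursts.
#'
#' Fewer than two bursts leaves the period undefined (`period_defined` is
#' `FALSE`), not an error.
#'
#' @param train_a Burst train of cell A ([segment_bursts()] output).
#' @param train_b Optional burst train of cell B.
#' @return Tibble with one row per cell (`cell` = "A", "B") and a `phase`
#'   column (identical on both rows; `NA` for a single cell).
#' @examples
#' a <- segment_bursts(c(1, 1.1, 1.2, 9, 9.1, 9.2, 17, 17.1, 17.2))
#' burst_characteristics(a)
#' @export
burst_characteristics <- function(train_a, train_b = NULL) {
  rows <- cell_characteristics(train_a) |> mutate(cell = "A")
  ph <- NA_real_
  if (!is.null(train_b)) {
    rows <- bind_rows(rows, cell_characteristics(train_b) |>
                        mutate(cell = "B"))
    ph <- phase_between(train_a, train_b)
  }
  rows |> mutate(phase = ph) |> relocate("cell")
}

#' Per-instance characteristics of a trace pair
#'
#' Runs spike detection, burst segmentation and [burst_characteristics()] on
#' a two-cell trace pair and collapses the result to one instance-level row:
#' period, spike frequency and duty cycle are averaged over the two cells;
#' the coefficients of variation take the worse (larger) cell.
#'
#' @param pair A trace pair: tibble with columns `time`, `v_a`, `v_b`
#'   (from [synthesize_trace_pair()] or [simulate_pair()]).
#' @param threshold Spike threshold (mV).
#' @param min_spikes,min_gap Burst segmentation parameters.
#' @return One-row tibble: `period_s`, `spike_freq_hz`, `duty_pct`, `phase`,
#'   `cv_period`, `cv_amp`, `n_bursts_a`, `n_bursts_b`, `n_spikes_a`,
#'   `n_spikes_b`, `period_defined`.
#' @export
trace_pair_characteristics <- function(pair, threshold = -20, min_spikes = 3,
                                       min_gap = 1) {
  window <- range(pair$time)
  sp_a <- detect_spikes(pair$time, pair$v_a, threshold)
  sp_b <- detect_spikes(pair$time, pair$v_b, threshold)
  tr_a <- segment_bursts(sp_a, min_spikes, min_gap, window)
  tr_b <- segment_bursts(sp_b, min_spikes, min_gap, window)
  ch <- burst_characteristics(tr_a, tr_b)
  tibble(
    period_s = mean(ch$period_s),
    spike_freq_hz = mean(ch$spike_freq_hz),
    duty_pct = mean(ch$duty_pct),
    phase = ch$phase[1],
    cv_period = max(ch$cv_period),
    cv_amp = max(ch$cv_amp),
    n_bursts_a = ch$n_bursts[1],
    n_bursts_b = ch$n_bursts[2],
    n_spikes_a = nrow(sp_a),
    n_spikes_b = nrow(sp_b),
    period_defined = all(ch$period_defined)
  )
}
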