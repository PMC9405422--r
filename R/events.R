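## first derivative in mV/ms of a (optionally low-pass smoothed) trace
smoothed_derivative <- function(tr, smooth_hz = NULL) {
  x <- if (!is.null(smooth_hz) && smooth_hz < tr$rate / 2)
    lowpass(tr, smooth_hz)$samples else tr$samples
  d <- c(0, diff(x)) * tr$rate / 1000
  list(x = x, d = d)
}

empty_events <- function() {
  data.frame(onset_s = numeric(), peak_time_s = numeric(),
             amplitude_mv = numeric(), half_duration_ms = numeric(),
             onset_to_peak_ms = numeric(), kind = character(),
             channel_role = character(), flagged = logical(),
             stringsAsFactors = FALSE)
}

## contiguous runs of a logical vector as (start, end) index pairs
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Event onset by backward derivative-threshold scan
#'
#' The onset is the latest time before the peak at which the first
#' derivative crosses the threshold upward (in the direction of the
#' event). Conventional thresholds: 10 mV/ms for action potentials,
#' 0.1 mV/ms for postsynaptic potentials. If no crossing is found within
#' `search_back_s` the onset falls back to `peak - search_back_s` and is
#' flagged.
#'
#' @param tr A [trace()].
#' @param peak_time Peak time in seconds (within the trace).
#' @param derivative_threshold Threshold in mV/ms.
#' @param smooth_hz Optional low-pass cutoff applied before
#'   differentiation.
#' @param search_back_s Backward search horizon (default 0.1 s).
#' @return A list with `onset` (s) and `flagged`.
#' @export
event_onset <- function(tr, peak_time, derivative_threshold,
                        smooth_hz = NULL, search_back_s = 0.1) {
  stopifnot(is_trace(tr))
  if (peak_time < tr$t0 ||
      peak_time > tr$t0 + (length(tr$samples) - 1) / tr$rate)
    stop("peak_time outside trace")
  ip <- time_to_index(tr, peak_time)
  sd_ <- smoothed_derivative(tr, smooth_hz)
  i0 <- max(2L, ip - round(search_back_s * tr$rate))
  # event direction: sign of the deflection from the search-window start
  dir <- sign(sd_$x[ip] - sd_$x[i0])
  if (dir == 0) dir <- 1
  d <- sd_$d * dir
  seg <- i0:ip
  below <- d[seg] < derivative_threshold
  above <- d[seg] >= derivative_threshold
  # latest upward crossing: last index where above follows below
  cross <- which(above[-1] & below[-length(below)])
  if (!length(cross)) {
    if (all(above)) return(list(onset = index_to_time(tr, i0), flagged = FALSE))
    return(list(onset = peak_time - search_back_s, flagged = TRUE))
  }
  list(onset = index_to_time(tr, seg[cross[length(cross)] + 1L]),
       flagged = FALSE)
}

#' Measure an event's amplitude and kinetics
#'
#' Amplitude is the extremum value minus the mean membrane potential in
#' the interval 1--5 ms before onset; half-duration is the width at
#' half-amplitude with linearly interpolated crossings; onset-to-peak is
#' the peak-minus-onset interval. If the baseline window falls outside
#' the trace it is truncated and the event flagged.
#'
#' @param tr A [trace()].
#' @param onset Onset time, s.
#' @param peak_time Peak time, s (`> onset`).
#' @param kind Event label (`"AP"` or `"PSP"`).
#' @return One-row data frame (`onset_s`, `peak_time_s`, `amplitude_mv`,
#'   `half_duration_ms`, `onset_to_peak_ms`, `kind`, `channel_role`,
#'   `flagged`).
#' @export
measure_event <- function(tr, onset, peak_time, kind = "PSP") {
  stopifnot(is_trace(tr))
  if (!(onset < peak_time)) stop("onset must precede peak_time")
  ip <- time_to_index(tr, peak_time)
  b0 <- time_to_index(tr, onset - 5e-3)
  b1 <- time_to_index(tr, onset - 1e-3)
  flagged <- (onset - 5e-3) < tr$t0
  if (b1 <= b0) { b0 <- max(1L, b0); b1 <- max(b0 + 1L, b1); flagged <- TRUE }
  baseline <- mean(tr$samples[b0:b1])
  amp <- tr$samples[ip] - baseline
  half <- baseline + amp / 2
  v <- tr$samples
  # left half-crossing (interpolated), searching back from the peak
  i <- ip
  while (i > 1L && (v[i] - half) * sign(amp) > 0) i <- i - 1L
  t_left <- if (i == ip) index_to_time(tr, ip) else {
    frac <- (half - v[i]) / (v[i + 1L] - v[i])
    index_to_time(tr, i) + frac / tr$rate
  }
  # right half-crossing
  j <- ip
  nmax <- min(length(v), ip + round(0.2 * tr$rate))
  while (j < nmax && (v[j] - half) * sign(amp) > 0) j <- j + 1L
  t_right <- if (j == ip) index_to_time(tr, ip) else {
    frac <- (half - v[j - 1L]) / (v[j] - v[j - 1L])
    index_to_time(tr, j - 1L) + frac / tr$rate
  }
  data.frame(onset_s = onset, peak_time_s = index_to_time(tr, ip),
             amplitude_mv = amp,
             half_duration_ms = (t_right - t_left) * 1000,
             onset_to_peak_ms = (index_to_time(tr, ip) - onset) * 1000,
             kind = kind, channel_role = tr$channel_role,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Detect action potentials in a whole-cell trace
#'
#' APs are contiguous excursions exceeding 40 mV above the resting
#' potential; the peak is the maximum within each excursion, the onset
#' is found by backward scan at 10 mV/ms.
#'
#' @param tr A WC [trace()].
#' @param resting Resting potential in mV; defaults to the trace median.
#' @param threshold_above_rest Detection threshold above rest, mV
#'   (default 40).
#' @param onset_threshold Onset derivative threshold, mV/ms (default 10).
#' @param smooth_hz Low-pass cutoff for the derivative (default 1000).
#' @return Event data frame (see [measure_event()]).
#' @export
detect_aps_wc <- function(tr, resting = NULL, threshold_above_rest = 40,
                          onset_threshold = 10, smooth_hz = 1000) {
  stopifnot(is_trace(tr))
  if (tr$channel_role != "WC") stop("detect_aps_wc expects a WC trace")
  if (is.null(resting)) resting <- stats::median(tr$samples)
  thr <- resting + threshold_above_rest
  mask <- tr$samples > thr
  if (!any(mask)) return(empty_events())
  runs <- logical_runs(mask)
  out <- lapply(seq_len(nrow(runs)), function(k) {
    seg <- runs[k, "start"]:runs[k, "end"]
    ip <- seg[which.max(tr$samples[seg])]
    pt <- index_to_time(tr, ip)
    on <- event_onset(tr, pt, onset_threshold, smooth_hz = smooth_hz)
    ev <- measure_event(tr, on$onset, pt, kind = "AP")
    ev$flagged <- ev$flagged | on$flagged
    ev
  })
  do.call(rbind, out)
}

#' Detect action potentials in a cell-attached trace
#'
#' Cell-attached APs are strongly attenuated, so detection uses the
#' first derivative of the (smoothed) potential at a 1 mV/ms threshold
#' with refractory grouping of nearby crossings. Measurement is
#' performed on the smoothed trace.
#'
#' @param tr A CA [trace()].
#' @param threshold Derivative threshold, mV/ms (default 1).
#' @param smooth_hz Low-pass cutoff before differentiation (default
#'   1000; use a lower cutoff at low sampling rates so the derivative
#'   noise floor stays well below threshold).
#' @param refractory_ms Crossings closer than this are grouped (default
#'   2 ms).
#' @param peak_window_ms Forward peak-search window from the crossing
#'   (default 10 ms).
#' @return Event data frame.
#' @export
detect_aps_ca <- function(tr, threshold = 1, smooth_hz = 1000,
                          refractory_ms = 2, peak_window_ms = 10) {
  stopifnot(is_trace(tr))
  if (tr$channel_role != "CA") stop("detect_aps_ca expects a CA trace")
  sd_ <- smoothed_derivative(tr, smooth_hz)
  sm <- tr; sm$samples <- sd_$x
  mask <- sd_$d >= threshold
  if (!any(mask)) return(empty_events())
  runs <- logical_runs(mask)
  # merge runs separated by less than the refractory gap
  gap_n <- round(refractory_ms * 1e-3 * tr$rate)
  keep <- list(runs[1, ])
  if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
    lastk <- keep[[length(keep)]]
    if (runs[k, "start"] - lastk["end"] <= gap_n)
      keep[[length(keep)]]["end"] <- runs[k, "end"]
    else keep[[length(keep) + 1L]] <- runs[k, ]
  }
  out <- lapply(keep, function(rn) {
    j1 <- min(length(sm$samples), rn["end"] + round(peak_window_ms * 1e-3 *
                                                    tr$rate))
    seg <- rn["start"]:j1
    ip <- seg[which.max(sm$samples[seg])]
    pt <- index_to_time(tr, ip)
    on <- event_onset(sm, pt, threshold)
    if (!(on$onset < pt)) return(NULL)
    ev <- measure_event(sm, on$onset, pt, kind = "AP")
    ev$flagged <- ev$flagged | on$flagged
    ev
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_events() else out
}

#' Detect spontaneous PSPs in a whole-cell trace
#'
#' sPSPs are detected where the first derivative of the (smoothed)
#' potential exceeds 1 mV/ms, after blanking +/-10 ms around any
#' supplied AP times; the peak is the local extremum within 50 ms of the
#' crossing and the onset is refined by backward scan at 0.1 mV/ms.
#' Measurement is performed on the smoothed trace.
#'
#' @param tr A WC [trace()].
#' @param threshold Detection derivative threshold, mV/ms (default 1).
#' @param onset_threshold Onset derivative threshold, mV/ms (default
#'   0.1).
#' @param smooth_hz Low-pass cutoff before differentiation for the
#'   detection scan (default 500).
#' @param measure_smooth_hz Lower cutoff used for onset refinement and
#'   amplitude measurement (default 300); the gentler 0.1 mV/ms onset
#'   scan needs a derivative noise floor well below its threshold, while
#'   the detection scan benefits from preserving the rise slope.
#' @param ap_times AP times (s) to blank (default: detected internally
#'   with [detect_aps_wc()]).
#' @param blank_ms Half-width of the AP blanking window, ms (default 10).
#' @param peak_window_ms Forward peak-search window, ms (default 50).
#' @param min_separation_ms Events with peaks closer than this are
#'   collapsed to the earlier one (default 10 ms).
#' @return Event data frame.
#' @export
detect_spsps <- function(tr, threshold = 1, onset_threshold = 0.1,
                         smooth_hz = 500, measure_smooth_hz = 300,
                         ap_times = NULL, blank_ms = 10,
                         peak_window_ms = 50, min_separation_ms = 10) {
  stopifnot(is_trace(tr))
  if (tr$channel_role != "WC") stop("detect_spsps expects a WC trace")
  if (is.null(ap_times)) ap_times <- detect_aps_wc(tr,
                                                   smooth_hz = smooth_hz)$peak_time_s
  sd_ <- smoothed_derivative(tr, smooth_hz)
  d <- sd_$d
  # smoother copy for onset refinement and amplitude/kinetics measurement
  sm <- tr
  sm$samples <- smoothed_derivative(tr, min(measure_smooth_hz,
                                            smooth_hz))$x
  if (length(ap_times)) {
    for (ta in ap_times) {
      i0 <- time_to_index(tr, ta - blank_ms * 1e-3)
      i1 <- time_to_index(tr, ta + blank_ms * 1e-3)
      d[i0:i1] <- 0
    }
  }
  mask <- d >= threshold
  if (!any(mask)) return(empty_events())
  runs <- logical_runs(mask)
  # merge threshold runs separated by less than min_separation (one event)
  gap_n <- round(min_separation_ms * 1e-3 * tr$rate)
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
    lastk <- merged[[length(merged)]]
    if (runs[k, "start"] - lastk["end"] <= gap_n)
      merged[[length(merged)]]["end"] <- runs[k, "end"]
    else merged[[length(merged) + 1L]] <- runs[k, ]
  }
  pw <- round(peak_window_ms * 1e-3 * tr$rate)
  starts <- vapply(merged, `[`, integer(1), "start")
  out <- list()
  for (k in seq_along(merged)) {
    i0 <- starts[k]
    # bound the peak search at the next detection run so overlapping
    # events are not absorbed into one another
    i1 <- min(length(sm$samples), i0 + pw,
              if (k < length(merged)) starts[k + 1L] - 1L else .Machine$integer.max)
    if (i1 <= i0) next
    seg <- i0:i1
    ip <- seg[which.max(sm$samples[seg])]
    pt <- index_to_time(tr, ip)
    on <- event_onset(sm, pt, onset_threshold)
    if (!(on$onset < pt)) next
    ev <- measure_event(sm, on$onset, pt, kind = "PSP")
    ev$flagged <- ev$flagged | on$flagged
    out[[length(out) + 1L]] <- ev
  }
  if (!length(out)) return(empty_events())
  do.call(rbind, out)
}

#' Evoked-response amplitude from an averaged trace
#'
#' Signed maximum deflection within 200 ms after the stimulus, relative
#' to the median baseline within 200 ms before the stimulus.
#'
#' @param avg_tr An averaged [trace()].
#' @param stim_time Stimulus time, s.
#' @param window_s Pre/post window length, s (default 0.2).
#' @return Signed amplitude in mV.
#' @export
evoked_amplitude <- function(avg_tr, stim_time, window_s = 0.2) {
  stopifnot(is_trace(avg_tr))
  t_lo <- stim_time - window_s; t_hi <- stim_time + window_s
  if (t_lo < avg_tr$t0 - 0.5 / avg_tr$rate ||
      t_hi > avg_tr$t0 + trace_duration(avg_tr) + 0.5 / avg_tr$rate)
    stop("stimulus window outside trace bounds")
  i_stim <- time_to_index(avg_tr, stim_time)
  pre <- avg_tr$samples[time_to_index(avg_tr, t_lo):(i_stim - 1L)]
  post <- avg_tr$samples[(i_stim + 1L):time_to_index(avg_tr, t_hi)]
  defl <- post - stats::median(pre)
  defl[which.max(abs(defl))]
}

#' Dominant frequency of an event waveform
#'
#' Computed on the convention that the event half-width spans one third
#' of the oscillation period: `f = 1 / (3 * half_width)`.
#'
#' @param half_width_ms Event half-width in ms (> 0).
#' @return Frequency in Hz.
#' @examples
#' dominant_frequency(1.389)  # ~240 Hz, AP-like
#' dominant_frequency(85.5)   # ~3.9 Hz, sPSP-like
#' @export
dominant_frequency <- function(half_width_ms) {
  if (any(half_width_ms <= 0)) stop("half-width must be positive")
  1000 / (3 * half_width_ms)
}

#' Amplitude-to-noise ratio of detected events
#'
#' Mean absolute event amplitude divided by the baseline noise SD
#' (conventionally the SD of the quietest 1 s interval, see
#' [quietest_interval()]).
#'
#' @param events Event data frame with an `amplitude_mv` column.
#' @param noise_sd Baseline noise SD, mV (> 0).
#' @return Dimensionless ratio.
#' @export
amplitude_noise_ratio <- function(events, noise_sd) {
  if (!nrow(events)) stop("no events: amplitude-to-noise ratio undefined")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive")
  mean(abs(events$amplitude_mv)) / noise_sd
}

#' Pair WC events with the CA trace and compute transfer statistics
#'
#' For each WC-detected event the simultaneous CA trace is measured at
#' the same onset, with the CA peak searched up to `max_lag_ms` beyond
#' the WC peak (CA peaks are delayed by the circuit filter). The summary
#' reports the per-event CA/WC amplitude-ratio median and IQR, the
#' regression slope through the origin, and the Pearson correlation of
#' paired amplitudes.
#'
#' @param wc_events Event data frame from WC detection.
#' @param ca_trace The time-aligned CA [trace()].
#' @param max_lag_ms Maximum CA peak lag beyond the WC peak, ms
#'   (default 5).
#' @param smooth_hz Low-pass cutoff for CA measurement (default 1000).
#' @return A list with `pairs` (data frame: WC and CA measurements plus
#'   `lag_ms`) and `summary` (`ratio_median`, `ratio_iqr`, `slope`,
#'   `pearson_r`, `n`).
#' @export
pair_and_transfer <- function(wc_events, ca_trace, max_lag_ms = 5,
                              smooth_hz = 1000) {
  stopifnot(is_trace(ca_trace))
  if (ca_trace$channel_role != "CA") stop("ca_trace must have role CA")
  if (!nrow(wc_events))
    return(list(pairs = empty_events(), summary = list(n = 0L)))
  sm <- if (!is.null(smooth_hz) && smooth_hz < ca_trace$rate / 2)
    lowpass(ca_trace, smooth_hz) else ca_trace
  rows <- list()
  for (k in seq_len(nrow(wc_events))) {
    ev <- wc_events[k, ]
    i0 <- time_to_index(sm, ev$onset_s)
    i1 <- time_to_index(sm, ev$peak_time_s + max_lag_ms * 1e-3)
    if (i1 <= i0) next
    seg <- i0:i1
    ip <- if (ev$amplitude_mv >= 0) seg[which.max(sm$samples[seg])]
          else seg[which.min(sm$samples[seg])]
    pt <- index_to_time(sm, ip)
    if (!(ev$onset_s < pt)) next
    ca_ev <- measure_event(sm, ev$onset_s, pt, kind = ev$kind)
    rows[[length(rows) + 1L]] <- data.frame(
      onset_s = ev$onset_s,
      wc_amplitude_mv = ev$amplitude_mv,
      ca_amplitude_mv = ca_ev$amplitude_mv,
      wc_half_duration_ms = ev$half_duration_ms,
      ca_half_duration_ms = ca_ev$half_duration_ms,
      ratio = ca_ev$amplitude_mv / ev$amplitude_mv,
      lag_ms = (pt - ev$peak_time_s) * 1000,
      kind = ev$kind, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    return(list(pairs = data.frame(), summary = list(n = 0L)))
  qs <- stats::quantile(pairs$ratio, c(0.25, 0.5, 0.75), names = FALSE)
  list(pairs = pairs,
       summary = list(
         ratio_median = qs[2], ratio_iqr = c(qs[1], qs[3]),
         slope = sum(pairs$wc_amplitude_mv * pairs$ca_amplitude_mv) /
           sum(pairs$wc_amplitude_mv^2),
         pearson_r = if (nrow(pairs) > 2)
           stats::cor(pairs$wc_amplitude_mv, pairs$ca_amplitude_mv)
         else NA_real_,
         n = nrow(pairs)))
}
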