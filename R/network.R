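#' Detect field network events (GDPs / SWRs) from an LFP trace
#'
#' Events are detected from the 1--100 Hz band-passed LFP as
#' supra-threshold excursions of the declared polarity, at a threshold
#' of 3 standard deviations of the quietest 100 s episode (traces
#' shorter than the episode fall back to the quietest half, flagged).
#' Excursions closer than 200 ms are merged; the event reference time is
#' the excursion extremum. Giant depolarizing potentials are negative
#' field deflections (CA3), sharp-wave ripples positive (CA1 pyramidal
#' layer). The threshold is SD-relative, so the LFP unit declaration
#' cancels.
#'
#' @param lfp An LFP [trace()].
#' @param polarity `"negative"` or `"positive"`.
#' @param band Band-pass corners, Hz (default `c(1, 100)`).
#' @param threshold_sd Threshold in SDs of the quiet episode (default 3).
#' @param quiet_s Quiet-episode duration, s (default 100).
#' @param merge_gap_s Excursions closer than this are merged (default
#'   0.2).
#' @param sidelobe_s Side-lobe rejection window, s (default 0.3; 0
#'   disables): an excursion is discarded when a larger excursion of the
#'   opposite polarity lies within this distance, since band-passing a
#'   monophasic deflection leaves rebound lobes of the opposite sign
#'   that would otherwise register as spurious events.
#' @param kind Label stored with the events (defaults to `"GDP"` for
#'   negative polarity, `"SWR"` for positive).
#' @return Data frame (`ref_time_s`, `start_s`, `end_s`,
#'   `field_amplitude`, `kind`) with attributes `threshold` and
#'   `quiet_flagged`.
#' @export
detect_field_events <- function(lfp, polarity = c("negative", "positive"),
                                band = c(1, 100), threshold_sd = 3,
                                quiet_s = 100, merge_gap_s = 0.2,
                                sidelobe_s = 0.3, kind = NULL) {
  stopifnot(is_trace(lfp))
  polarity <- match.arg(polarity)
  if (is.null(kind)) kind <- if (polarity == "negative") "GDP" else "SWR"
  filt <- bandpass(lfp, band[1], band[2])
  flagged <- FALSE
  if (trace_duration(filt) >= quiet_s) {
    q <- quietest_interval(filt, quiet_s)
  } else {
    q <- quietest_interval(filt, trace_duration(filt) / 2)
    flagged <- TRUE
  }
  thr <- threshold_sd * q$sd
  s <- if (polarity == "negative") -filt$samples else filt$samples
  mask <- s > thr
  empty <- data.frame(ref_time_s = numeric(), start_s = numeric(),
                      end_s = numeric(), field_amplitude = numeric(),
                      kind = character(), stringsAsFactors = FALSE)
  if (!any(mask)) {
    attr(empty, "threshold") <- thr; attr(empty, "quiet_flagged") <- flagged
    return(empty)
  }
  runs <- logical_runs(mask)
  gap_n <- round(merge_gap_s * lfp$rate)
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
    lastk <- merged[[length(merged)]]
    if (runs[k, "start"] - lastk["end"] <= gap_n)
      merged[[length(merged)]]["end"] <- runs[k, "end"]
    else merged[[length(merged) + 1L]] <- runs[k, ]
  }
  out <- do.call(rbind, lapply(merged, function(rn) {
    seg <- rn["start"]:rn["end"]
    ip <- seg[which.max(s[seg])]
    data.frame(ref_time_s = index_to_time(filt, ip),
               start_s = index_to_time(filt, rn[["start"]]),
               end_s = index_to_time(filt, rn[["end"]]),
               field_amplitude = filt$samples[ip], kind = kind,
               stringsAsFactors = FALSE)
  }))
  if (sidelobe_s > 0 && nrow(out)) {
    sl_n <- round(sidelobe_s * lfp$rate)
    keep_ev <- vapply(seq_len(nrow(out)), function(k) {
      ic <- time_to_index(filt, out$ref_time_s[k])
      seg <- max(1L, ic - sl_n):min(length(s), ic + sl_n)
      max(-s[seg]) <= s[ic]
    }, logical(1))
    out <- out[keep_ev, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- thr
  attr(out, "quiet_flagged") <- flagged
  out
}

#' Detect multi-unit activity from an LFP trace
#'
#' Spikes are negative-going crossings of 3 standard deviations (of the
#' quietest 100 s episode) in the 300--2500 Hz band-passed signal, with
#' a 1 ms dead time; the spike time is the local minimum following the
#' crossing.
#'
#' @param lfp An LFP [trace()]; the sampling rate must exceed twice the
#'   upper band corner.
#' @param band Band corners, Hz (default `c(300, 2500)`).
#' @param threshold_sd Threshold in SDs (default 3).
#' @param quiet_s Quiet-episode duration, s (default 100).
#' @param dead_time_ms Dead time after each spike, ms (default 1).
#' @return Numeric vector of spike times in seconds, with attribute
#'   `threshold`.
#' @export
detect_mua <- function(lfp, band = c(300, 2500), threshold_sd = 3,
                       quiet_s = 100, dead_time_ms = 1) {
  stopifnot(is_trace(lfp))
  if (lfp$rate <= 2 * band[2])
    stop("sampling rate too low for the ", band[2], " Hz band corner")
  filt <- bandpass(lfp, band[1], band[2])
  q <- if (trace_duration(filt) >= quiet_s) quietest_interval(filt, quiet_s)
       else quietest_interval(filt, trace_duration(filt) / 2)
  thr <- threshold_sd * q$sd
  v <- filt$samples
  below <- v < -thr
  cross <- which(below[-1] & !below[-length(below)]) + 1L
  dead_n <- round(dead_time_ms * 1e-3 * lfp$rate)
  times <- numeric()
  last <- -Inf
  for (i in cross) {
    if (i - last < dead_n) next
    seg <- i:min(length(v), i + dead_n)
    ip <- seg[which.min(v[seg])]
    times <- c(times, index_to_time(filt, ip))
    last <- i
  }
  attr(times, "threshold") <- thr
  times
}

#' Peri-event average or histogram
#'
#' Aligns either a voltage trace or a set of spike times to field-event
#' reference times. For a trace, returns the event-aligned mean and
#' standard error after subtracting a per-event baseline (the median of
#' the first half of the pre-event window); for spike times, returns a
#' peri-event histogram in the stated bins. Events whose window falls
#' outside the trace are dropped and counted.
#'
#' @param x A [trace()] (typically the CA channel) or a numeric vector
#'   of spike times in seconds.
#' @param events Event data frame from [detect_field_events()] (uses
#'   `ref_time_s`).
#' @param window Half-window in seconds (axis spans `-window..+window`).
#' @param bin_ms Bin width for trace decimation / spike histogram, ms.
#' @return A list of class `cacc_perievent`: `time_s` (relative axis),
#'   and either `mean`/`se` (trace input, in trace units) or `counts`
#'   (spike input, mean counts per event per bin), plus `n_events`,
#'   `n_dropped`.
#' @export
peri_event <- function(x, events, window = 1, bin_ms = 10) {
  if (!nrow(events)) stop("no events supplied")
  refs <- events$ref_time_s
  if (is_trace(x)) {
    wn <- round(window * x$rate)
    n_tr <- length(x$samples)
    mat <- NULL
    dropped <- 0L
    for (r in refs) {
      ic <- time_to_index(x, r)
      if (ic - wn < 1L || ic + wn > n_tr) { dropped <- dropped + 1L; next }
      seg <- x$samples[(ic - wn):(ic + wn)]
      base <- stats::median(seg[1:floor(wn / 2)])  # first half of pre-window
      mat <- rbind(mat, seg - base)
    }
    if (is.null(mat)) stop("all events fall at trace edges")
    list(
      structure(list(
        time_s = seq(-wn, wn) / x$rate,
        mean = colMeans(mat),
        se = apply(mat, 2, stats::sd) / sqrt(nrow(mat)),
        n_events = nrow(mat), n_dropped = dropped),
        class = "cacc_perievent"))[[1]]
  } else {
    spikes <- as.numeric(x)
    breaks <- seq(-window, window, by = bin_ms * 1e-3)
    counts <- numeric(length(breaks) - 1L)
    for (r in refs) {
      rel <- spikes - r
      rel <- rel[rel >= -window & rel <= window]
      if (length(rel))
        counts <- counts + graphics::hist(rel, breaks = breaks,
                                          plot = FALSE)$counts
    }
    structure(list(
      time_s = (breaks[-1] + breaks[-length(breaks)]) / 2,
      counts = counts / length(refs),
      n_events = length(refs), n_dropped = 0L),
      class = "cacc_perievent")
  }
}

#' Membrane-potential change during a network event
#'
#' Signed extremum of the CA voltage within the event window relative to
#' the pre-event baseline (median of the 1 s preceding the window;
#' truncated and flagged if unavailable). A short running-median filter
#' (default 20 ms) suppresses superimposed action potentials first, so
#' the extremum reflects the slow depolarization envelope rather than
#' spike peaks.
#'
#' @param ca A CA [trace()].
#' @param event One row of a [detect_field_events()] data frame (uses
#'   `start_s`, `end_s`).
#' @param baseline_s Pre-event baseline duration, s (default 1).
#' @param median_ms AP-suppression median window, ms (default 20; 0
#'   disables).
#' @return Signed change in mV with attribute `flagged`.
#' @export
event_em_change <- function(ca, event, baseline_s = 1, median_ms = 20) {
  stopifnot(is_trace(ca))
  i0 <- time_to_index(ca, event$start_s)
  i1 <- time_to_index(ca, event$end_s)
  if (i1 <= i0) stop("event window outside trace")
  b0 <- time_to_index(ca, event$start_s - baseline_s)
  flagged <- (event$start_s - baseline_s) < ca$t0
  if (b0 >= i0) { b0 <- max(1L, i0 - 1L); flagged <- TRUE }
  v <- ca$samples
  if (median_ms > 0) {
    k <- round(median_ms * 1e-3 * ca$rate)
    if (k %% 2 == 0) k <- k + 1L
    if (k >= 3 && k < (i1 - b0)) {
      seg <- b0:i1
      v <- ca$samples
      v[seg] <- stats::runmed(ca$samples[seg], k, endrule = "median")
    }
  }
  base <- stats::median(v[b0:(i0 - 1L)])
  defl <- v[i0:i1] - base
  out <- defl[which.max(abs(defl))]
  attr(out, "flagged") <- flagged
  out
}
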