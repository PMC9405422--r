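#' Correct a trace for the liquid junction potential
#'
#' Applies the convention `corrected = recorded - ljp`, which makes
#' membrane potentials more negative (e.g. a 16 mV junction potential
#' shifts -65 mV to -81 mV). The correction may be applied only once;
#' `ljp_applied` records it.
#'
#' @param tr A [trace()] with `ljp_applied == 0`.
#' @param ljp Junction potential in mV.
#' @return The corrected trace.
#' @export
correct_ljp <- function(tr, ljp) {
  stopifnot(is_trace(tr))
  if (tr$ljp_applied != 0)
    stop("liquid junction correction already applied (",
         tr$ljp_applied, " mV)")
  out <- tr
  out$samples <- tr$samples - ljp
  out$ljp_applied <- ljp
  out
}

#' Nernst equilibrium potential
#'
#' \deqn{E = \frac{RT}{zF} \ln\frac{[X]_{out}}{[X]_{in}}} in mV.
#'
#' @param z Ion valence (e.g. -1 for chloride, +1 for potassium).
#' @param conc_in Intracellular (pipette) concentration, mM (> 0).
#' @param conc_out Extracellular (bath) concentration, mM (> 0).
#' @param temperature_c Temperature in Celsius; default 30 (bath
#'   temperature of a typical submerged-slice recording).
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential(-1, conc_in = 4, conc_out = 136.1)   # about -92 mV
#' @export
nernst_potential <- function(z, conc_in, conc_out, temperature_c = 30) {
  if (conc_in <= 0 || conc_out <= 0)
    stop("concentrations must be positive")
  if (z == 0) stop("valence must be non-zero")
  R <- 8.314462618; F <- 96485.33212
  T_k <- temperature_c + 273.15
  1000 * (R * T_k / (z * F)) * log(conc_out / conc_in)
}

#' Off-line bridge compensation
#'
#' Removes the voltage drop across the electrode during current-step
#' injection by subtracting a rectangular potential. Boundaries are
#' placed where the first derivative of the potential exceeds a fraction
#' (default 30%) of the derivative peak during the step ON-phase. The
#' rectangle amplitude is the instantaneous voltage jump at the ON
#' boundary, estimated as the difference of 0.2-ms means immediately
#' inside and outside the boundary.
#'
#' @param tr A [trace()] containing a step-evoked episode.
#' @param derivative_threshold_frac Fraction of the ON-phase derivative
#'   peak defining the boundaries (default 0.30).
#' @return The corrected trace with attributes `bridge_on_s`,
#'   `bridge_off_s`, `bridge_amplitude_mv`, `bridge_flagged` (TRUE if no
#'   step boundary was found and the trace was returned unchanged).
#' @export
bridge_compensate <- function(tr, derivative_threshold_frac = 0.30) {
  stopifnot(is_trace(tr))
  if (isTRUE(attr(tr, "bridge_applied")))
    stop("bridge compensation already applied")
  v <- tr$samples
  d <- c(0, diff(v)) * tr$rate / 1000  # mV/ms
  pk <- max(abs(d))
  if (pk <= 0) {
    out <- tr
    attr(out, "bridge_flagged") <- TRUE
    return(out)
  }
  thr <- derivative_threshold_frac * pk
  above <- which(abs(d) >= thr)
  # the ON transient is the excursion containing the global derivative peak;
  # the OFF transient is the last excursion of comparable magnitude
  i_on <- above[1]
  i_off <- above[length(above)]
  if (i_off <= i_on + 1) {
    out <- tr
    attr(out, "bridge_flagged") <- TRUE
    return(out)
  }
  k <- max(1L, round(0.2e-3 * tr$rate))  # 0.2 ms in samples
  pre <- v[max(1L, i_on - k):(i_on - 1L)]
  post <- v[i_on:min(length(v), i_on + k - 1L)]
  amp <- mean(post) - mean(pre)
  out <- tr
  out$samples[i_on:(i_off - 1L)] <- out$samples[i_on:(i_off - 1L)] - amp
  attr(out, "bridge_on_s") <- index_to_time(tr, i_on)
  attr(out, "bridge_off_s") <- index_to_time(tr, i_off)
  attr(out, "bridge_amplitude_mv") <- amp
  attr(out, "bridge_flagged") <- FALSE
  attr(out, "bridge_applied") <- TRUE
  out
}

#' Quietest interval of a trace
#'
#' Finds the window of the requested duration with the smallest sample
#' standard deviation, searched on a sliding grid with stride
#' duration/10. Used to estimate the baseline noise floor (e.g. the
#' quietest 1 s for PSP amplitude-to-noise ratios, or the quietest 100 s
#' for SD-relative field-event thresholds).
#'
#' @param tr A [trace()].
#' @param duration Window duration in seconds (<= trace duration).
#' @return A list with `start` (s), `duration` (s), `sd` and `mean`
#'   (trace units).
#' @export
quietest_interval <- function(tr, duration) {
  stopifnot(is_trace(tr))
  n <- length(tr$samples)
  wn <- round(duration * tr$rate)
  if (wn < 2 || wn > n)
    stop("trace shorter than the requested interval")
  stride <- max(1L, round(wn / 10))
  starts <- seq.int(1L, n - wn + 1L, by = stride)
  cs <- c(0, cumsum(tr$samples))
  cs2 <- c(0, cumsum(tr$samples^2))
  s1 <- cs[starts + wn] - cs[starts]
  s2 <- cs2[starts + wn] - cs2[starts]
  v <- (s2 - s1^2 / wn) / (wn - 1)
  i <- which.min(v)
  list(start = index_to_time(tr, starts[i]), duration = wn / tr$rate,
       sd = sqrt(max(v[i], 0)), mean = s1[i] / wn)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass. Standard corners in this pipeline: 1-100 Hz for field
#' events, 300-2500 Hz for multi-unit activity.
#'
#' @param tr A [trace()].
#' @param lo,hi Corner frequencies in Hz, `0 < lo < hi < rate/2`.
#' @param order Butterworth order per direction (default 3: passband
#'   flat to within ~1% across 1-100 Hz at typical rates).
#' @return The filtered trace.
#' @export
bandpass <- function(tr, lo, hi, order = 3) {
  stopifnot(is_trace(tr))
  ny <- tr$rate / 2
  if (!(lo > 0 && lo < hi && hi < ny))
    stop("band corners must satisfy 0 < lo < hi < rate/2")
  bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  out <- tr
  out$samples <- filtfilt_padded(bf, tr$samples, round(3 * tr$rate / lo))
  out
}

## zero-phase filtering with reflection padding and demeaning: plain
## forward-backward filtering starts from zero state, so a DC-offset
## trace would otherwise show large edge transients
filtfilt_padded <- function(bf, x, pad_n) {
  n <- length(x)
  p <- min(n - 1L, max(pad_n, 1L))
  xm <- mean(x)
  xc <- x - xm
  xp <- c(rev(xc[2:(p + 1L)]), xc, rev(xc[(n - p):(n - 1L)]))
  y <- as.numeric(signal::filtfilt(bf, xp))[(p + 1L):(p + n)]
  dc_gain <- sum(bf$b) / sum(bf$a)  # 1 for low-pass, 0 for band-pass
  y + xm * dc_gain^2
}

#' Zero-phase low-pass filter
#'
#' Forward-backward Butterworth low-pass, used to smooth traces before
#' derivative-threshold event detection.
#'
#' @param tr A [trace()].
#' @param cutoff Corner frequency in Hz, `< rate/2`.
#' @param order Butterworth order per direction (default 2).
#' @return The filtered trace.
#' @export
lowpass <- function(tr, cutoff, order = 2) {
  stopifnot(is_trace(tr))
  ny <- tr$rate / 2
  if (!(cutoff > 0 && cutoff < ny))
    stop("cutoff must satisfy 0 < cutoff < rate/2")
  bf <- signal::butter(order, cutoff / ny, type = "low")
  out <- tr
  out$samples <- filtfilt_padded(bf, tr$samples, round(3 * tr$rate / cutoff))
  out
}

#' Running-median low-pass filter
#'
#' Median filter with window `1/cutoff` seconds (rounded to an odd
#' sample count). A sub-1-Hz median low-pass suppresses action
#' potentials while preserving slow membrane-potential shifts.
#'
#' @param tr A [trace()].
#' @param cutoff Effective cutoff in Hz (window = 1/cutoff s), `< rate/2`.
#' @return The filtered trace.
#' @export
median_lowpass <- function(tr, cutoff) {
  stopifnot(is_trace(tr))
  if (!(cutoff > 0 && cutoff < tr$rate / 2))
    stop("cutoff must satisfy 0 < cutoff < rate/2")
  k <- round(tr$rate / cutoff)
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, length(tr$samples) - (1 - length(tr$samples) %% 2))
  out <- tr
  out$samples <- as.numeric(stats::runmed(tr$samples, k, endrule = "median"))
  out
}

#' Steady-state voltage shift between two windows
#'
#' Mean voltage over the response window minus mean voltage over the
#' baseline window; used for high-potassium depolarizations and
#' current-step responses where steady-state levels define the response.
#'
#' @param tr A [trace()].
#' @param baseline_window,response_window Two-element numeric vectors
#'   `c(start, end)` in seconds, within the trace and non-overlapping.
#' @return Shift in mV (response minus baseline).
#' @export
steady_state_shift <- function(tr, baseline_window, response_window) {
  stopifnot(is_trace(tr), length(baseline_window) == 2,
            length(response_window) == 2)
  if (max(baseline_window[1], response_window[1]) <
      min(baseline_window[2], response_window[2]))
    stop("baseline and response windows must not overlap")
  t1 <- trace_times(tr)[c(1, length(tr$samples))]
  for (wdw in list(baseline_window, response_window))
    if (wdw[1] < t1[1] - 0.5 / tr$rate || wdw[2] > t1[2] + 0.5 / tr$rate)
      stop("window outside trace bounds")
  idx <- function(wdw) time_to_index(tr, wdw[1]):time_to_index(tr, wdw[2])
  mean(tr$samples[idx(response_window)]) -
    mean(tr$samples[idx(baseline_window)])
}
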