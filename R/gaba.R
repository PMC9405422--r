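#' Fit evoked-amplitude versus membrane potential (reversal-potential
#' estimate)
#'
#' Ordinary least-squares fit of the linear model
#' `amplitude = slope * (E_GABA - Em)`: the amplitude depends negatively
#' on the membrane potential, the zero-amplitude intercept estimates the
#' reversal potential `E_GABA`, and the slope is a conductance proxy.
#' Because the intercept is a ratio, scaling all amplitudes by a
#' positive constant (e.g. circuit attenuation in the cell-attached
#' frame) changes the slope but not `E_GABA`.
#'
#' @param amplitudes Evoked response amplitudes, mV.
#' @param em Membrane potentials at which they were measured, mV (same
#'   length; at least 2 distinct values).
#' @param frame Reference frame label: `"WC"`, `"CA"`, or
#'   `"CA-reframed-to-WC"`.
#' @return A list of class `cacc_gaba_fit`: `slope` (mV per mV,
#'   conductance proxy, positive for a GABA-like negative dependence),
#'   `E_GABA` (mV; `NA` and `degenerate = TRUE` when the slope is
#'   indistinguishable from zero), `frame`, `r` (Pearson correlation),
#'   `n`.
#' @examples
#' fit_amplitude_vs_em(c(2, -2), c(-80, -40), frame = "WC")$E_GABA  # -60
#' @export
fit_amplitude_vs_em <- function(amplitudes, em,
                                frame = c("WC", "CA",
                                          "CA-reframed-to-WC")) {
  frame <- match.arg(frame)
  if (length(amplitudes) != length(em))
    stop("amplitudes and em must be paired (equal length)")
  if (length(unique(em)) < 2)
    stop("at least 2 distinct Em levels are required")
  fit <- stats::lm(amplitudes ~ em)
  b <- unname(stats::coef(fit))
  slope <- -b[2]  # amplitude = slope * (E_GABA - Em)
  degenerate <- !is.finite(slope) || abs(slope) < 1e-12
  e_gaba <- if (degenerate) NA_real_ else b[1] / slope
  r <- if (stats::sd(amplitudes) == 0) NA_real_
       else if (length(em) > 2) stats::cor(em, amplitudes)
       else sign(stats::cov(em, amplitudes))
  structure(list(slope = slope, E_GABA = e_gaba, frame = frame,
                 r = r, n = length(em), degenerate = degenerate),
            class = "cacc_gaba_fit")
}

#' @export
print.cacc_gaba_fit <- function(x, ...) {
  cat(sprintf(
    "<cacc_gaba_fit %s> E_GABA %s mV, slope %.4g, r %.3f (n = %d)\n",
    x$frame, if (is.na(x$E_GABA)) "NA" else sprintf("%.2f", x$E_GABA),
    x$slope, x$r, x$n))
  invisible(x)
}

#' GABA driving force
#'
#' `DF_GABA = E_GABA - Em`; positive when GABA is depolarizing.
#'
#' @param E_GABA Reversal potential, mV.
#' @param Em Membrane potential, mV.
#' @return Driving force in mV.
#' @export
driving_force <- function(E_GABA, Em) {
  if (any(!is.finite(E_GABA)) || any(!is.finite(Em)))
    stop("E_GABA and Em must be finite")
  E_GABA - Em
}

#' Refit cell-attached amplitudes against whole-cell membrane potentials
#'
#' The cell-attached frame reports a biased membrane potential (seal
#' shunt), so reversal potentials fitted against the CA baseline are
#' shifted. Refitting the CA amplitudes against the simultaneous WC
#' membrane potentials removes that bias while keeping the CA amplitude
#' measurements.
#'
#' @param ca_amplitudes CA-frame evoked amplitudes, mV.
#' @param em_wc_levels Simultaneous WC membrane potentials, mV (paired).
#' @return A `cacc_gaba_fit` with `frame = "CA-reframed-to-WC"`.
#' @export
reframe_ca_to_wc <- function(ca_amplitudes, em_wc_levels) {
  if (length(ca_amplitudes) != length(em_wc_levels))
    stop("CA amplitudes must be paired with WC Em levels")
  fit_amplitude_vs_em(ca_amplitudes, em_wc_levels,
                      frame = "CA-reframed-to-WC")
}

#' Classify the polarity of an evoked response
#'
#' Sign-based label with an isoelectric dead band around zero.
#'
#' @param evoked_amplitude Signed amplitude, mV (from
#'   [evoked_amplitude()]).
#' @param isoelectric_band Dead-band half-width, mV (default 0.3, about
#'   the noise floor of averaged traces).
#' @return `"depolarizing"`, `"hyperpolarizing"` or `"isoelectric"`
#'   (vectorized).
#' @export
classify_polarity <- function(evoked_amplitude, isoelectric_band = 0.3) {
  out <- ifelse(abs(evoked_amplitude) <= isoelectric_band, "isoelectric",
                ifelse(evoked_amplitude > 0, "depolarizing",
                       "hyperpolarizing"))
  unname(out)
}

#' Analyze a simulated (or measured) GABA session in all three frames
#'
#' Measures per-level evoked amplitudes with [evoked_amplitude()] from
#' the WC and CA averaged traces and fits the amplitude-versus-Em line
#' in the WC frame, the native CA frame (CA amplitudes against CA
#' baselines), and the CA frame reframed to WC membrane potentials.
#'
#' @param session A `cacc_gaba_session` from
#'   [simulate_gaba_experiment()].
#' @return A list with `amp_wc`, `amp_ca` (per-level amplitudes),
#'   `fit_wc`, `fit_ca`, `fit_ca_reframed` (`cacc_gaba_fit`s), and
#'   `df_gaba_wc` (driving force at each WC level from the WC fit).
#' @export
analyze_gaba_session <- function(session) {
  stopifnot(inherits(session, "cacc_gaba_session"))
  amp_wc <- vapply(session$wc_avg, evoked_amplitude, numeric(1),
                   stim_time = session$stim_time_s)
  amp_ca <- vapply(session$ca_avg, evoked_amplitude, numeric(1),
                   stim_time = session$stim_time_s)
  fit_wc <- fit_amplitude_vs_em(amp_wc, session$em_wc, frame = "WC")
  fit_ca <- fit_amplitude_vs_em(amp_ca, session$em_ca, frame = "CA")
  fit_re <- reframe_ca_to_wc(amp_ca, session$em_wc)
  list(amp_wc = amp_wc, amp_ca = amp_ca,
       fit_wc = fit_wc, fit_ca = fit_ca, fit_ca_reframed = fit_re,
       df_gaba_wc = driving_force(fit_wc$E_GABA, session$em_wc))
}
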