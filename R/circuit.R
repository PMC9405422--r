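#' Patch/seal equivalent-circuit parameters
#'
#' The cell-attached current-clamp configuration behaves as a voltage
#' divider made of two RC branches: the membrane patch under the pipette
#' tip (resistance `R_patch`, capacitance `C_patch`) in series with the
#' seal contact (`R_seal`) which is shunted by the electrode capacitance
#' (`C_elec`). The derived quantities
#' \deqn{K_R = R_{seal}/R_{patch}, \quad K_C = C_{elec}/C_{patch}, \quad
#'       \tau = R_{patch} C_{patch}}
#' parameterize the amplitude transfer function (see
#' [amplitude_response()]). Note that GOhm x pF gives tau in
#' milliseconds; the stored `tau_s` is converted to seconds.
#'
#' @param R_seal Seal resistance, GOhm (> 0).
#' @param R_patch Patch resistance, GOhm (> 0).
#' @param C_patch Patch capacitance, pF (> 0).
#' @param C_elec Electrode capacitance, pF (> 0).
#' @return An object of class `cacc_circuit` with fields `R_seal`,
#'   `R_patch`, `C_patch`, `C_elec` and read-only derived `K_R`, `K_C`,
#'   `tau_s`.
#' @examples
#' circuit_params(R_seal = 55.6, R_patch = 7.3, C_patch = 0.8, C_elec = 7)
#' @export
circuit_params <- function(R_seal, R_patch, C_patch, C_elec) {
  prim <- c(R_seal = R_seal, R_patch = R_patch,
            C_patch = C_patch, C_elec = C_elec)
  if (any(!is.finite(prim)) || any(prim <= 0))
    stop("all circuit primitives must be positive and finite")
  structure(list(
    R_seal = R_seal, R_patch = R_patch, C_patch = C_patch, C_elec = C_elec,
    K_R = R_seal / R_patch,
    K_C = C_elec / C_patch,
    tau_s = R_patch * C_patch * 1e-3  # GOhm * pF = ms
  ), class = "cacc_circuit")
}

#' @export
print.cacc_circuit <- function(x, ...) {
  cat(sprintf(paste0(
    "<cacc_circuit> R_seal %.3g GOhm, R_patch %.3g GOhm, ",
    "C_patch %.3g pF, C_elec %.3g pF\n",
    "  K_R %.4g, K_C %.4g, tau %.4g ms; DC %.4g, HF %.4g\n"),
    x$R_seal, x$R_patch, x$C_patch, x$C_elec,
    x$K_R, x$K_C, x$tau_s * 1e3, dc_transfer(x), hf_transfer(x)))
  invisible(x)
}

#' Amplitude transfer function of the cell-attached recording circuit
#'
#' Amplitude ratio of the cell-attached to whole-cell voltage signal at
#' frequency `f`:
#' \deqn{AR(f) = \frac{\sqrt{(2\pi K_R \tau f)^2 + K_R^2}}
#'                    {\sqrt{(2\pi (K_C+1) K_R \tau f)^2 + (K_R+1)^2}}}
#' with the divider limits \eqn{R_{seal}/(R_{seal}+R_{patch})} at DC and
#' \eqn{C_{patch}/(C_{patch}+C_{elec})} at high frequency.
#'
#' @param params A [circuit_params()].
#' @param f Frequency in Hz (vectorized, each >= 0).
#' @return Dimensionless amplitude ratio, same length as `f`.
#' @examples
#' p <- circuit_params(55.6, 7.3, 0.8, 7)
#' amplitude_response(p, c(0.1, 1000))
#' @export
amplitude_response <- function(params, f) {
  stopifnot(inherits(params, "cacc_circuit"))
  if (any(f < 0)) stop("frequency must be non-negative")
  w <- 2 * pi * f * params$K_R * params$tau_s
  sqrt(w^2 + params$K_R^2) /
    sqrt((w * (params$K_C + 1))^2 + (params$K_R + 1)^2)
}

#' DC (zero-frequency) transfer coefficient
#'
#' Resistive-divider limit \eqn{R_{seal}/(R_{seal}+R_{patch})}, the
#' attenuation of resting potential and slow voltage shifts.
#'
#' @inheritParams amplitude_response
#' @return Dimensionless ratio in (0, 1).
#' @export
dc_transfer <- function(params) {
  stopifnot(inherits(params, "cacc_circuit"))
  params$R_seal / (params$R_seal + params$R_patch)
}

#' High-frequency transfer coefficient
#'
#' Capacitive-divider limit \eqn{C_{patch}/(C_{patch}+C_{elec})}, the
#' attenuation floor for fast signals such as action potentials.
#'
#' @inheritParams amplitude_response
#' @return Dimensionless ratio in (0, 1).
#' @export
hf_transfer <- function(params) {
  stopifnot(inherits(params, "cacc_circuit"))
  params$C_patch / (params$C_patch + params$C_elec)
}

#' Complex transfer function of the recording circuit
#'
#' The circuit evaluated as a complex voltage divider
#' \eqn{H(j\omega) = Z_{seal}/(Z_{patch} + Z_{seal})} with
#' \eqn{Z_{patch} = R_{patch}/(1 + j\omega R_{patch} C_{patch})} and
#' \eqn{Z_{seal} = R_{seal}/(1 + j\omega R_{seal} C_{elec})}. Its modulus
#' is algebraically identical to [amplitude_response()]; the two
#' independent derivations serve as mutual correctness oracles.
#'
#' @inheritParams amplitude_response
#' @return Complex gain, same length as `f`.
#' @export
complex_transfer <- function(params, f) {
  stopifnot(inherits(params, "cacc_circuit"))
  if (any(f < 0)) stop("frequency must be non-negative")
  w <- 2 * pi * f
  # impedances in GOhm; omega * GOhm * pF = 1e-3 * omega * s-units
  zp <- params$R_patch / (1 + 1i * w * params$R_patch * params$C_patch * 1e-3)
  zs <- params$R_seal / (1 + 1i * w * params$R_seal * params$C_elec * 1e-3)
  zs / (zp + zs)
}

#' Simulate a cell-attached trace by filtering a whole-cell trace
#'
#' Time-domain realization of the recording circuit: the one-zero/one-pole
#' transfer \eqn{H(s) = K_R (1 + s\tau) / [(K_R+1) + s (K_C+1) K_R \tau]}
#' discretized by the bilinear transform at the trace's sampling rate
#' (which preserves the DC gain exactly). An optional constant offset
#' models active currents across the patch (e.g. single-channel openings
#' depolarizing the patch); it is added after filtering.
#'
#' The filter state is initialized at steady state for the first sample,
#' so traces that start at baseline show no startup transient. Signal
#' content above the Nyquist frequency is aliasing territory, not an
#' error.
#'
#' @param params A [circuit_params()].
#' @param wc A whole-cell [trace()] (`channel_role == "WC"`).
#' @param patch_current_offset Constant offset in mV added after
#'   filtering (default 0).
#' @return A [trace()] with `channel_role = "CA"`, same length and rate.
#' @export
filter_trace <- function(params, wc, patch_current_offset = 0) {
  stopifnot(inherits(params, "cacc_circuit"), is_trace(wc))
  if (wc$channel_role != "WC") stop("input trace must have channel_role WC")
  coef <- bilinear_coef(params, wc$rate)
  x0 <- wc$samples[1]
  y <- as.numeric(signal::filter(coef$b, coef$a, wc$samples - x0))
  y <- y + dc_transfer(params) * x0 + patch_current_offset
  trace(y, rate = wc$rate, channel_role = "CA", t0 = wc$t0,
        units = wc$units, ljp_applied = wc$ljp_applied,
        label = paste0(wc$label, " [CA-filtered]"))
}

## bilinear-transform coefficients of H(s) at sampling rate `rate`
bilinear_coef <- function(params, rate) {
  KR <- params$K_R; KC <- params$K_C; tau <- params$tau_s
  k <- 2 * rate
  # numerator K_R (1 + s tau), denominator (K_R+1) + s (K_C+1) K_R tau
  b <- KR * c(1 + k * tau, 1 - k * tau)
  cden <- k * (KC + 1) * KR * tau
  a <- c(KR + 1 + cden, KR + 1 - cden)
  list(b = b / a[1], a = a / a[1])
}

#' White-noise RMS gain of the recording circuit at a sampling rate
#'
#' Root-mean-square gain of the discretized circuit filter for white
#' noise at the given sampling rate, computed from the frequency response
#' on a dense grid. Used by the synthetic generator to budget excess
#' cell-attached noise.
#'
#' @param params A [circuit_params()].
#' @param rate Sampling rate in Hz.
#' @return Scalar RMS gain in (0, 1].
#' @export
noise_rms_gain <- function(params, rate) {
  coef <- bilinear_coef(params, rate)
  w <- seq(0, pi, length.out = 2048)
  z <- exp(-1i * w)
  h <- (coef$b[1] + coef$b[2] * z) / (coef$a[1] + coef$a[2] * z)
  sqrt(mean(Mod(h)^2))
}

#' Fit the circuit transfer model to a measured amplitude response
#'
#' Least-squares fit of the amplitude transfer function to measured
#' frequency/ratio pairs, with the electrode capacitance held fixed (a
#' four-parameter fit is degenerate against amplitude-only data). The
#' three free parameters are optimized in log-space, which enforces
#' positivity; residuals are taken on the linear amplitude ratio, with an
#' optional log-ratio weighting flag.
#'
#' Default initialization inverts the closed-form limits: the lowest
#' frequency point gives `R_seal/(R_seal+R_patch)` (with an `R_patch` =
#' 5 GOhm prior) and the highest gives `C_patch/(C_patch+C_elec)`.
#'
#' @param fr A [frequency_response()] table.
#' @param C_elec_fixed Electrode capacitance held fixed during the fit,
#'   pF.
#' @param init Optional [circuit_params()] starting point.
#' @param log_residuals Fit residuals on log(AR) instead of AR.
#' @return A list of class `cacc_fit` with `params`
#'   ([circuit_params()]), `residual_norm`, `estimates`, `converged`,
#'   `fixed` (parameter mask).
#' @examples
#' truth <- circuit_params(55.6, 7.3, 0.8, 7)
#' f <- 10^seq(-1, 2, length.out = 25)
#' fit <- fit_transfer(frequency_response(f, amplitude_response(truth, f)),
#'                     C_elec_fixed = 7)
#' fit$params$R_seal
#' @export
fit_transfer <- function(fr, C_elec_fixed, init = NULL,
                         log_residuals = FALSE) {
  stopifnot(inherits(fr, "cacc_freqresp"))
  f <- fr$frequencies; r <- fr$ratios
  w <- fr$weights %||% rep(1, length(f))
  if (length(f) < 3)
    stop("insufficient data: at least 3 frequency points are required ",
         "to fit 3 free parameters")
  if (is.null(init)) {
    dc0 <- min(max(r[which.min(f)], 1e-3), 0.999)
    hf0 <- min(max(r[which.max(f)], 1e-4), 0.999)
    Rp0 <- 5
    Rs0 <- Rp0 * dc0 / (1 - dc0)
    Cp0 <- C_elec_fixed * hf0 / (1 - hf0)
    init <- circuit_params(Rs0, Rp0, Cp0, C_elec_fixed)
  }
  make_params <- function(th)
    circuit_params(exp(th[1]), exp(th[2]), exp(th[3]), C_elec_fixed)
  resid_fn <- function(th) {
    p <- make_params(th)
    m <- amplitude_response(p, f)
    if (log_residuals) sqrt(w) * (log(m) - log(r)) else sqrt(w) * (m - r)
  }
  th0 <- log(c(init$R_seal, init$R_patch, init$C_patch))
  ans <- minpack.lm::nls.lm(par = th0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  converged <- ans$info %in% 1:4
  pars <- make_params(ans$par)
  structure(list(
    params = pars,
    residual_norm = sqrt(sum(ans$fvec^2)),
    estimates = c(R_seal = pars$R_seal, R_patch = pars$R_patch,
                  C_patch = pars$C_patch, C_elec = C_elec_fixed),
    converged = converged,
    fixed = c(R_seal = FALSE, R_patch = FALSE, C_patch = FALSE,
              C_elec = TRUE),
    message = ans$message
  ), class = "cacc_fit")
}

#' @export
print.cacc_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<cacc_fit> %s; residual norm %.3g\n",
    "  R_seal %.4g GOhm, R_patch %.4g GOhm, C_patch %.4g pF ",
    "(C_elec fixed at %.3g pF)\n"),
    if (x$converged) "converged" else "NOT converged",
    x$residual_norm, x$params$R_seal, x$params$R_patch, x$params$C_patch,
    x$params$C_elec))
  invisible(x)
}

#' Measured amplitude-response table
#'
#' Frequency/ratio pairs of the cell-attached over whole-cell amplitude
#' transfer coefficient, e.g. measured from responses to sinusoidal
#' current injection.
#'
#' @param frequencies Strictly increasing frequencies in Hz (> 0).
#' @param ratios Amplitude transfer coefficients (> 0), same length.
#' @param weights Optional per-point weights (> 0).
#' @return An object of class `cacc_freqresp`.
#' @export
frequency_response <- function(frequencies, ratios, weights = NULL) {
  if (length(frequencies) != length(ratios))
    stop("frequencies and ratios must have equal length")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (!is.null(weights) && (length(weights) != length(ratios) ||
                            any(weights <= 0)))
    stop("weights must be positive and match length")
  structure(list(frequencies = as.numeric(frequencies),
                 ratios = as.numeric(ratios), weights = weights),
            class = "cacc_freqresp")
}

#' Depolarization of the patch by a single-channel current
#'
#' Back-of-envelope estimate of how active channels in the attached
#' patch shift the cell-attached potential: a channel of conductance `g`
#' under driving force `df` passes `I = g * df`, which across the patch
#' resistance produces a voltage shift `I * R_patch` (e.g. 100 pS at
#' +90 mV gives 9 pA, hence +9 mV across a 1 GOhm patch). Conveniently,
#' pS x mV = 1e-3 pA and pA x GOhm = mV.
#'
#' @param conductance_ps Channel conductance, pS.
#' @param driving_force_mv Driving force across the patch, mV.
#' @param R_patch Patch resistance, GOhm.
#' @return List with `current_pa` and `depolarization_mv`.
#' @examples
#' single_channel_depolarization(100, 90, 1)
#' @export
single_channel_depolarization <- function(conductance_ps, driving_force_mv,
                                          R_patch) {
  i_pa <- conductance_ps * driving_force_mv * 1e-3
  list(current_pa = i_pa, depolarization_mv = i_pa * R_patch)
}
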