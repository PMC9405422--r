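#' Voltage trace
#'
#' Container for a uniformly sampled voltage series. Time is stored as a
#' sampling rate plus a start time, never as per-sample timestamps; the
#' recording configuration (whole-cell, cell-attached, or extracellular
#' field) is fixed at creation.
#'
#' Internal units are millivolts, seconds and hertz throughout the package.
#' LFP traces may be acquired in microvolts; the `units` field declares
#' this and the field-event detectors are SD-relative so the declaration
#' never needs to be resolved against an absolute scale.
#'
#' @param samples Numeric vector of voltages (mV; for LFP, mV or uV as
#'   declared in `units`). Must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param channel_role One of `"WC"`, `"CA"`, `"LFP"`.
#' @param t0 Start time of the first sample in seconds.
#' @param units Unit string, default `"mV"`.
#' @param ljp_applied Liquid-junction correction already applied, in mV
#'   (0 if none).
#' @param label Free-text label.
#' @return An object of class `cacc_trace`.
#' @export
trace <- function(samples, rate, channel_role = c("WC", "CA", "LFP"),
                  t0 = 0, units = "mV", ljp_applied = 0, label = "") {
  channel_role <- match.arg(channel_role)
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("sampling rate must be a single positive number")
  if (length(samples) == 0L) stop("trace must contain at least one sample")
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  structure(
    list(samples = samples, rate = as.numeric(rate), t0 = as.numeric(t0),
         channel_role = channel_role, units = units,
         ljp_applied = as.numeric(ljp_applied), label = as.character(label)),
    class = "cacc_trace")
}

#' @export
print.cacc_trace <- function(x, ...) {
  cat(sprintf("<cacc_trace %s> %d samples @ %g Hz (%.3f s), units %s%s\n",
              x$channel_role, length(x$samples), x$rate,
              length(x$samples) / x$rate, x$units,
              if (x$ljp_applied != 0)
                sprintf(", LJP %g mV applied", x$ljp_applied) else ""))
  invisible(x)
}

#' @export
length.cacc_trace <- function(x) length(x$samples)

#' Time axis of a trace
#'
#' @param x A `cacc_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "cacc_trace"))
  x$t0 + (seq_along(x$samples) - 1) / x$rate
}

#' Duration of a trace in seconds
#' @param x A `cacc_trace`.
#' @export
trace_duration <- function(x) length(x$samples) / x$rate

#' @export
as.data.frame.cacc_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), voltage = x$samples)
}

is_trace <- function(x) inherits(x, "cacc_trace")

## clamp a time (s) to the nearest sample index of a trace
time_to_index <- function(tr, t) {
  i <- round((t - tr$t0) * tr$rate) + 1L
  pmin(pmax(as.integer(i), 1L), length(tr$samples))
}

index_to_time <- function(tr, i) tr$t0 + (i - 1) / tr$rate

#' Stimulus protocol descriptor
#'
#' @param kind One of `"none"`, `"step"`, `"sinusoid"`,
#'   `"extracellular_pulse"`, `"high_K"`.
#' @param onset,offset Protocol window in seconds (`offset > onset`).
#' @param amplitude Injected current in pA (step, sinusoid), or a
#'   dimensionless marker (high_K: target drive shift in mV).
#' @param frequency Sinusoid frequency in Hz (required for sinusoid).
#' @param pulse_times Stimulus times in seconds (extracellular pulses).
#' @return An object of class `cacc_protocol`.
#' @export
protocol <- function(kind = c("none", "step", "sinusoid",
                              "extracellular_pulse", "high_K"),
                     onset = 0, offset = 0, amplitude = 0,
                     frequency = NA_real_, pulse_times = numeric()) {
  kind <- match.arg(kind)
  if (kind != "none" && !(offset > onset))
    stop("protocol offset must exceed onset")
  if (kind == "sinusoid" && (!is.finite(frequency) || frequency <= 0))
    stop("sinusoid protocol requires frequency > 0")
  structure(list(kind = kind, onset = onset, offset = offset,
                 amplitude = amplitude, frequency = frequency,
                 pulse_times = as.numeric(pulse_times)),
            class = "cacc_protocol")
}

#' Recording-solution composition
#'
#' Per-ion concentrations in mM plus bath temperature. Used with
#' [nernst_potential()] to derive equilibrium potentials from solution
#' recipes.
#'
#' @param ... Named ion concentrations in mM (e.g. `Cl = 4`, `K = 144`).
#' @param temperature_c Temperature in degrees Celsius (0--40).
#' @return An object of class `cacc_solution`.
#' @export
solution <- function(..., temperature_c = 30) {
  conc <- c(...)
  if (length(conc) && (is.null(names(conc)) || any(names(conc) == "")))
    stop("all concentrations must be named by ion")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (temperature_c < 0 || temperature_c > 40)
    stop("temperature must lie within 0-40 C")
  structure(list(concentrations_mm = conc, temperature_c = temperature_c),
            class = "cacc_solution")
}

#' Session bundle
#'
#' A named collection of simultaneously acquired traces sharing a common
#' time reference, the stimulus protocols applied, optional ground truth
#' (present only for synthetic sessions), and provenance (configuration
#' and seed).
#'
#' @param traces Named list of [trace()] objects with identical `t0`.
#' @param protocols List of [protocol()] objects.
#' @param ground_truth Optional list of ground-truth vectors
#'   (e.g. `ap_times_s`, `psp_times_s`, `psp_amplitudes_mv`,
#'   `event_windows_s`).
#' @param provenance List of free-form provenance fields (config, seed).
#' @return An object of class `cacc_bundle`.
#' @export
bundle <- function(traces, protocols = list(), ground_truth = NULL,
                   provenance = list()) {
  if (!length(traces) || is.null(names(traces)) || any(names(traces) == ""))
    stop("traces must be a non-empty named list")
  if (!all(vapply(traces, is_trace, logical(1))))
    stop("all elements of traces must be cacc_trace objects")
  t0s <- vapply(traces, function(x) x$t0, numeric(1))
  if (diff(range(t0s)) > 1e-12)
    stop("all traces in a bundle must share the same t0")
  structure(list(traces = traces, protocols = protocols,
                 ground_truth = ground_truth, provenance = provenance),
            class = "cacc_bundle")
}

#' @export
print.cacc_bundle <- function(x, ...) {
  cat(sprintf("<cacc_bundle> %d trace(s): %s; %d protocol(s)%s\n",
              length(x$traces), paste(names(x$traces), collapse = ", "),
              length(x$protocols),
              if (!is.null(x$ground_truth)) "; ground truth present" else ""))
  invisible(x)
}

## first trace with a given role, or NULL
bundle_trace <- function(b, role) {
  for (tr in b$traces) if (tr$channel_role == role) return(tr)
  NULL
}
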