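#' Read a voltage trace from CSV
#'
#' Accepts either a two-column file (`time_s,voltage_mV`) from which the
#' sampling rate is inferred, or a single-column file with the rate
#' supplied in `metadata$rate`. Sampling must be uniform: time steps
#' deviating from the median step by more than `1e-6` relative tolerance
#' are rejected.
#'
#' @param path Path to the CSV file.
#' @param metadata Named list of trace metadata passed to [trace()]
#'   (`channel_role`, `rate` for single-column files, `units`,
#'   `ljp_applied`, `label`, `t0`).
#' @return A [trace()].
#' @export
read_trace_csv <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, colClasses = "numeric"),
    warning = function(w) stop("non-numeric rows in ", path),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e)))
  if (any(!vapply(df, is.numeric, logical(1))) || anyNA(df))
    stop("non-numeric rows in ", path)
  role <- metadata$channel_role %||% "WC"
  if (ncol(df) >= 2) {
    tt <- df[[1]]; vv <- df[[2]]
    if (length(tt) < 2) stop("need at least 2 samples to infer rate")
    dt <- diff(tt)
    dt0 <- stats::median(dt)
    if (dt0 <= 0 || any(abs(dt - dt0) > 1e-6 * dt0))
      stop("non-uniform sampling in ", path)
    rate <- 1 / dt0
    t0 <- tt[1]
  } else {
    vv <- df[[1]]
    rate <- metadata$rate
    if (is.null(rate)) stop("single-column CSV requires metadata$rate")
    t0 <- metadata$t0 %||% 0
  }
  trace(vv, rate = rate, channel_role = role, t0 = t0,
        units = metadata$units %||% "mV",
        ljp_applied = metadata$ljp_applied %||% 0,
        label = metadata$label %||% "")
}

#' Write a voltage trace to CSV
#'
#' Writes the `time_s,voltage_mV` layout read back by [read_trace_csv()].
#' Values are written with 17 significant digits so the read/write
#' round-trip reproduces the samples exactly.
#'
#' @param tr A [trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(tr, path) {
  stopifnot(is_trace(tr))
  tt <- trace_times(tr)
  lines <- c("time_s,voltage_mV",
             paste(sprintf("%.17g", tt), sprintf("%.17g", tr$samples),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a session bundle to a JSON container
#'
#' Serializes traces (with their sampling-rate, role, units, LJP and t0
#' attributes), protocols, ground truth and provenance into a single JSON
#' document. Doubles are written at full precision, so the write/read
#' round-trip is bit-lossless.
#'
#' @param b A [bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(b, path) {
  stopifnot(inherits(b, "cacc_bundle"))
  doc <- list(
    format = "cacc-bundle",
    version = 1L,
    traces = lapply(b$traces, function(tr) {
      list(samples = tr$samples, sampling_rate_hz = tr$rate,
           channel_role = tr$channel_role, units = tr$units,
           ljp_applied_mv = tr$ljp_applied, t0_s = tr$t0,
           label = tr$label)
    }),
    protocols = lapply(b$protocols, unclass),
    ground_truth = b$ground_truth,
    provenance = b$provenance)
  # 17 significant digits: exact round-trip for IEEE doubles
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a session bundle from a JSON container
#'
#' @param path Path written by [write_bundle()].
#' @return A [bundle()].
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(doc$traces) || !length(doc$traces))
    stop("not a cacc bundle (missing traces): ", path)
  traces <- lapply(doc$traces, function(d) {
    if (is.null(d$sampling_rate_hz))
      stop("trace missing sampling_rate_hz attribute in ", path)
    trace(unlist(d$samples), rate = d$sampling_rate_hz,
          channel_role = d$channel_role, t0 = d$t0_s %||% 0,
          units = d$units %||% "mV", ljp_applied = d$ljp_applied_mv %||% 0,
          label = d$label %||% "")
  })
  protocols <- lapply(doc$protocols, function(p) {
    protocol(kind = p$kind, onset = p$onset %||% 0, offset = p$offset %||% 0,
             amplitude = p$amplitude %||% 0,
             frequency = p$frequency %||% NA_real_,
             pulse_times = unlist(p$pulse_times) %||% numeric())
  })
  gt <- doc$ground_truth
  if (!is.null(gt)) gt <- lapply(gt, function(x)
    if (is.list(x)) lapply(x, unlist) else unlist(x))
  bundle(traces, protocols = protocols, ground_truth = gt,
         provenance = doc$provenance %||% list())
}
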