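#' Run a pipeline stage from a configuration
#'
#' Single entry point tying the analysis stages together. The
#' configuration (a named list, or a path to a JSON file) names a
#' subcommand and its inputs; results are written as machine-readable
#' files (JSON summary plus CSV tables) into `out_dir`, and every run
#' logs its parameters, seed and configuration hash in the summary.
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{Generate a dual WC/CA session
#'     ([simulate_membrane()] + [simulate_dual()]); writes the bundle
#'     JSON and ground-truth CSVs.}
#'   \item{fit-transfer}{Fit the circuit model to a
#'     `frequency_hz,ratio` CSV ([fit_transfer()]); writes the fit JSON
#'     and a Bode-style model curve CSV.}
#'   \item{detect-events}{Detect APs and sPSPs in a bundle and compute
#'     CA/WC transfer statistics; writes the event CSV and summary.}
#'   \item{detect-network}{Detect field events and MUA in a bundle's
#'     LFP, with peri-event CA change; writes the event CSV and
#'     summary.}
#'   \item{gaba}{Fit reversal potentials from an `amplitude_mv,em_mv`
#'     CSV (optionally with CA columns); writes per-frame fits.}
#'   \item{report}{Summarize a bundle (traces, durations, ground-truth
#'     counts).}
#' }
#'
#' @param config Named list or path to a JSON config file. Must contain
#'   `subcommand`; other fields per subcommand (`duration`, `rate`,
#'   `circuit`, `input`, ...).
#' @param seed Integer seed used for all randomness (required for
#'   `simulate`).
#' @param out_dir Output directory (created if missing).
#' @return The summary list, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = tempfile("cacc_")) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$subcommand))
    stop("config must name a subcommand")
  sub <- config$subcommand
  known <- c("simulate", "fit-transfer", "detect-events", "detect-network",
             "gaba", "report")
  if (!sub %in% known)
    stop("unknown subcommand '", sub, "'; expected one of ",
         paste(known, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  summary <- list(subcommand = sub, seed = seed,
                  config_md5 = unname(tools::md5sum(cfg_path)),
                  package_version = as.character(
                    utils::packageVersion("cacc")))

  get_circuit <- function() {
    cc <- config$circuit %||%
      list(R_seal = 15.4, R_patch = 4.9, C_patch = 0.8, C_elec = 7)
    circuit_params(cc$R_seal, cc$R_patch, cc$C_patch, cc$C_elec)
  }
  need_input <- function() {
    if (is.null(config$input) || !file.exists(config$input))
      stop("missing input file: ", config$input %||% "<unset>")
    config$input
  }

  if (sub == "simulate") {
    nc <- do.call(neuron_config, config$neuron %||% list())
    ns <- do.call(noise_config, config$noise %||% list())
    b <- simulate_membrane(nc, protocol = NULL,
                           duration = config$duration %||% 30,
                           rate = config$rate %||% 5000, seed = seed)
    b <- simulate_dual(b, get_circuit(), ns, seed = seed + 1L)
    write_bundle(b, file.path(out_dir, "bundle.json"))
    gt <- b$ground_truth
    utils::write.csv(data.frame(ap_time_s = gt$ap_times_s),
                     file.path(out_dir, "ground_truth_ap.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(psp_time_s = gt$psp_times_s,
                                psp_amplitude_mv = gt$psp_amplitudes_mv),
                     file.path(out_dir, "ground_truth_psp.csv"),
                     row.names = FALSE)
    summary$n_aps <- length(gt$ap_times_s)
    summary$n_psps <- length(gt$psp_times_s)
  } else if (sub == "fit-transfer") {
    df <- utils::read.csv(need_input())
    fr <- frequency_response(df$frequency_hz, df$ratio)
    fit <- fit_transfer(fr, C_elec_fixed = config$C_elec %||% 7)
    summary$fit <- c(as.list(fit$estimates),
                     list(residual_norm = fit$residual_norm,
                          converged = fit$converged))
    grid <- 10^seq(log10(min(fr$frequencies)), log10(max(fr$frequencies)),
                   length.out = 100)
    utils::write.csv(data.frame(
      frequency_hz = grid,
      model_ratio = amplitude_response(fit$params, grid)),
      file.path(out_dir, "model_bode.csv"), row.names = FALSE)
  } else if (sub == "detect-events") {
    b <- read_bundle(need_input())
    wc <- bundle_trace(b, "WC")
    if (is.null(wc)) stop("bundle lacks a WC trace (WC detection requested)")
    sm_hz <- config$smooth_hz %||% min(1000, wc$rate / 4)
    aps <- detect_aps_wc(wc, smooth_hz = sm_hz)
    psps <- detect_spsps(wc, smooth_hz = sm_hz,
                         ap_times = aps$peak_time_s)
    events <- rbind(aps, psps)
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    summary$n_aps <- nrow(aps); summary$n_psps <- nrow(psps)
    ca <- bundle_trace(b, "CA")
    if (!is.null(ca) && nrow(psps)) {
      pt <- pair_and_transfer(psps, ca,
                              max_lag_ms = config$max_lag_ms %||% 5,
                              smooth_hz = sm_hz)
      summary$psp_transfer <- pt$summary
      utils::write.csv(pt$pairs, file.path(out_dir, "paired_events.csv"),
                       row.names = FALSE)
    }
  } else if (sub == "detect-network") {
    b <- read_bundle(need_input())
    lfp <- bundle_trace(b, "LFP")
    if (is.null(lfp)) stop("bundle lacks an LFP trace")
    pol <- config$polarity %||% "negative"
    ev <- detect_field_events(lfp, polarity = pol)
    ca <- bundle_trace(b, "CA")
    if (!is.null(ca) && nrow(ev))
      ev$em_change_mv <- vapply(seq_len(nrow(ev)), function(k)
        as.numeric(event_em_change(ca, ev[k, ])), numeric(1))
    utils::write.csv(ev, file.path(out_dir, "network_events.csv"),
                     row.names = FALSE)
    summary$n_events <- nrow(ev)
  } else if (sub == "gaba") {
    df <- utils::read.csv(need_input())
    fit_wc <- fit_amplitude_vs_em(df$amplitude_mv, df$em_mv, frame = "WC")
    summary$fit_wc <- unclass(fit_wc)
    if (!is.null(df$ca_amplitude_mv)) {
      summary$fit_ca_reframed <-
        unclass(reframe_ca_to_wc(df$ca_amplitude_mv, df$em_mv))
    }
  } else if (sub == "report") {
    b <- read_bundle(need_input())
    summary$traces <- lapply(b$traces, function(tr)
      list(role = tr$channel_role, n = length(tr$samples), rate = tr$rate,
           duration_s = trace_duration(tr), units = tr$units))
    if (!is.null(b$ground_truth))
      summary$ground_truth_counts <- lapply(b$ground_truth, length)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(summary)
}
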