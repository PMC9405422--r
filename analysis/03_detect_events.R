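#!/usr/bin/env Rscript
# Detect APs and spontaneous PSPs in the simulated dual session, measure
# their amplitudes and kinetics in both configurations, and summarize
# the CA/WC transfer statistics (amplitude ratio, half-duration change,
# amplitude-to-noise ratios, dominant frequencies).

suppressPackageStartupMessages(library(cacc))
if (!file.exists("results/dual_session.json"))
  stop("run analysis/01_simulate.R first")
b <- read_bundle("results/dual_session.json")
wc <- b$traces$WC; ca <- b$traces$CA

aps <- detect_aps_wc(wc)
caps <- detect_aps_ca(ca, smooth_hz = 300)
psps <- detect_spsps(wc, ap_times = aps$peak_time_s)
events <- rbind(aps, psps)
utils::write.csv(events, "results/events_wc.csv", row.names = FALSE)

pt <- pair_and_transfer(psps, ca, max_lag_ms = 20, smooth_hz = 300)
utils::write.csv(pt$pairs, "results/paired_psps.csv", row.names = FALSE)

noise_wc <- quietest_interval(wc, 1)$sd
noise_ca <- quietest_interval(ca, 1)$sd
anr_wc <- amplitude_noise_ratio(psps, noise_wc)
anr_ca <- amplitude_noise_ratio(
  data.frame(amplitude_mv = pt$pairs$ca_amplitude_mv), noise_ca)

hw_ap <- stats::median(aps$half_duration_ms)
hw_psp <- stats::median(psps$half_duration_ms)

summ <- list(
  n_aps_wc = nrow(aps), n_aps_ca = nrow(caps), n_psps = nrow(psps),
  ap_amplitude_wc_mv = stats::median(aps$amplitude_mv),
  ap_dominant_freq_hz = dominant_frequency(hw_ap),
  psp_dominant_freq_hz = dominant_frequency(hw_psp),
  psp_transfer = pt$summary,
  amplitude_noise_ratio = list(wc = anr_wc, ca = anr_ca,
                               wc_over_ca = anr_wc / anr_ca))
jsonlite::write_json(summ, "results/event_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

cat(sprintf("APs: %d in WC, %d in CA; PSPs: %d (from WC)\n",
            nrow(aps), nrow(caps), nrow(psps)))
cat(sprintf("PSP CA/WC amplitude ratio: median %.2f [%.2f %.2f] (n = %d)\n",
            pt$summary$ratio_median, pt$summary$ratio_iqr[1],
            pt$summary$ratio_iqr[2], pt$summary$n))
cat(sprintf("dominant frequencies: AP %.0f Hz, PSP %.1f Hz\n",
            dominant_frequency(hw_ap), dominant_frequency(hw_psp)))
cat(sprintf("amplitude-to-noise: WC %.1f, CA %.1f (%.1f-fold lower in CA)\n",
            anr_wc, anr_ca, anr_wc / anr_ca))
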