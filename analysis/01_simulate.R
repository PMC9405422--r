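#!/usr/bin/env Rscript
# Generate the study's synthetic sessions: a dual WC/CA recording with
# spontaneous PSPs and evoked APs from a neuron with group-median patch
# circuit parameters. Writes the session bundle and ground-truth tables
# used by the downstream detection scripts.

suppressPackageStartupMessages(library(cacc))
dir.create("results", showWarnings = FALSE)

seed <- 20260923L
circuit <- circuit_params(R_seal = 15.4, R_patch = 4.9, C_patch = 0.8,
                          C_elec = 7)
nc <- neuron_config(ap_times = seq(5, 115, by = 10), psp_rate_hz = 1,
                    ap_threshold = 100)

b <- simulate_membrane(nc, duration = 120, rate = 5000, seed = seed)
b <- simulate_dual(b, circuit, noise_config(), seed = seed + 1L)

write_bundle(b, "results/dual_session.json")
utils::write.csv(data.frame(ap_time_s = b$ground_truth$ap_times_s),
                 "results/ground_truth_ap.csv", row.names = FALSE)
utils::write.csv(data.frame(psp_time_s = b$ground_truth$psp_times_s,
                            psp_amplitude_mv = b$ground_truth$psp_amplitudes_mv),
                 "results/ground_truth_psp.csv", row.names = FALSE)

cat(sprintf("dual session: %.0f s at %g Hz; %d APs, %d PSPs inserted\n",
            trace_duration(b$traces$WC), b$traces$WC$rate,
            length(b$ground_truth$ap_times_s),
            length(b$ground_truth$psp_times_s)))
cat(sprintf("quiet-segment SD: WC %.2f mV, CA %.2f mV (ratio %.2f)\n",
            quietest_interval(b$traces$WC, 1)$sd,
            quietest_interval(b$traces$CA, 1)$sd,
            quietest_interval(b$traces$CA, 1)$sd /
              quietest_interval(b$traces$WC, 1)$sd))
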