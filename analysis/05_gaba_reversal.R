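#!/usr/bin/env Rscript
# Estimate the GABA reversal potential and driving force from evoked
# responses at multiple commanded membrane potentials, in the WC frame,
# the native CA frame, and the CA frame reframed to WC potentials. The
# native CA fit is biased by the seal-shunt depolarization of the CA
# baseline; reframing removes the bias while the amplitude attenuation
# (smaller apparent conductance) remains.

suppressPackageStartupMessages(library(cacc))
dir.create("results", showWarnings = FALSE)

circuit <- circuit_params(R_seal = 15.4, R_patch = 4.9, C_patch = 0.8,
                          C_elec = 7)
nc <- neuron_config(E_GABA = -60, gaba_g_scale = 0.1)
s <- simulate_gaba_experiment(nc, em_levels = seq(-90, -50, by = 10),
                              n_stim = 10, circuit = circuit,
                              noise = noise_config(), seed = 20260925L)
an <- analyze_gaba_session(s)

tab <- data.frame(em_wc_mv = s$em_wc, em_ca_mv = round(s$em_ca, 1),
                  amp_wc_mv = round(an$amp_wc, 2),
                  amp_ca_mv = round(an$amp_ca, 2),
                  polarity_wc = classify_polarity(an$amp_wc),
                  polarity_ca = classify_polarity(an$amp_ca),
                  df_gaba_mv = round(an$df_gaba_wc, 1))
utils::write.csv(tab, "results/gaba_sweep.csv", row.names = FALSE)
jsonlite::write_json(
  list(fit_wc = unclass(an$fit_wc), fit_ca = unclass(an$fit_ca),
       fit_ca_reframed = unclass(an$fit_ca_reframed),
       true_E_GABA = s$true_E_GABA),
  "results/gaba_fits.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

print(tab)
cat(sprintf("\nE_GABA (true %g mV):\n", s$true_E_GABA))
cat(sprintf("  WC frame            %.1f mV (slope %.3f)\n",
            an$fit_wc$E_GABA, an$fit_wc$slope))
cat(sprintf("  CA frame (native)   %.1f mV  <- biased by the seal shunt\n",
            an$fit_ca$E_GABA))
cat(sprintf("  CA reframed to WC   %.1f mV (slope %.3f)\n",
            an$fit_ca_reframed$E_GABA, an$fit_ca_reframed$slope))
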