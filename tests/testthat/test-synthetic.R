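# synthetic generator: determinism, ground truth, physical contracts

test_that("membrane simulation is deterministic and obeys passive physics", {
  nc <- neuron_config(psp_rate_hz = 0, ap_threshold = 100)
  b1 <- simulate_membrane(nc, duration = 2, rate = 2000, seed = 1)
  b2 <- simulate_membrane(nc, duration = 2, rate = 2000, seed = 1)
  expect_identical(b1$traces$WC$samples, b2$traces$WC$samples)
  # zero rates, no protocol -> constant resting potential
  expect_true(all(abs(b1$traces$WC$samples - nc$E_rest) < 1e-9))
  # -50 pA step on 100 MOhm -> -5 mV steady-state deflection (Ohm's law)
  bs <- simulate_membrane(neuron_config(R_input = 100, psp_rate_hz = 0,
                                        ap_threshold = 100),
                          protocol(kind = "step", onset = 1, offset = 3,
                                   amplitude = -50),
                          duration = 4, rate = 2000, seed = 2)
  sh <- steady_state_shift(bs$traces$WC, c(0, 0.9), c(2.5, 2.9))
  expect_equal(sh, -5, tolerance = 0.01)
  # high-K ramp of +15 mV shifts the steady state by +15 mV
  bk <- simulate_membrane(neuron_config(psp_rate_hz = 0, ap_threshold = 100),
                          protocol(kind = "high_K", onset = 1, offset = 5,
                                   amplitude = 15),
                          duration = 8, rate = 2000, seed = 3)
  expect_equal(steady_state_shift(bk$traces$WC, c(0, 0.9), c(6, 7.9)), 15,
               tolerance = 0.02)
  expect_error(simulate_membrane(nc, duration = 2, rate = 2000), "seed")
  expect_error(neuron_config(R_input = -1), "positive")
})

test_that("ground truth lists every inserted event exactly once", {
  nc <- neuron_config(psp_rate_hz = 3, ap_times = c(0.5, 1.5, 2.5),
                      ap_threshold = 100)
  b <- simulate_membrane(nc, duration = 3, rate = 5000, seed = 5)
  gt <- b$ground_truth
  expect_equal(length(gt$ap_times_s), 3L)
  expect_equal(length(gt$psp_times_s), length(gt$psp_amplitudes_mv))
  expect_false(any(duplicated(gt$psp_times_s)))
  expect_true(all(diff(gt$psp_times_s) >= 0))
  expect_true(all(gt$psp_amplitudes_mv > 0))
})

test_that("dual simulation filters, offsets and scales noise as configured", {
  # ideal circuit (dc = hf = 1), no noise -> CA == WC
  ideal <- circuit_params(1e9, 1e-6, 1, 1e-9)
  nc <- neuron_config(psp_rate_hz = 2, ap_threshold = 100)
  b <- simulate_membrane(nc, duration = 2, rate = 2000, seed = 7)
  quiet <- noise_config(wc_sd = 0, telegraph_rate_hz = 0,
                        telegraph_step_mv = 0)
  bi <- simulate_dual(b, ideal, quiet, seed = 8)
  expect_equal(bi$traces$CA$samples, bi$traces$WC$samples, tolerance = 1e-6)
  # constant -80 mV through the group-median circuit -> about -60.7 mV
  bc <- simulate_membrane(neuron_config(E_rest = -80, psp_rate_hz = 0,
                                        ap_threshold = 100),
                          duration = 1, rate = 2000, seed = 9)
  bc <- simulate_dual(bc, group_median_cell(), quiet, seed = 10)
  expect_equal(mean(bc$traces$CA$samples), -80 * dc_transfer(group_median_cell()),
               tolerance = 1e-3)
  expect_equal(mean(bc$traces$CA$samples), -60.7, tolerance = 0.01)
  # default noise: SD(CA)/SD(WC) ~ 2 over quiet segments
  bq <- simulate_membrane(neuron_config(psp_rate_hz = 0.2,
                                        ap_threshold = 100),
                          duration = 30, rate = 2000, seed = 11)
  bq <- simulate_dual(bq, group_median_cell(), noise_config(), seed = 12)
  r <- quietest_interval(bq$traces$CA, 1)$sd /
    quietest_interval(bq$traces$WC, 1)$sd
  expect_gt(r, 2 * 0.8); expect_lt(r, 2 * 1.2)
  # determinism under seed
  bq2 <- simulate_dual(simulate_membrane(neuron_config(psp_rate_hz = 0.2,
                                                       ap_threshold = 100),
                                         duration = 30, rate = 2000,
                                         seed = 11),
                       group_median_cell(), noise_config(), seed = 12)
  expect_identical(bq$traces$CA$samples, bq2$traces$CA$samples)
  expect_error(simulate_dual(bundle(list(LFP = trace(1:10, 10, "LFP"))),
                             group_median_cell(), noise_config(), seed = 1),
               "lacks a WC")
})

test_that("network sessions respect rate, polarity and ground truth", {
  cfgGDP <- network_config("GDP", rate_hz = 0.2)
  # zero event rate -> noise-only LFP, empty ground truth
  b0 <- simulate_network_session(network_config("GDP", rate_hz = 0),
                                 group_median_cell(), noise_config(),
                                 duration = 20, rate = 2000, seed = 21)
  expect_equal(length(b0$ground_truth$event_times_s), 0L)
  expect_lt(sd(b0$traces$LFP$samples), 3 * noise_config()$lfp_pink_sd)
  # GDP session: negative field deflections at event times
  bg <- simulate_network_session(cfgGDP, group_median_cell(), noise_config(),
                                 duration = 60, rate = 2000, seed = 22)
  ev <- bg$ground_truth$event_times_s
  expect_gt(length(ev), 2)
  lfp_at <- bg$traces$LFP$samples[round(ev * 2000) + 1]
  expect_true(all(lfp_at < 0))
  # hyperpolarizing SWR -> negative peri-event CA average
  cfgSWR <- network_config("SWR", rate_hz = 0.2, em_deflection_mv = -1.5)
  bs <- simulate_network_session(cfgSWR, group_median_cell(), noise_config(),
                                 duration = 60, rate = 2000, seed = 23)
  evs <- data.frame(ref_time_s = bs$ground_truth$event_times_s)
  pe <- peri_event(bs$traces$CA, evs, window = 0.5)
  mid <- abs(pe$time_s) < 0.05
  expect_lt(mean(pe$mean[mid]), 0)
})

test_that("GABA sweep generator reproduces driving-force linearity", {
  p <- group_median_cell()
  nc <- neuron_config(E_GABA = -60, gaba_g_scale = 0.1)
  quiet <- noise_config(wc_sd = 0, telegraph_rate_hz = 0,
                        telegraph_step_mv = 0)
  s <- simulate_gaba_experiment(nc, em_levels = c(-80, -70, -60, -50, -40),
                                n_stim = 3, circuit = p, noise = quiet,
                                seed = 31, amp_noise_sd = 0)
  # Em = E_GABA -> zero evoked amplitude; +/-10 mV -> symmetric polarity
  amps <- vapply(s$wc_avg, evoked_amplitude, numeric(1),
                 stim_time = s$stim_time_s)
  expect_lt(abs(amps[3]), 0.05)
  expect_gt(amps[2], 0); expect_lt(amps[4], 0)
  expect_equal(amps[2], -amps[4], tolerance = 0.02)
  expect_equal(unname(amps[1]), 0.1 * 20, tolerance = 0.05)
  # CA/WC amplitude ratio ~ amplitude response at the PSP's dominant freq
  amps_ca <- vapply(s$ca_avg, evoked_amplitude, numeric(1),
                    stim_time = s$stim_time_s)
  ratio <- amps_ca[1] / amps[1]
  # evoked kernel half-width ~ 45 ms -> dominant frequency ~ 7.4 Hz
  ar <- amplitude_response(p, dominant_frequency(45))
  expect_equal(ratio, ar, tolerance = 0.15 * ar + 0.15)
  expect_error(simulate_gaba_experiment(nc, numeric(), circuit = p, seed = 1),
               "non-empty")
})
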