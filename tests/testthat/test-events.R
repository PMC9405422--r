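# AP/PSP detection, onset and amplitude measurement, transfer pairing

test_that("event onset finds the latest derivative crossing before peak", {
  rate <- 10000
  # linear ramp at 1 mV/ms starting at t = 0.5 s, 20 ms long
  tt <- seq(0, 1, by = 1 / rate)
  v <- ifelse(tt < 0.5, 0, pmin((tt - 0.5) * 1000, 20))
  tr <- trace(v, rate, "WC")
  on <- event_onset(tr, peak_time = 0.52, derivative_threshold = 0.1)
  expect_false(on$flagged)
  expect_equal(on$onset, 0.5, tolerance = 1e-3)
  # flat-then-jump pathological trace within horizon -> flagged fallback
  v2 <- c(rep(0, 9999), rep(10, 1))
  tr2 <- trace(c(v2, rep(10, 2)), rate, "WC")
  on2 <- event_onset(tr2, peak_time = 0.9999, derivative_threshold = 1e9)
  expect_true(on2$flagged)
  expect_equal(on2$onset, 0.9999 - 0.1, tolerance = 1e-6)
  expect_error(event_onset(tr, 5, 1), "outside")
})

test_that("measure_event implements the 1-5 ms baseline and half-width", {
  rate <- 10000
  # triangle of height 10 mV, base 20 ms, on a flat baseline
  tt <- seq(0, 1, by = 1 / rate)
  v <- pmax(0, 10 * (1 - abs(tt - 0.5) / 0.01))
  tr <- trace(v - 70, rate, "WC")
  ev <- measure_event(tr, onset = 0.49, peak_time = 0.5)
  expect_equal(ev$amplitude_mv, 10, tolerance = 1e-6)
  expect_equal(ev$half_duration_ms, 10, tolerance = 0.05)  # half the base
  expect_equal(ev$onset_to_peak_ms, 10, tolerance = 1e-6)
  expect_false(ev$flagged)
  # sloped baseline of 0.1 mV/ms: bias = slope x (baseline-centre to
  # peak distance); for a 2-ms-to-peak event that is 0.1 x 5 = 0.5 mV
  vfast <- pmax(0, 10 * (1 - abs(tt - 0.5) / 0.002)) + 0.1 * (tt * 1000)
  evs <- measure_event(trace(vfast, rate, "WC"), onset = 0.498,
                       peak_time = 0.5)
  expect_lt(abs(evs$amplitude_mv - 10), 0.6)
  expect_equal(evs$amplitude_mv - 10, 0.5, tolerance = 0.05)
  expect_error(measure_event(tr, 0.5, 0.4), "precede")
})

test_that("WC AP detection recovers template spikes at exact times", {
  nc <- neuron_config(ap_times = seq(0.5, 9.5, by = 1), psp_rate_hz = 0,
                      ap_threshold = 100)
  b <- simulate_membrane(nc, duration = 10, rate = 10000, seed = 41)
  b <- simulate_dual(b, example_cell(), noise_config(), seed = 42)
  aps <- detect_aps_wc(b$traces$WC)
  expect_equal(nrow(aps), 10L)
  expect_lt(max(abs(sort(aps$peak_time_s) - b$ground_truth$ap_times_s)),
            2e-4)
  # amplitude ~ template amplitude, half-duration ~ template half-width
  expect_equal(median(aps$amplitude_mv), 100, tolerance = 0.05)
  expect_equal(median(aps$half_duration_ms), 1.4, tolerance = 0.15)
  # flat trace -> empty list
  expect_equal(nrow(detect_aps_wc(trace(rep(-80, 1000), 1000, "WC"))), 0L)
  # sub-threshold excursion (39 mV above rest) is not detected
  v <- rep(-80, 10000); v[5000:5050] <- -80 + 39
  expect_equal(nrow(detect_aps_wc(trace(v, 10000, "WC"), resting = -80)), 0L)
})

test_that("CA AP detection recovers filtered spikes; noise-only FP rate low", {
  nc <- neuron_config(ap_times = seq(0.5, 19.5, by = 1), psp_rate_hz = 0,
                      ap_threshold = 100)
  b <- simulate_membrane(nc, duration = 20, rate = 10000, seed = 43)
  quiet_tel <- noise_config(telegraph_rate_hz = 0, telegraph_step_mv = 0)
  b <- simulate_dual(b, group_median_cell(), quiet_tel, seed = 44)
  caps <- detect_aps_ca(b$traces$CA, smooth_hz = 500)
  rec <- match_fraction(b$ground_truth$ap_times_s, caps$peak_time_s,
                        tol_s = 5e-3)
  expect_gte(rec, 0.9)
  # CA spikes are attenuated versus the 100 mV template
  expect_lt(median(caps$amplitude_mv), 50)
  # pure Gaussian noise, 0.2 mV SD at 50 kHz, 1 kHz smoothing:
  # false-positive rate below 0.1 Hz
  set.seed(45)
  noise_tr <- trace(rnorm(50000 * 10, 0, 0.2), 50000, "CA")
  fps <- detect_aps_ca(noise_tr, smooth_hz = 1000)
  expect_lt(nrow(fps) / 10, 0.1)
  # a single inserted CA-like waveform gives exactly one event
  v <- rep(0, 20000)
  v[5000:5300] <- 13 * sin(seq(0, pi, length.out = 301))
  one <- detect_aps_ca(trace(v, 10000, "CA"), smooth_hz = 1000)
  expect_equal(nrow(one), 1L)
})

test_that("sPSP detection recovers fast-rising events and rejects slow ones", {
  nc <- neuron_config(psp_rate_hz = 1, ap_threshold = 100)
  b <- simulate_membrane(nc, duration = 60, rate = 5000, seed = 46)
  b <- simulate_dual(b, group_median_cell(), noise_config(), seed = 47)
  psps <- detect_spsps(b$traces$WC)
  gt <- b$ground_truth$psp_times_s
  expect_gte(match_fraction(gt, psps$onset_s, 0.015), 0.85)
  # PSPs rising at ~0.5 mV/ms stay below the 1 mV/ms threshold
  slow <- neuron_config(psp_rate_hz = 1, psp_rise_ms = 8, psp_decay_ms = 60,
                        psp_amp_median_mv = 2, psp_amp_sigma = 0.01,
                        ap_threshold = 100)
  bs <- simulate_membrane(slow, duration = 30, rate = 5000, seed = 48)
  bs <- simulate_dual(bs, group_median_cell(), noise_config(), seed = 49)
  expect_lt(nrow(detect_spsps(bs$traces$WC)),
            0.2 * length(bs$ground_truth$psp_times_s) + 1)
  # quiet trace -> empty
  expect_equal(nrow(detect_spsps(trace(rep(-80, 5000), 5000, "WC"))), 0L)
})

test_that("evoked amplitude is the signed post-stimulus deflection", {
  rate <- 5000
  tt <- seq(0, 1, by = 1 / rate)
  kern <- 1.5 * exp(-(tt - 0.55)^2 / (2 * 0.02^2))
  tr <- trace(-70 + kern, rate, "WC")
  expect_equal(evoked_amplitude(tr, 0.5), 1.5, tolerance = 0.01)
  trn <- trace(-70 - 2 * exp(-(tt - 0.55)^2 / (2 * 0.02^2)), rate, "WC")
  expect_equal(evoked_amplitude(trn, 0.5), -2, tolerance = 0.01)
  flat <- trace(rep(-70, length(tt)), rate, "WC")
  expect_equal(evoked_amplitude(flat, 0.5), 0, tolerance = 1e-9)
  expect_error(evoked_amplitude(tr, 0.05), "bounds")
})

test_that("dominant frequency inverts the 1/3-period half-width rule", {
  expect_equal(dominant_frequency(1.389), 240, tolerance = 1e-3)
  expect_equal(dominant_frequency(85.5), 3.9, tolerance = 1e-3)
  expect_equal(dominant_frequency(1000 / 3), 1)
  # exact identity f * 3 * half_width = 1 (half-width in seconds)
  hw <- c(0.5, 2, 17, 120)
  expect_equal(dominant_frequency(hw) * 3 * hw / 1000, rep(1, 4))
  expect_error(dominant_frequency(0), "positive")
})

test_that("amplitude-to-noise ratio and its degenerate cases", {
  ev <- data.frame(amplitude_mv = c(2, 2, 2))
  expect_equal(amplitude_noise_ratio(ev, 1), 2)
  expect_equal(amplitude_noise_ratio(ev, 1e6), 2e-6)
  expect_error(amplitude_noise_ratio(ev[0, , drop = FALSE], 1), "no events")
  expect_error(amplitude_noise_ratio(ev, 0), "positive")
})

test_that("pairing: identical traces give unit transfer, noise decorrelates", {
  nc <- neuron_config(psp_rate_hz = 1, ap_threshold = 100)
  b <- simulate_membrane(nc, duration = 30, rate = 5000, seed = 50)
  wc_noisy <- b$traces$WC
  wc_noisy$samples <- wc_noisy$samples + rnorm(length(wc_noisy), 0, 0.1)
  psps <- detect_spsps(wc_noisy)
  same <- wc_noisy; same$channel_role <- "CA"
  pt <- pair_and_transfer(psps, same, max_lag_ms = 1, smooth_hz = 300)
  expect_equal(pt$summary$ratio_median, 1, tolerance = 0.05)
  expect_equal(pt$summary$slope, 1, tolerance = 0.05)
  expect_gt(pt$summary$pearson_r, 0.95)
  # CA trace of pure noise: correlation near zero
  set.seed(51)
  noise_ca <- trace(rnorm(length(wc_noisy), 0, 0.5), 5000, "CA")
  ptn <- pair_and_transfer(psps, noise_ca, max_lag_ms = 5, smooth_hz = 300)
  expect_lt(abs(ptn$summary$pearson_r), 0.5)
})

test_that("paired CA events are attenuated and broadened versus WC", {
  p <- group_median_cell()
  nc <- neuron_config(psp_rate_hz = 1, ap_threshold = 100)
  b <- simulate_membrane(nc, duration = 120, rate = 5000, seed = 52)
  b <- simulate_dual(b, p, noise_config(), seed = 53)
  psps <- detect_spsps(b$traces$WC)
  pt <- pair_and_transfer(psps, b$traces$CA, max_lag_ms = 20,
                          smooth_hz = 300)
  expect_gt(pt$summary$n, 30)
  # amplitudes systematically smaller in CA (sign test)
  n_down <- sum(pt$pairs$ratio < 1)
  expect_lt(binom.test(n_down, nrow(pt$pairs),
                       alternative = "greater")$p.value, 0.01)
  # half-durations systematically longer in CA
  n_broader <- sum(pt$pairs$ca_half_duration_ms > pt$pairs$wc_half_duration_ms)
  expect_lt(binom.test(n_broader, nrow(pt$pairs),
                       alternative = "greater")$p.value, 0.01)
  # median ratio consistent with AR at the measured dominant frequency
  f_dom <- dominant_frequency(median(pt$pairs$wc_half_duration_ms))
  expect_equal(pt$summary$ratio_median, amplitude_response(p, f_dom),
               tolerance = 0.35)
  # WC amplitude-to-noise ratio exceeds CA's (lower CA signal-to-noise)
  anr_wc <- amplitude_noise_ratio(
    data.frame(amplitude_mv = pt$pairs$wc_amplitude_mv),
    quietest_interval(b$traces$WC, 1)$sd)
  anr_ca <- amplitude_noise_ratio(
    data.frame(amplitude_mv = pt$pairs$ca_amplitude_mv),
    quietest_interval(b$traces$CA, 1)$sd)
  expect_gt(anr_wc / anr_ca, 1)
})
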