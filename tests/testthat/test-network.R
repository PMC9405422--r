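# field-event detection (GDP/SWR), MUA, peri-event analysis

test_that("GDP detection recovers ground truth with few false positives", {
  p <- group_median_cell()
  b <- simulate_network_session(network_config("GDP", rate_hz = 0.2), p,
                                noise_config(), duration = 120,
                                rate = 10000, seed = 61)
  gt <- b$ground_truth$event_times_s
  ev <- detect_field_events(b$traces$LFP, "negative")
  expect_gte(match_fraction(gt, ev$ref_time_s, tol_s = 0.1), 0.95)
  expect_lte(length(false_positives(gt, ev$ref_time_s, tol_s = 0.1)),
             0.05 * length(gt))
  expect_true(all(ev$field_amplitude < 0))
  # polarity selectivity: positive detection on a negative-event session
  evp <- detect_field_events(b$traces$LFP, "positive")
  expect_lte(nrow(evp), 1)
  # threshold is SD-relative: doubling all amplitudes changes nothing
  lfp2 <- b$traces$LFP; lfp2$samples <- 2 * lfp2$samples
  ev2 <- detect_field_events(lfp2, "negative")
  expect_equal(ev2$ref_time_s, ev$ref_time_s)
  # noise-only trace: essentially no events (3-SD excursions of 1-100 Hz
  # pink noise lasting long enough to register are rare)
  b0 <- simulate_network_session(network_config("GDP", rate_hz = 0), p,
                                 noise_config(), duration = 120,
                                 rate = 10000, seed = 62)
  ev0 <- detect_field_events(b0$traces$LFP, "negative")
  expect_lt(nrow(ev0) / 120, 0.5)
})

test_that("MUA detection recovers spikes; FP rate follows crossing theory", {
  p <- group_median_cell()
  b <- simulate_network_session(network_config("GDP", rate_hz = 0.2), p,
                                noise_config(), duration = 120,
                                rate = 10000, seed = 63)
  gm <- b$ground_truth$mua_times_s
  mua <- detect_mua(b$traces$LFP)
  expect_gte(match_fraction(gm, mua, tol_s = 2e-3), 0.9)
  # doubling the spike amplitude does not decrease recovery
  cfg2 <- network_config("GDP", rate_hz = 0.2, mua_amplitude = 0.8)
  b2 <- simulate_network_session(cfg2, p, noise_config(), duration = 120,
                                 rate = 10000, seed = 63)
  mua2 <- detect_mua(b2$traces$LFP)
  expect_gte(match_fraction(b2$ground_truth$mua_times_s, mua2, 2e-3),
             match_fraction(gm, mua, 2e-3) - 1e-9)
  # spike-free Gaussian band noise: the -3 sigma crossing rate of the
  # 300-2500 Hz band is set by Rice's formula nu = f_rms * exp(-9/2);
  # the observed FP rate should agree with it within a factor of 2,
  # and a 4.5-SD threshold pushes the rate below 0.5 Hz
  b0 <- simulate_network_session(network_config("GDP", rate_hz = 0), p,
                                 noise_config(), duration = 120,
                                 rate = 10000, seed = 64)
  filt <- bandpass(b0$traces$LFP, 300, 2500)
  f_rms <- sqrt(sum(diff(filt$samples)^2) /
                  sum(filt$samples^2)) * filt$rate / (2 * pi)
  rice_rate <- f_rms * exp(-9 / 2)
  fp3 <- length(detect_mua(b0$traces$LFP)) / 120
  expect_gt(fp3, rice_rate / 2); expect_lt(fp3, rice_rate * 2)
  fp45 <- length(detect_mua(b0$traces$LFP, threshold_sd = 4.5)) / 120
  expect_lt(fp45, 0.5)
  # rate too low for the upper band corner -> error
  expect_error(detect_mua(trace(rnorm(5000), 4000, "LFP")), "too low")
})

test_that("peri-event averages recover the filtered Em deflection", {
  p <- group_median_cell()
  # AP-free session isolates the slow-deflection transfer
  cfg <- network_config("GDP", rate_hz = 0.2, ap_mean_count = 0)
  b <- simulate_network_session(cfg, p, noise_config(), duration = 120,
                                rate = 10000, seed = 65)
  ev <- detect_field_events(b$traces$LFP, "negative")
  pe <- peri_event(b$traces$CA, ev, window = 1)
  expect_equal(length(pe$time_s), length(pe$mean))
  expect_equal(pe$time_s[1], -1); expect_equal(pe$time_s[length(pe$time_s)], 1)
  # peak ~ 16 mV x AR at the GDP dominant frequency (~3 Hz)
  pred <- 16 * amplitude_response(p, dominant_frequency(110))
  expect_equal(max(pe$mean), pred, tolerance = 0.15)
  # em_change per event matches the same prediction
  ch <- vapply(seq_len(nrow(ev)), function(k)
    as.numeric(event_em_change(b$traces$CA, ev[k, ])), numeric(1))
  expect_equal(median(ch), pred, tolerance = 0.15)
  expect_true(all(ch > 0))
})

test_that("event-locked APs peak at the field reference time", {
  p <- group_median_cell()
  b <- simulate_network_session(network_config("GDP", rate_hz = 0.2), p,
                                noise_config(), duration = 120,
                                rate = 10000, seed = 66)
  ev <- detect_field_events(b$traces$LFP, "negative")
  hist_ap <- peri_event(b$ground_truth$ap_times_s, ev, window = 1,
                        bin_ms = 50)
  peak_bin <- hist_ap$time_s[which.max(hist_ap$counts)]
  expect_lte(abs(peak_bin), 0.05 + 1e-9)  # within one 50 ms bin of zero
})

test_that("SWR responses split by configured Em-deflection sign", {
  p <- group_median_cell()
  signs <- c(1.5, 1.5, -1.5, -1.5, 1.5)  # Em deflection per simulated cell
  got <- vapply(seq_along(signs), function(k) {
    cfg <- network_config("SWR", rate_hz = 0.25, em_deflection_mv = signs[k],
                          ap_mean_count = 0)
    b <- simulate_network_session(cfg, p, noise_config(), duration = 60,
                                  rate = 10000, seed = 70 + k)
    ev <- detect_field_events(b$traces$LFP, "positive")
    ch <- vapply(seq_len(nrow(ev)), function(j)
      as.numeric(event_em_change(b$traces$CA, ev[j, ])), numeric(1))
    median(ch)
  }, numeric(1))
  expect_identical(sign(got), sign(signs))
  # depolarizing and hyperpolarizing responses of ~1.5 mV magnitude
  expect_equal(abs(got), rep(1.5 * amplitude_response(p,
                                                      dominant_frequency(50)),
                             5), tolerance = 0.5)
})

test_that("peri-event input validation and single-event behavior", {
  tr <- trace(rep(0, 10000), 1000, "CA")
  ev1 <- data.frame(ref_time_s = 5)
  pe <- peri_event(tr, ev1, window = 1)
  expect_equal(pe$n_events, 1L)
  expect_true(all(pe$mean == 0))
  expect_error(peri_event(tr, ev1[0, , drop = FALSE], window = 1),
               "no events")
  expect_error(peri_event(tr, data.frame(ref_time_s = 0.0001), window = 1),
               "edges")
})
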