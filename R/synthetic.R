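#' Synthetic neuron configuration
#'
#' Parameters of the single-compartment leaky integrator used to emulate
#' whole-cell membrane-potential recordings: passive properties, an
#' action-potential template inserted at threshold crossings (the
#' analyses here concern waveform transfer, not spike generation, so
#' template insertion gives exact ground truth), Poisson
#' difference-of-exponentials PSPs, and GABAergic parameters for evoked
#' responses (PSP amplitude proportional to driving force).
#'
#' @param E_rest Resting potential, mV.
#' @param R_input Input resistance, MOhm.
#' @param C_m Membrane capacitance, pF.
#' @param ap_threshold Spike threshold, mV.
#' @param ap_amplitude_mv AP template amplitude above baseline, mV.
#' @param ap_half_width_ms AP template width at half amplitude, ms
#'   (default 1.4 ms, a dominant frequency of ~240 Hz).
#' @param ap_times Optional fixed AP insertion times (s); inserted
#'   unconditionally in addition to threshold-triggered spikes.
#' @param psp_rate_hz Poisson rate of spontaneous PSPs, Hz.
#' @param psp_amp_median_mv,psp_amp_sigma Log-normal sPSP amplitude
#'   distribution (median in mV, log-SD).
#' @param psp_rise_ms,psp_decay_ms PSP kinetics (difference of
#'   exponentials), ms.
#' @param E_GABA GABA-A reversal potential, mV.
#' @param gaba_g_scale Evoked GABA-PSP amplitude per mV of driving
#'   force (dimensionless conductance proxy).
#' @return An object of class `cacc_neuron`.
#' @export
neuron_config <- function(E_rest = -81.3, R_input = 100, C_m = 150,
                          ap_threshold = -45, ap_amplitude_mv = 100,
                          ap_half_width_ms = 1.4, ap_times = NULL,
                          psp_rate_hz = 1, psp_amp_median_mv = 3,
                          psp_amp_sigma = 0.3, psp_rise_ms = 1.5,
                          psp_decay_ms = 20, E_GABA = -60,
                          gaba_g_scale = 0.1) {
  if (R_input <= 0 || C_m <= 0)
    stop("R_input and C_m must be positive (membrane time constant)")
  if (psp_rate_hz < 0) stop("PSP rate must be non-negative")
  if (ap_half_width_ms <= 0) stop("AP half-width must be positive")
  structure(as.list(environment()), class = "cacc_neuron")
}

#' Synthetic noise configuration
#'
#' Instrument/baseline noise of the paired recordings: whole-cell white
#' Gaussian noise, excess cell-attached noise (the CA baseline SD is
#' about twice the WC SD in paired recordings), and two-state telegraph
#' steps on the CA channel emulating sporadic single-channel gating in
#' the patch.
#'
#' @param wc_sd WC baseline noise SD, mV.
#' @param ca_excess_sd_factor Target SD(CA)/SD(WC) over quiet segments
#'   (>= 1, default 2).
#' @param telegraph_rate_hz Telegraph switching rate, Hz.
#' @param telegraph_step_mv Telegraph step size, mV (peak-to-peak).
#' @param lfp_pink_sd LFP pink-noise SD (trace units).
#' @return An object of class `cacc_noise`.
#' @export
noise_config <- function(wc_sd = 0.2, ca_excess_sd_factor = 2,
                         telegraph_rate_hz = 1, telegraph_step_mv = 2,
                         lfp_pink_sd = 0.05) {
  if (wc_sd < 0 || lfp_pink_sd < 0) stop("noise SDs must be non-negative")
  if (ca_excess_sd_factor < 1) stop("ca_excess_sd_factor must be >= 1")
  structure(as.list(environment()), class = "cacc_noise")
}

#' Network-event session configuration
#'
#' Parameters of synthetic giant-depolarizing-potential (GDP) or
#' sharp-wave-ripple (SWR) sessions: field-deflection shape and polarity
#' (negative for GDPs in CA3, positive for SWRs in CA1), the concomitant
#' membrane depolarization (about +16 mV for GDPs; about +/-1.5 mV for
#' SWRs), event-locked action potentials in the recorded cell, and
#' multi-unit spikes on the field electrode. Field waveforms are
#' phenomenological Gaussian-windowed deflections chosen to exercise the
#' SD-relative detectors, not a volume-conduction model.
#'
#' @param kind `"GDP"` or `"SWR"`.
#' @param rate_hz Event rate, Hz.
#' @param em_deflection_mv Membrane-potential deflection during the
#'   event (signed, pre-filter), mV.
#' @param em_half_width_ms Half-width of the membrane deflection, ms
#'   (defaults give dominant frequencies of ~3 Hz for GDPs and ~7 Hz for
#'   SWRs under the 1/3-period convention).
#' @param field_amplitude Field-deflection amplitude (trace units,
#'   positive; polarity from `field_polarity`).
#' @param field_polarity `+1` or `-1`.
#' @param field_half_width_ms Half-width of the field deflection, ms.
#' @param ap_mean_count Mean AP count per event (Poisson).
#' @param mua_per_event Mean multi-unit spikes per event (Poisson).
#' @param mua_amplitude MUA spike amplitude (trace units).
#' @return An object of class `cacc_netconfig`.
#' @export
network_config <- function(kind = c("GDP", "SWR"), rate_hz = 0.2,
                           em_deflection_mv = if (kind[1] == "GDP") 16 else 1.5,
                           em_half_width_ms = if (kind[1] == "GDP") 110 else 50,
                           field_amplitude = 0.5,
                           field_polarity = if (kind[1] == "GDP") -1 else 1,
                           field_half_width_ms = em_half_width_ms,
                           ap_mean_count = 3, mua_per_event = 10,
                           mua_amplitude = 0.4) {
  kind <- match.arg(kind)
  if (rate_hz < 0) stop("event rate must be non-negative")
  if (em_half_width_ms <= 0 || field_half_width_ms <= 0)
    stop("half-widths must be positive")
  structure(list(kind = kind, rate_hz = rate_hz,
                 em_deflection_mv = em_deflection_mv,
                 em_half_width_ms = em_half_width_ms,
                 field_amplitude = field_amplitude,
                 field_polarity = sign(field_polarity),
                 field_half_width_ms = field_half_width_ms,
                 ap_mean_count = ap_mean_count,
                 mua_per_event = mua_per_event,
                 mua_amplitude = mua_amplitude),
            class = "cacc_netconfig")
}

## Gaussian bump with given half-width (FWHM) in seconds, unit peak
gauss_bump <- function(tt, center, half_width_s) {
  s <- half_width_s / (2 * sqrt(2 * log(2)))
  exp(-(tt - center)^2 / (2 * s^2))
}

## biphasic AP template sampled at `rate`; returns list(wave, peak_offset_s)
ap_template <- function(amplitude, half_width_ms, rate) {
  s <- half_width_ms * 1e-3 / (2 * sqrt(2 * log(2)))
  tt <- seq(-4 * s, 12 * s, by = 1 / rate)
  wave <- amplitude * exp(-tt^2 / (2 * s^2)) -
    0.15 * amplitude * exp(-(tt - 4 * s)^2 / (2 * (2.5 * s)^2))
  list(wave = wave, peak_offset = which.max(wave) - 1L, n = length(wave))
}

## difference-of-exponentials PSP kernel, unit peak, sampled at `rate`
psp_kernel <- function(rise_ms, decay_ms, rate) {
  tr <- rise_ms * 1e-3; td <- decay_ms * 1e-3
  tt <- seq(0, td * 6, by = 1 / rate)
  k <- exp(-tt / td) - exp(-tt / tr)
  k / max(k)
}

## add `wave` into `x` starting at sample index i (clipped at both ends)
add_wave <- function(x, wave, i) {
  j0 <- max(1L, i)
  j1 <- min(length(x), i + length(wave) - 1L)
  if (j1 < j0) return(x)
  x[j0:j1] <- x[j0:j1] + wave[(j0 - i + 1L):(j1 - i + 1L)]
  x
}

## exact exponential-integrator solution of the leaky membrane
## dV/dt = (E_eff - V)/tau_m, V[1] = E_eff[1]
integrate_membrane <- function(E_eff, tau_m_s, dt) {
  a <- exp(-dt / tau_m_s)
  v <- as.numeric(signal::filter(c(1 - a), c(1, -a), E_eff - E_eff[1]))
  v + E_eff[1]
}

#' Simulate a whole-cell membrane-potential recording
#'
#' Single-compartment leaky integrator
#' \deqn{dV/dt = (E_{drive} - V)/(R_{input} C_m) + I_{inj}/C_m}
#' solved with an exact exponential integrator, plus Poisson
#' difference-of-exponentials PSPs (voltage events with exact
#' ground-truth times and amplitudes) and template action potentials
#' inserted at threshold crossings (and at any fixed `ap_times` in the
#' neuron config). The `high_K` protocol ramps the drive potential. The
#' returned trace is noise-free; instrument noise is added by
#' [simulate_dual()].
#'
#' @param neuron A [neuron_config()].
#' @param protocol A [protocol()] (`none`, `step`, `sinusoid`, `high_K`).
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz (default 5000, the fast-test profile;
#'   use 50000 to match a typical acquisition rate).
#' @param seed Integer RNG seed (required; simulation is deterministic
#'   under it).
#' @return A [bundle()] with a `WC` trace and ground truth
#'   (`ap_times_s`, `psp_times_s`, `psp_amplitudes_mv`).
#' @export
simulate_membrane <- function(neuron, protocol = NULL, duration, rate = 5000,
                              seed) {
  stopifnot(inherits(neuron, "cacc_neuron"))
  if (missing(seed)) stop("seed is required")
  if (duration * rate > 1e8) stop("requested trace too long (> 1e8 samples)")
  tau_m <- neuron$R_input * neuron$C_m * 1e-6  # MOhm * pF -> s
  if (tau_m <= 0) stop("non-positive membrane time constant")
  set.seed(seed)
  n <- round(duration * rate)
  dt <- 1 / rate
  tt <- (seq_len(n) - 1) * dt

  E_drive <- rep(neuron$E_rest, n)
  I_inj <- numeric(n)
  if (!is.null(protocol) && protocol$kind != "none") {
    on_i <- pmin(pmax(round(protocol$onset * rate) + 1L, 1L), n)
    off_i <- pmin(pmax(round(protocol$offset * rate) + 1L, 1L), n)
    if (protocol$kind == "step") {
      I_inj[on_i:off_i] <- protocol$amplitude
    } else if (protocol$kind == "sinusoid") {
      idx <- on_i:off_i
      I_inj[idx] <- protocol$amplitude *
        sin(2 * pi * protocol$frequency * (tt[idx] - tt[on_i]))
    } else if (protocol$kind == "high_K") {
      # linear ramp of the drive potential to +amplitude, then hold
      idx <- on_i:off_i
      E_drive[idx] <- E_drive[idx] +
        protocol$amplitude * (idx - on_i) / max(off_i - on_i, 1L)
      if (off_i < n) E_drive[(off_i + 1L):n] <-
          E_drive[(off_i + 1L):n] + protocol$amplitude
    }
  }
  # pA * MOhm = 1e-3 mV
  E_eff <- E_drive + I_inj * neuron$R_input * 1e-3
  v <- integrate_membrane(E_eff, tau_m, dt)

  # Poisson PSPs
  psp_times <- psp_amps <- numeric()
  if (neuron$psp_rate_hz > 0) {
    n_psp <- stats::rpois(1, neuron$psp_rate_hz * duration)
    if (n_psp > 0) {
      psp_times <- sort(stats::runif(n_psp, 0, duration))
      psp_amps <- stats::rlnorm(n_psp, log(neuron$psp_amp_median_mv),
                                neuron$psp_amp_sigma)
      kern <- psp_kernel(neuron$psp_rise_ms, neuron$psp_decay_ms, rate)
      for (k in seq_len(n_psp))
        v <- add_wave(v, psp_amps[k] * kern, round(psp_times[k] * rate) + 1L)
    }
  }

  # APs: template insertions at threshold crossings + fixed times
  tmpl <- ap_template(neuron$ap_amplitude_mv, neuron$ap_half_width_ms, rate)
  ap_times <- numeric()
  refr <- max(0.005, tmpl$n / rate)
  cross <- which(v[-1] >= neuron$ap_threshold &
                 v[-length(v)] < neuron$ap_threshold) + 1L
  last <- -Inf
  for (i in cross) {
    t_i <- (i - 1) * dt
    if (t_i - last < refr) next
    v <- add_wave(v, tmpl$wave, i - 0L)
    ap_times <- c(ap_times, t_i + tmpl$peak_offset * dt)
    last <- t_i
  }
  if (!is.null(neuron$ap_times) && length(neuron$ap_times)) {
    for (t_i in neuron$ap_times) {
      i <- round(t_i * rate) + 1L
      v <- add_wave(v, tmpl$wave, i)
      ap_times <- c(ap_times, (i - 1) * dt + tmpl$peak_offset * dt)
    }
    ap_times <- sort(ap_times)
  }

  wc <- trace(v, rate = rate, channel_role = "WC", label = "synthetic WC")
  bundle(list(WC = wc),
         protocols = if (is.null(protocol)) list() else list(protocol),
         ground_truth = list(ap_times_s = ap_times,
                             psp_times_s = psp_times,
                             psp_amplitudes_mv = psp_amps),
         provenance = list(generator = "simulate_membrane", seed = seed,
                           rate = rate, duration = duration))
}

## telegraph (two-state) noise: +/- step/2, Poisson switching
telegraph_noise <- function(n, rate, switch_rate, step) {
  if (switch_rate <= 0 || step == 0) return(numeric(n))
  state <- sample(c(-1, 1), 1)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    gap <- max(1L, round(stats::rexp(1, switch_rate) * rate))
    j <- min(n, i + gap - 1L)
    out[i:j] <- state * step / 2
    state <- -state
    i <- j + 1L
  }
  out
}

## pink (1/f) noise of length n, unit SD, via FFT shaping
pink_noise <- function(n, sd = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

#' Add a simulated cell-attached channel to a whole-cell bundle
#'
#' The CA trace is the (noise-free) WC trace passed through the
#' equivalent-circuit filter ([filter_trace()]), plus excess Gaussian
#' noise and two-state telegraph steps. Instrument noise is also added
#' to the WC channel here. The excess CA noise SD is budgeted so that
#' SD(CA) is `ca_excess_sd_factor` times SD(WC) over quiet segments,
#' accounting for the filter's white-noise gain and the telegraph
#' variance.
#'
#' @param b A [bundle()] containing a `WC` trace (treated as the
#'   noise-free membrane potential).
#' @param circuit A [circuit_params()].
#' @param noise A [noise_config()].
#' @param seed Integer RNG seed.
#' @param patch_current_offset Constant CA offset in mV (default 0).
#' @return The bundle with noise added to `WC` and a new `CA` trace;
#'   ground truth is preserved.
#' @export
simulate_dual <- function(b, circuit, noise = noise_config(), seed,
                          patch_current_offset = 0) {
  stopifnot(inherits(b, "cacc_bundle"), inherits(circuit, "cacc_circuit"),
            inherits(noise, "cacc_noise"))
  if (missing(seed)) stop("seed is required")
  wc <- b$traces$WC
  if (is.null(wc)) stop("bundle lacks a WC trace")
  set.seed(seed)
  n <- length(wc$samples)
  ca <- filter_trace(circuit, wc, patch_current_offset)
  # white excess noise carries the quiet-segment SD contract
  # (SD(CA) = factor x SD(WC)); telegraph steps are slow and sit on top,
  # contributing little variance within any single quiet window
  excess_sd <- noise$ca_excess_sd_factor * noise$wc_sd
  ca$samples <- ca$samples +
    stats::rnorm(n, 0, excess_sd) +
    telegraph_noise(n, wc$rate, noise$telegraph_rate_hz,
                    noise$telegraph_step_mv)
  out <- b
  out$traces$WC$samples <- wc$samples + stats::rnorm(n, 0, noise$wc_sd)
  out$traces$CA <- ca
  out$provenance$circuit <- unclass(circuit)[c("R_seal", "R_patch",
                                               "C_patch", "C_elec")]
  out$provenance$dual_seed <- seed
  out
}

#' Simulate a network-event session (LFP + CA with ground truth)
#'
#' Generates an LFP channel (pink noise, Gaussian-windowed field
#' deflections of the configured polarity, event-locked multi-unit
#' spikes) and a cell-attached channel (membrane deflections time-locked
#' to the field events with event-locked template APs, passed through
#' the circuit filter plus noise). Ground truth lists event reference
#' times, event windows, and AP/MUA times.
#'
#' @param cfg A [network_config()].
#' @param circuit A [circuit_params()].
#' @param noise A [noise_config()].
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz (default 10000; must exceed twice the
#'   MUA band's upper corner for MUA analysis).
#' @param seed Integer RNG seed.
#' @param neuron A [neuron_config()] for the CA cell's resting state and
#'   AP template.
#' @return A [bundle()] with `LFP` and `CA` traces (plus the noise-free
#'   `WC` membrane potential for reference) and ground truth
#'   (`event_times_s`, `event_start_s`, `event_end_s`, `ap_times_s`,
#'   `mua_times_s`).
#' @export
simulate_network_session <- function(cfg, circuit, noise = noise_config(),
                                     duration, rate = 10000, seed,
                                     neuron = neuron_config(E_rest = -62,
                                                            psp_rate_hz = 0)) {
  stopifnot(inherits(cfg, "cacc_netconfig"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate

  # event times: Poisson count, uniform placement with minimum separation
  min_sep <- 6 * cfg$field_half_width_ms * 1e-3
  n_ev <- stats::rpois(1, cfg$rate_hz * duration)
  ev <- numeric()
  guard <- 2 * cfg$field_half_width_ms * 1e-3
  tries <- 0
  while (length(ev) < n_ev && tries < 50 * max(n_ev, 1)) {
    cand <- stats::runif(1, guard, duration - guard)
    if (!length(ev) || min(abs(ev - cand)) >= min_sep) ev <- c(ev, cand)
    tries <- tries + 1
  }
  ev <- sort(ev)

  # LFP: pink noise + field deflections + MUA spikes
  lfp <- pink_noise(n, noise$lfp_pink_sd)
  fw <- cfg$field_half_width_ms * 1e-3
  mua_times <- numeric()
  mua_wave <- local({  # brief biphasic extracellular spike, ~1 ms
    ts <- seq(0, 1.2e-3, by = 1 / rate)
    -sin(2 * pi * ts / 1.2e-3) * exp(-ts / 8e-4)
  })
  for (e in ev) {
    lfp <- lfp + cfg$field_polarity * cfg$field_amplitude *
      gauss_bump(tt, e, fw)
    n_mua <- stats::rpois(1, cfg$mua_per_event)
    if (n_mua > 0) {
      tm <- stats::rnorm(n_mua, e, fw / 2)
      tm <- tm[tm > 0 & tm < duration]
      for (t_i in tm)
        lfp <- add_wave(lfp, cfg$mua_amplitude * mua_wave,
                        round(t_i * rate) + 1L)
      mua_times <- c(mua_times, tm)
    }
  }
  mua_times <- sort(mua_times)

  # membrane potential: resting level + event deflections + event APs
  v <- rep(neuron$E_rest, n)
  ew <- cfg$em_half_width_ms * 1e-3
  ap_times <- numeric()
  tmpl <- ap_template(neuron$ap_amplitude_mv, neuron$ap_half_width_ms, rate)
  for (e in ev) {
    v <- v + cfg$em_deflection_mv * gauss_bump(tt, e, ew)
    if (cfg$em_deflection_mv > 0 && cfg$ap_mean_count > 0) {
      n_ap <- stats::rpois(1, cfg$ap_mean_count)
      if (n_ap > 0) {
        ta <- stats::rnorm(n_ap, e, ew / 3)
        ta <- ta[ta > 0 & ta < duration]
        for (t_i in ta) {
          i <- round(t_i * rate) + 1L
          v <- add_wave(v, tmpl$wave, i)
          ap_times <- c(ap_times, (i - 1) / rate + tmpl$peak_offset / rate)
        }
      }
    }
  }
  ap_times <- sort(ap_times)

  wc <- trace(v, rate = rate, channel_role = "WC", label = "network WC")
  b <- bundle(list(WC = wc,
                   LFP = trace(lfp, rate = rate, channel_role = "LFP",
                               units = "mV", label = "synthetic LFP")),
              ground_truth = list(
                event_times_s = ev,
                event_start_s = ev - 3 * fw,
                event_end_s = ev + 3 * fw,
                ap_times_s = ap_times,
                mua_times_s = mua_times),
              provenance = list(generator = "simulate_network_session",
                                seed = seed, kind = cfg$kind))
  simulate_dual(b, circuit, noise, seed = seed + 1L)
}

#' Simulate an evoked GABA-PSP experiment at multiple membrane potentials
#'
#' For each commanded membrane potential, evoked GABA-PSPs are generated
#' with amplitude `gaba_g_scale * (E_GABA - Em)` plus Gaussian trial
#' noise, recorded in the WC frame and through the circuit filter in the
#' CA frame, and averaged across stimuli. The seal shunt depolarizes the
#' CA baseline relative to WC (DC transfer < 1), reproducing the
#' frame-dependent bias in reversal-potential estimates.
#'
#' @param neuron A [neuron_config()] (supplies `E_GABA`, `gaba_g_scale`
#'   and PSP-like kinetics for the evoked response).
#' @param em_levels Commanded WC membrane potentials, mV (non-empty).
#' @param n_stim Stimuli per level.
#' @param circuit A [circuit_params()].
#' @param noise A [noise_config()].
#' @param seed Integer RNG seed.
#' @param rate Sampling rate in Hz.
#' @param amp_noise_sd Per-trial amplitude jitter SD, mV.
#' @return A list of class `cacc_gaba_session`: `em_wc` (levels),
#'   `em_ca` (CA baselines), `wc_avg`/`ca_avg` (per-level averaged
#'   [trace()]s), `stim_time_s` (stimulus time within each average),
#'   `true_E_GABA`, `true_amplitudes` (noise-free per-level WC
#'   amplitudes).
#' @export
simulate_gaba_experiment <- function(neuron, em_levels, n_stim = 10,
                                     circuit, noise = noise_config(), seed,
                                     rate = 5000, amp_noise_sd = 0.3) {
  stopifnot(inherits(neuron, "cacc_neuron"), inherits(circuit, "cacc_circuit"))
  if (!length(em_levels)) stop("em_levels must be non-empty")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  pre <- 0.3; post <- 0.5
  sweep_n <- round((pre + post) * rate)
  kern <- psp_kernel(rise_ms = 5, decay_ms = 40, rate)
  stim_i <- round(pre * rate) + 1L
  wc_avg <- ca_avg <- vector("list", length(em_levels))
  em_ca <- true_amp <- numeric(length(em_levels))
  for (li in seq_along(em_levels)) {
    em <- em_levels[li]
    amp0 <- neuron$gaba_g_scale * (neuron$E_GABA - em)
    true_amp[li] <- amp0
    acc_wc <- acc_ca <- numeric(sweep_n)
    for (s in seq_len(n_stim)) {
      amp <- amp0 + stats::rnorm(1, 0, amp_noise_sd)
      v <- rep(em, sweep_n)
      v <- add_wave(v, amp * kern, stim_i)
      wc_tr <- trace(v, rate = rate, channel_role = "WC")
      ca_tr <- filter_trace(circuit, wc_tr)
      acc_wc <- acc_wc + v + stats::rnorm(sweep_n, 0, noise$wc_sd)
      acc_ca <- acc_ca + ca_tr$samples +
        stats::rnorm(sweep_n, 0, noise$ca_excess_sd_factor * noise$wc_sd)
    }
    wc_avg[[li]] <- trace(acc_wc / n_stim, rate = rate, channel_role = "WC",
                          label = sprintf("GABA avg, Em %g mV", em))
    ca_avg[[li]] <- trace(acc_ca / n_stim, rate = rate, channel_role = "CA",
                          label = sprintf("GABA avg (CA), Em %g mV", em))
    em_ca[li] <- stats::median(ca_avg[[li]]$samples[1:(stim_i - 1L)])
  }
  structure(list(em_wc = em_levels, em_ca = em_ca, wc_avg = wc_avg,
                 ca_avg = ca_avg, stim_time_s = pre,
                 true_E_GABA = neuron$E_GABA, true_amplitudes = true_amp,
                 provenance = list(seed = seed, n_stim = n_stim)),
            class = "cacc_gaba_session")
}
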