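---
title: "Methods: the CA/CC transfer model and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CA/CC transfer model and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific choices behind the package: the
equivalent-circuit model of cell-attached current-clamp (CA/CC)
recording, the detection conventions, the synthetic-data generator that
stands in for paired-electrode experiments, and the numerical decisions
a user should know before trusting (or tuning) the defaults.

## The recording circuit and its transfer function

A CA/CC electrode senses the membrane potential through the patch of
membrane spanning the pipette tip. Electrically the configuration is a
voltage divider: the patch branch (R_patch in parallel with C_patch) in
series with the seal branch (R_seal in parallel with the electrode
capacitance C_elec to the bath). `amplitude_response()` evaluates the
resulting amplitude transfer coefficient

$$AR(f) = \frac{\sqrt{(2\pi K_R \tau f)^2 + K_R^2}}
               {\sqrt{(2\pi (K_C+1) K_R \tau f)^2 + (K_R+1)^2}},
\qquad K_R = \frac{R_{seal}}{R_{patch}},\;
K_C = \frac{C_{elec}}{C_{patch}},\;
\tau = R_{patch} C_{patch}.$$

Units matter: resistances are in GOhm and capacitances in pF
throughout, so τ comes out in milliseconds and is converted to seconds
internally once, at construction (`circuit_params()`). The two closed
forms `dc_transfer()` = R_seal/(R_seal+R_patch) and `hf_transfer()` =
C_patch/(C_patch+C_elec) are the f → 0 and f → ∞ limits.

`complex_transfer()` evaluates the same circuit as a complex divider
H(jω) = Z_seal/(Z_patch + Z_seal). Its modulus is algebraically
identical to AR(f); the property suite checks agreement to 1e-10
relative error over random parameter draws, so each derivation guards
the other against transcription errors.

### Assumptions

- The cell interior is treated as an ideal voltage source: no loading
  of the cell by the recording circuit, no pipette series resistance.
- Parameters are passive and constant. Active currents across the
  patch (single-channel gating) are represented only as a constant
  offset hook in `filter_trace()` and as telegraph noise in the
  generator; no magnitude model is attempted for cells whose CA
  baseline is *more negative* than WC.
- Phase response is never fitted — only amplitude data are used, which
  is also why the electrode capacitance must be fixed externally (see
  below).

## Fitting the model

`fit_transfer()` performs nonlinear least squares (Levenberg–Marquardt
via `minpack.lm`) on the linear amplitude ratio, with the three free
parameters optimized in log-space so positivity is structural rather
than a constraint. An optional flag switches the residuals to log(AR)
for data spanning many decades of attenuation.

- **C_elec is always held fixed.** Against amplitude-only data the
  four-parameter problem is degenerate (C_elec and C_patch trade off
  through K_C); a typical patch pipette is near 7 pF and the value
  should be measured or assumed by the user.
- **Initialization** inverts the closed-form limits: the lowest
  frequency point gives R_seal/(R_seal+R_patch) under an R_patch =
  5 GOhm prior; the highest gives C_patch/(C_patch+C_elec). These
  starts are robust across the realistic parameter range; on noiseless
  25-point curves the generating parameters are recovered to well
  under 1%, and with 1% multiplicative noise to ~10% (Monte-Carlo
  property test).
- At least 3 frequency points are required (3 free parameters); ≥ 4
  points spanning two decades are recommended.

## Time-domain filter

`filter_trace()` realizes H(s) = K_R(1+sτ) / [(K_R+1) + s(K_C+1)K_Rτ]
by bilinear transform at the trace's sampling rate. The bilinear
transform preserves the DC gain exactly and the low-frequency response
accurately; sinusoid attenuation matches AR(f) within 1% for
f ≤ rate/20 (tested). The filter state is initialized so a trace that
starts at baseline shows no startup transient. Content above Nyquist
is aliased, as with any sampled system — the generator's templates are
band-limited well below the rates used.

## Detection conventions

All thresholds are exposed as arguments with these defaults:

| quantity | value |
| --- | --- |
| WC AP threshold | 40 mV above resting potential |
| CA AP / sPSP detection | 1 mV/ms on the first derivative |
| AP onset | 10 mV/ms, backward scan from peak |
| PSP onset | 0.1 mV/ms, backward scan from peak |
| event amplitude baseline | mean over 1–5 ms before onset |
| evoked-PSP amplitude | extremum within 200 ms post-stimulus minus 200 ms pre-stimulus median |
| field events (GDP/SWR) | 3 SD of the quietest 100 s, 1–100 Hz band |
| MUA | 3 SD of the quietest 100 s, 300–2500 Hz band, negative crossings, 1 ms dead time |
| dominant frequency | half-width = 1/3 period, f = 1/(3·HW) |

Derivative thresholds are applied to a low-pass-smoothed copy of the
trace: differentiating raw wideband noise would make a 1 mV/ms
threshold meaningless. Detection uses a 500 Hz cutoff by default
(preserving PSP rise slopes), while onset refinement and amplitude
measurement use a 300 Hz copy — the 0.1 mV/ms onset scan needs a
derivative noise floor well below its threshold, otherwise the
backward scan stops at the first noise upcrossing and the 1–5 ms
baseline window lands on the rising phase. Both cutoffs are arguments.

Half-durations are measured at half of the amplitude defined above,
with linear interpolation between samples. CA events are paired to WC
events at the WC onset, with the CA peak searched up to a configurable
lag beyond the WC peak (default 5 ms; the circuit's pole delays CA
peaks, so slow-PSP transfer studies should allow ~20 ms).

Two detector behaviors deserve a warning:

- **Field-event side lobes.** Band-passing a monophasic field
  deflection (1–100 Hz) leaves opposite-polarity rebound lobes of
  roughly a fifth of the peak — a scale-invariant artifact, so it
  cannot be escaped by better signal-to-noise. `detect_field_events()`
  therefore rejects an excursion when a larger opposite-polarity
  excursion lies within 0.3 s (configurable).
- **MUA false positives.** A −3 SD threshold on Gaussian band-limited
  noise crosses at the Rice rate ν ≈ f_rms·exp(−9/2), on the order of
  10 Hz for a 300–2500 Hz band. The 3 SD convention is retained as the
  field standard, but users needing low false-positive rates on
  near-Gaussian noise should raise `threshold_sd` (4.5 SD brings the
  rate below 0.5 Hz); the test suite asserts both facts.
- **Network-event Em change.** `event_em_change()` applies a 20 ms
  running median before taking the extremum, so spike peaks riding on
  a GDP/SWR depolarization do not masquerade as the slow envelope —
  the same trick as suppressing APs with a sub-1 Hz median filter when
  measuring slow potassium-induced depolarizations.

## Trace-level corrections

- **Liquid junction potential:** corrected = recorded − LJP, making
  membrane potentials more negative (16 mV for a 4 mM Cl⁻ pipette
  solution, 12.5 mV for 30 mM). One application only; the trace
  records it.
- **Bridge compensation** (offline): boundaries where |dV/dt| exceeds
  30% of the ON-phase derivative peak; the subtracted rectangle's
  amplitude is the jump at the ON boundary estimated from 0.2 ms means
  on either side (the boundary rule is standard; the amplitude
  estimator is this package's choice).
- **Nernst potentials** default to 30 °C (a typical submerged-slice
  bath). With a 4 mM Cl⁻ pipette against ~136 mM bath chloride the
  chloride equilibrium is −92 mV; with 30 mM, −39.5 mV. Note the pair
  (−92, −39) quoted in slice work is not exactly consistent with any
  single temperature; −39.5 rounds ambiguously.
- **Quietest-interval search** uses a stride of duration/10 — a
  runtime/precision compromise; the spec of the window (1 s for PSP
  noise floors, 100 s for field thresholds) is the convention, the
  stride is ours. Traces shorter than the window fall back to the
  quietest half and flag it.

## The synthetic generator

The generator exists so that every pipeline stage has an input with
exact ground truth. It emulates:

- a single-compartment passive membrane (exact exponential
  integrator), resting near −81 mV with R_input 100 MOhm, C_m 150 pF
  (τ_m = 15 ms);
- Poisson sPSPs as difference-of-exponentials *voltage* templates
  (rise 1.5 ms, decay 20 ms, log-normal amplitudes, median 3 mV,
  σ = 0.3, 1 Hz) — no conductance shunting, because the analyses treat
  amplitude as proportional to driving force;
- APs as fixed biphasic templates (100 mV, 1.4 ms half-width, i.e.
  ~240 Hz dominant frequency) inserted at threshold crossings or at
  listed times — waveform transfer, not spike generation, is the
  object of study, and templates give exact ground truth;
- the CA channel as the *noise-free* membrane potential passed through
  the circuit filter, plus white excess noise scaled to make the CA
  quiet-segment SD twice the WC SD, plus two-state telegraph steps
  (2 mV, 1 Hz) emulating sporadic channel gating in the patch;
- network sessions: pink-noise LFP with Gaussian-windowed field
  deflections (negative for GDPs, half-width 110 ms ≈ 3 Hz dominant;
  positive for SWRs, 50 ms ≈ 7 Hz), event-locked AP bursts and
  multi-unit spikes; GDP membrane deflections default to +16 mV, SWR
  to ±1.5 mV;
- evoked GABA sweeps: per-level evoked amplitude g·(E_GABA − Em) with
  trial noise, averaged over stimuli, recorded in WC and through the
  filter in CA.

Defaults are fixed study conditions, not tuning knobs: they were
chosen once to represent realistic slice recordings (WC baseline noise
0.2 mV SD; 5 kHz sampling as a fast-test profile of the usual 50 kHz;
120 s sessions; 10 kHz for sessions analyzed for MUA) and the test
suite's recovery statements are made under exactly these conditions.

What the generator does **not** emulate — and therefore what passing
tests do *not* establish about real data: conductance-based synaptic
shunting, spike-generation dynamics and depolarization block,
volume-conduction physics of the LFP (waveforms are phenomenological),
electrode drift, temperature effects, and any magnitude model for
active patch currents beyond a constant offset. Detection rates and
amplitude errors quoted by the tests are properties of this synthetic
family, under its amplitude distributions and noise levels.

## Numerical choices

- Zero-phase filtering pads by reflection and removes the mean before
  forward–backward Butterworth filtering; plain forward–backward
  filtering from zero state on a −80 mV-offset trace produces edge
  transients large enough to masquerade as events.
- Band-pass order is 3 per direction (passband flat to ~1% across
  1–100 Hz at typical rates); low-pass smoothing is order 2.
- The JSON session container writes doubles with 17 significant
  digits, which round-trips IEEE float64 exactly; round-trip
  losslessness is tested bit-for-bit.
- Reversal-potential fits are unconstrained OLS of amplitude against
  Em; E_GABA is the zero-amplitude intercept, so rescaling all
  amplitudes (attenuation) moves the slope but never the intercept. A
  slope numerically indistinguishable from zero flags the fit
  degenerate instead of reporting an intercept.
- The isoelectric dead band for polarity classification defaults to
  0.3 mV, about the noise floor of a 10-sweep average under default
  noise; it is an argument, since "isoelectric" has no standard
  definition.
- Problem sizes in the test suite: 120 s sessions at 5 kHz (10 kHz
  for network/MUA analyses), five seeds for the pipeline-recovery
  statements, 100 replicates for the noisy-refit Monte-Carlo, 1000
  draws for the transfer-oracle identity.

## Known limitations

- The amplitude-only fit cannot separate C_elec from C_patch; a wrong
  fixed C_elec biases C_patch proportionally (K_C is what is
  identified).
- Overlapping PSPs closer than the detector's run-separation are
  counted once; at 1 Hz event rates this loses ~1–3% of events.
- The sPSP detector's sensitivity floor under default noise is an
  effective rise-slope threshold near 1 mV/ms after smoothing; events
  below ~1.5 mV are increasingly missed, exactly as with the same
  criterion applied to real recordings.
- `reframe_ca_to_wc()` removes the seal-shunt bias only insofar as the
  WC membrane potential is itself unbiased; it inherits any WC error
  (e.g. residual junction-potential error) unchanged.
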