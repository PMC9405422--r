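# shared fixtures: example-cell and group-median circuits, event matching

example_cell <- function() circuit_params(R_seal = 55.6, R_patch = 7.3,
                                          C_patch = 0.8, C_elec = 7)

group_median_cell <- function() circuit_params(R_seal = 15.4, R_patch = 4.9,
                                               C_patch = 0.8, C_elec = 7)

# fraction of `truth` times matched by `detected` within tol_s (1:1 greedy)
match_fraction <- function(truth, detected, tol_s = 5e-3) {
  if (!length(truth)) return(NA_real_)
  if (!length(detected)) return(0)
  used <- logical(length(detected))
  hit <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol_s) { hit <- hit + 1L; used[j] <- TRUE }
  }
  hit / length(truth)
}

# indices of detected events with no ground-truth partner (false positives)
false_positives <- function(truth, detected, tol_s = 5e-3) {
  if (!length(detected)) return(integer())
  which(vapply(detected, function(d)
    !length(truth) || min(abs(truth - d)) > tol_s, logical(1)))
}

# sinusoid amplitude of a trace segment (second half, peak-to-peak / 2)
settled_amplitude <- function(tr) {
  n <- length(tr$samples)
  seg <- tr$samples[floor(n / 2):n]
  (max(seg) - min(seg)) / 2
}

# amplitude of the f-Hz component of a trace segment (Fourier projection
# on the second half, exact for a settled sinusoid, immune to drift)
tone_amplitude <- function(tr, f) {
  n <- length(tr$samples)
  seg <- floor(n / 2):n
  x <- tr$samples[seg]
  t <- (seg - 1) / tr$rate
  2 * Mod(mean(x * exp(-2i * pi * f * t)))
}
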