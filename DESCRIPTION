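Package: cacc
Title: Accuracy Analysis of Cell-Attached Current-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how faithfully cell-attached
    current-clamp (CA/CC) recordings report neuronal membrane potential
    relative to whole-cell (WC) recordings. Implements the patch/seal RC
    equivalent-circuit transfer model of the recording configuration
    (amplitude and complex frequency response, least-squares fitting, and
    a time-domain filter), a synthetic paired-electrode trace generator
    with exact ground truth, trace-level corrections (liquid-junction,
    off-line bridge compensation, Nernst potentials), action-potential and
    postsynaptic-potential event detection with CA/WC transfer
    coefficients, detection of giant depolarizing potentials, sharp-wave
    ripples and multi-unit activity from local field potentials with
    peri-event analysis, and estimation of the GABA reversal potential and
    driving force from evoked responses at multiple membrane potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
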