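Package: neonirs
Title: Neonatal fNIRS Phoneme-Learning Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for event-related functional
    near-infrared spectroscopy (fNIRS) studies of rapid auditory learning in
    neonates. Generates synthetic two-wavelength optical recordings with a
    plantable group-by-phase-by-stimulus effect structure, converts raw
    intensities to oxy-/deoxyhaemoglobin concentration changes via the
    modified Beer-Lambert law with artifact-epoch masking, spike correction
    and zero-phase band-pass filtering, extracts per-trial mean amplitude and
    peak latency, fits Helmert-coded linear mixed-effects models with
    Satterthwaite tests, per-channel BLUPs and Benjamini-Hochberg seed
    selection, and estimates resting-state functional connectivity with
    Fisher z-transformed Pearson correlations and a reduced group-by-phase
    mixed model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    signal,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
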