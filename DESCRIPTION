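Package: ssvepbci
Title: Simulation and Analysis of SSVEP Brain-Computer Interface Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing steady-state visual evoked
    potential (SSVEP) brain-computer interface experiments with a
    neuromodulation arm. Provides a synthetic 64-channel EEG generator with
    known ground truth (harmonic SSVEP responses, 1/f background, alpha
    rhythm, semi-Markov microstate sequences, and an rTMS pulse schedule),
    BrainVision file I/O and standard preprocessing, filter-bank canonical
    correlation analysis (FBCCA) and task-discriminant component analysis
    (TDCA) decoders, the cumulative decoding effect (CDE) summary of
    accuracy-versus-duration curves, spectral SNR and task-related versus
    task-unrelated power decomposition, polarity-invariant microstate
    segmentation with dynamics metrics, channel-space cluster-based
    permutation tests with FDR control, and an end-to-end seeded study
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    lme4,
    optparse
Config/testthat/edition: 3
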