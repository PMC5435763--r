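Package: spindlefront
Title: Sleep Spindle Detection and Pareto-Front Performance Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects sleep spindles (11-16 Hz sigma-band EEG bursts) in
    single-channel polysomnography with six frequency-based detectors
    (Fourier bandpass/amplitude, RMS thresholding, Morlet wavelet
    probabilistic estimates, and Hilbert-Huang fuzzy-logic estimates)
    and three sequential double-reading hybrids. Detector performance is
    scored event-by-event under an intersection-over-union overlap rule
    (precision, recall, F-beta), and detector operating parameters are
    optimized as a two-objective problem (false negatives, false
    positives) with the Strength Pareto Evolutionary Algorithm (SPEA2),
    including subsampled training, hold-out and k-fold validation, and
    Monte-Carlo confidence intervals for F1 based on Beta-distributed
    precision and recall. A seeded synthetic polysomnography generator
    with planted spindles, K-complex confounders, and simulated scorers
    makes the whole pipeline testable without clinical recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, signal
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
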