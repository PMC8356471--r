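Package: opmbci
Title: Spatiotemporal LCMV Beamformer Decoding for OPM-MEG Visual
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding pipeline for visual brain-computer
    interfaces recorded with on-scalp magnetometer arrays (OPM-MEG) or
    scalp EEG. Provides a seeded synthetic-session generator for
    motion-onset evoked responses (N/M200, P/M300) and steady-state
    visual evoked potentials (SSVEP) with frequency-phase target coding;
    deterministic preprocessing (zero-phase Butterworth filtering,
    epoching, baselining, polyphase downsampling, planar-gradiometer
    synthesis, two-period overlapping segmentation); evoked-response
    statistics with BCa bootstrap confidence intervals and component SNR;
    spectral SSVEP features (neighbour-bin SNR, Fourier phase, circular
    dispersion); a regularized spatiotemporal linearly-constrained
    minimum-variance (LCMV) beamformer classifier for both paradigms with
    cross-validated evaluation and greedy forward channel selection; and
    a simulated real-time mind-spelling session with backspace correction
    and post hoc stimulation-length analysis.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
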