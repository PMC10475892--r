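Package: hisbeat
Title: Beat-by-Beat Extraction of His Bundle Signals from PR-Interval Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noninvasive, beat-by-beat retrieval of His bundle signals (HBS)
    from the PR interval of cardiac time series such as magnetocardiography
    (MCG) or body surface potential maps (BSPM). Combines interval-dependent
    wavelet soft thresholding (coif5, fixed-form universal threshold, with
    manually chosen preserved time intervals around the His deflection) with
    signal space projection: the atrial subspace is estimated by singular
    value decomposition of Savitzky-Golay over-smoothed epochs and removed by
    orthogonal projection, isolating the ~100 Hz biphasic His deflection in
    every beat. Includes QRS-onset detection and PR epoching, signal
    averaging, objective HBS identification criteria, a synthetic PR-epoch
    simulator with three atrial-repolarization waveform types and calibrated
    additive white Gaussian noise, quality metrics (SNR, band-limited
    signal-to-error ratio, Pearson correlation, HV-interval measurement),
    agreement statistics (Spearman rank correlation, Bland-Altman limits of
    agreement), inter-beat contour matrices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
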