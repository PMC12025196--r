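Package: mcgica
Title: Adaptive Independent Component Analysis Denoising for Multichannel
    Magnetocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Blind-source-separation denoising for multichannel optically
    pumped magnetometer (OPM) magnetocardiography (MCG) recordings. Estimates
    the beat-based signal-to-noise ratio of a recording, maps it to a PCA
    variance-contribution threshold to choose the number of retained
    components automatically, and identifies heartbeat-related independent
    components with two autocorrelation/cross-correlation statistics: the
    autocorrelation integral power ratio (IPR) and the cross-correlation
    function extremum (CFE). Includes the full preprocessing chain (zero-phase
    bandpass, powerline removal by spectral interpolation, wavelet-band R-wave
    enhancement, R-peak detection), a numerical phantom generator emulating a
    coil-driven 64-channel OPM array, and evaluation metrics (output SNR,
    ground-truth correlation, butterfly-plot export).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
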