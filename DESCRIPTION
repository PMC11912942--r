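Package: ccigait
Title: Co-Contraction Indices for Treadmill Gait from EMG and Foot Acceleration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying agonist-antagonist muscle co-contraction
    during treadmill walking from surface electromyography (EMG) and
    foot-mounted accelerometer signals. Provides a synthetic gait-trial
    generator with gait-phase-structured muscle bursts, linear-envelope
    extraction (bias removal, full-wave rectification, zero-phase Butterworth
    low-pass) with dynamic normalization to a reference fast-walking trial,
    initial-contact detection from vertical foot acceleration, stride-time
    outlier rejection and 101-point stride time normalization, three
    co-contraction index formulas (common-area integral, smaller/larger
    weighted ratio, and antagonist fraction of total activation), condition
    summaries with percent-change contrasts, and a nested linear mixed-effects
    model ladder selected by likelihood-ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    pracma,
    lme4,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
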