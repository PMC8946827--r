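Package: ipgbp
Title: Cuffless Blood Pressure Estimation from Single-Channel
    Bio-Impedance Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for personalized cuffless
    blood-pressure (BP) monitoring from single-channel impedance
    plethysmography (IPG). Provides a physics-based synthetic IPG data
    generator built on the Bramwell-Hill pressure/area relation and
    Ohm's-law impedance conversion, digital emulation of a Butterworth
    analog front end with beat segmentation, Daubechies-8 continuous
    wavelet transform scalogram features, an ultra-lightweight two-stream
    soft stagewise regression network trained with a quartile-weighted
    mean-absolute-error penalty loss, and a full accuracy-evaluation
    battery (mean error, mean absolute error, Bland-Altman limits of
    agreement, AAMI criterion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
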