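Package: normgain
Title: Divisive Normalization with Attentional Gain for Motion Duration
    Thresholds and Cortical Surface-Area Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking cortical surface area to spatial parameters of a
    divisive normalization model of visual motion perception. Implements a
    one-dimensional normalization model with a spatial top-down (attentional)
    gain field that converts peak population responses into predicted motion
    duration thresholds; a Bayesian adaptive (Psi) staircase with Weibull
    psychometric fitting, threshold-at-criterion readout and staircase quality
    control; cortical parcel surface-area normalization, atlas-wide correlation
    screening and group splits; percent-signal-change quantification of
    block-design ROI time courses with motion- and performance-based exclusion;
    and a synthetic-cohort generator that plants surface-area-to-model-parameter
    couplings so the whole pipeline can be exercised and validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
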