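Package: eegmarkers
Title: EEG Band-Power and Synchronization Biomarkers with Decision Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and statistical evaluation of quantitative EEG
    biomarkers for two-group (case/control) comparisons. Implements
    continuous Morlet wavelet band/lobe power biomarkers, two linear
    synchronization biomarkers (Welch magnitude-squared coherence and
    bivariate autoregressive coherence with minimum-description-length
    order selection), Welch two-sample significance mapping with
    assumption diagnostics, linear-discriminant leave-one-out
    classification, and four decision-fusion operators. Includes a
    synthetic multichannel EEG cohort generator with controllable
    band-specific power effects and within-lobe coupling so that the
    full pipeline can be exercised and calibrated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    car,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS
Config/testthat/edition: 3
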