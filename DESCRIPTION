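Package: sscbench
Title: Benchmarking VIS-SWNIR Calibration Models for Pear Soluble Solids Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reproducible benchmark of multivariate calibration pipelines
    that predict the soluble solids content (SSC, degrees Brix) of 'Rocha'
    pears from VIS-SWNIR diffuse reflectance spectra measured under
    packinghouse-like conditions. Includes a synthetic-data generator that
    emulates the statistical structure of a 3300-spectrum pear survey
    (fruit-level SSC, size and temperature distributions, chlorophyll and
    sugar/water absorption bands, size-dependent scatter, temperature band
    shifts, chronological drift), the standard chemometric preprocessing grid
    (absorbance, Savitzky-Golay derivatives, SNV, chlorophyll-band exclusion,
    temperature/size augmentation), a PLS wrapper wavelength-selection
    procedure, four calibration engines (PLS, MLR, RBF-kernel SVR with
    analytic hyperparameter seeding, and an averaged multilayer perceptron),
    internal and external (chronological) validation, and a metric suite
    including the Prediction Gain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
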