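Package: losrange
Title: Patient-Specific Length-of-Stay Range Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a patient-specific hospital length-of-stay (LOS) range
    rather than a point value. Implements six interval-construction methods:
    point prediction plus/minus a global root-mean-square error; a second
    network that learns each patient's error magnitude; three two-output
    distributional networks trained with custom interval losses (a
    probability-mass difference loss, an interval-overlap loss and a
    Wasserstein-style loss with a correlation penalty); and a conditional
    Wasserstein GAN with gradient penalty that generates per-patient LOS
    samples. Includes a synthetic electronic-health-record cohort generator
    with log-normal LOS outcomes, coverage-accuracy evaluation, an overall
    prediction error metric and alpha calibration of interval widths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
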