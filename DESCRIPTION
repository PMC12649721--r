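Package: devnorm
Title: Normative Developmental Models of Motor Performance with Age-Varying Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds normative models of motor-performance parameters across
    childhood and adolescence from cross-sectional cohort data. Fits
    exponential or quadratic age curves with dummy-coded sex and hand
    covariates using ten-fold cross-validated model selection, models the
    age dependence of variability as a linear function of age on absolute
    residuals, and standardizes observations into z-scores with an unbiased
    absolute-deviation scaling. Includes iterative 3-SD outlier removal,
    Shapiro-Wilk normality gating with a skew/kurtosis "normal enough"
    relaxation, a shift-then-transform ladder (log, square-root, inverse),
    age-resolved 95% normative performance intervals, deficit scoring of
    new individuals, and a synthetic-cohort generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
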