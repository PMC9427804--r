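Package: eakr
Title: Erythrocyte Aggregation Kinetics from Syllectograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, fits and simulates the initial kinetics of erythrocyte
    aggregation measured by light backscattering (syllectograms). Provides
    forward kinetic models (second-order inverse-linear, first-order
    mono-exponential, and the bi-exponential syllectogram decomposition),
    segment-wise nonlinear least-squares fitting with curve-peeling
    initialization, the EAK5s half-life statistic (ln 2 / k from the first
    5 s of the decay), a seeded synthetic-syllectogram and cohort simulator
    emulating a point-of-care stirred-tube aggregometer, shear-rate
    estimation from tube geometry, and the repeatability and group-comparison
    statistics used to validate such measurements (coefficients of variation,
    Shapiro-Wilk normality, pooled and Welch t-tests, Pearson correlation,
    measurement-stability analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
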