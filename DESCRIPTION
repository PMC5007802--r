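Package: bmrkit
Title: Basal Metabolic Rate Measurement, Prediction Equations and
    Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating basal metabolic rate (BMR) in adults.
    Converts ventilated-hood indirect-calorimetry gas-exchange traces
    (5-s VO2/VCO2 sampling) into measured BMR via the abbreviated Weir
    formula with habituation discard and coefficient-of-variation
    steady-state window selection; ships a registry of seven
    anthropometric BMR prediction equations (Singapore, Harris-Benedict,
    Henry, Liu, Yang, Mifflin, Owen) with Asian BMI classification;
    derives new weight/height/age/gender equations by forward stepwise
    least squares reporting R-squared and residual standard deviation;
    and validates equations against measured BMR with bias, paired
    t-tests, Bland-Altman limits of agreement, difference-versus-average
    regression and BMI-stratified +/-10 percent accuracy rates. A
    synthetic cohort generator reproduces the statistical structure of a
    Singaporean Chinese study population so the full pipeline can be
    exercised without subject-level data.
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
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
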