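Package: mdisbone
Title: Dietary Inflammatory Scoring and Bone Mineral Density Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the modified dietary inflammatory score (M-DIS) from
    nutrient and food intake profiles by z-score standardization against a
    reference population and summation of signed inflammatory weights;
    converts areal bone mineral density (BMD) measured by dual-energy X-ray
    absorptiometry into T-scores and classifies low-BMD (osteopenia or
    osteoporosis) status; and provides the tertile-based association
    pipeline used in nutritional epidemiology: descriptive tertile
    comparisons, ANCOVA-adjusted means with Tukey pairwise contrasts,
    crude and covariate-adjusted linear and logistic regression with
    trend and likelihood-ratio interaction tests, and stratified
    sensitivity analyses. A seedable synthetic-cohort generator emulating
    a senior Mediterranean population with overweight/obesity supports
    end-to-end testing and parameter-recovery studies without access to
    individual-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
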