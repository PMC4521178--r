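Package: glycurve
Title: Insulin Sensitivity and Beta-Cell Function from Meal-Test and Clamp Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the standard panel of insulin-sensitivity and beta-cell
    function indices from fasting measurements, euglycemic-hyperinsulinemic
    clamp steady states and liquid mixed-meal tolerance test (LMMTT) time
    series: HOMA-IR, HOMA-B, the clamp insulin sensitivity index per kg lean
    mass, Matsuda-type composite sensitivity, the insulinogenic index, the
    insulin secretion index (AUC ratio) and the oral disposition index.
    Fits the hyperbolic secretion-versus-sensitivity relationship across
    subjects and scores beta-cell compensation ("falling off the disposition
    index curve"), runs age-adjusted group comparisons with Bonferroni post
    hoc tests and split-plot repeated-measures ANOVA for post-meal
    excursions, and ships a seedable synthetic-cohort generator with known
    ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
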