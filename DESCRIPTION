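Package: lqascamp
Title: Lot Quality Assurance Sampling for Service Coverage Assessment in
    Refugee Camps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of Lot Quality Assurance Sampling (LQAS)
    coverage surveys in refugee-camp settings. Provides exact-binomial
    decision-rule selection with alpha/beta misclassification errors and
    operating-characteristic curves; classification of camp supervision
    areas against programme targets and against camp-average coverage
    (LQAS as a homogeneity test); stratified coverage estimation (crude,
    population-weighted, and survey-design with finite population
    correction) with a sensitivity comparison of the three estimators; a
    simulator of the field sampling pipeline (systematic PPS allocation
    of interview locations to villages, segmentation sampling with a
    random-walk fallback, and parallel sampling of two respondent
    groups); and a synthetic camp generator with known ground truth for
    validating every stage end to end. Ships the supervision-area count
    table from a WASH assessment of Batil camp, South Sudan, as a worked
    fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
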