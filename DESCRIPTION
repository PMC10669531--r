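Package: adrules
Title: Association-Rule Mining of Family and School Factors for Adolescent
    Depression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining combinations of family and school risk and
    protective factors associated with adolescent depression from item-level
    survey data. Provides psychometric scale scoring with reliability checks,
    quartile-based discretization of scale totals into risk and protective
    indicator items, a from-scratch levelwise Apriori miner with
    fixed-consequent rule generation (support, confidence, lift), stratified
    subgroup analyses by gender, age group and left-behind status, a
    calibrated synthetic survey-cohort generator with planted
    factor-depression dependence for end-to-end testing, and packaged
    transcriptions of published rule tables with internal-consistency
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
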