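Package: weightedspend
Title: Need-Weighted Comparison of Acute Hospital Spending Across General Practices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares acute hospital spending between general practices after
    standardising their registered populations for health care need. Implements
    three coefficient-table-driven capitation weighting schemes (an NHS
    core-services style allocation, an adapted variant restricted to acute and
    maternity need with residence-mixed local factors, and a Carr-Hill style
    global-sum weighting), quarterly population averaging, auditable
    focal-practice adjustments (site cohort removal, reference-cohort removal,
    expected-cost correction, GDP-deflator inflation), cost per weighted
    patient at practice and primary-care-network level, a one-sided z
    comparison with normality screening, and a seeded synthetic-region
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
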