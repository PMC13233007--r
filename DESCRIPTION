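Package: edmargin
Title: Dual-Framework Economic Modelling of Emergency Department Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the financial impact of efficiency interventions in
    hospital emergency departments (EDs) under two costing frameworks: a
    hospital-management perspective that partitions total cost into fixed,
    volume-variable, and care-hours-modifiable components, and a public-policy
    perspective in which cost tracks revenue at a fixed cost-to-charge ratio.
    Includes visit-level revenue processing (ED revenue attribution for
    admitted patients, percentile capping, stratified mean imputation),
    pre/post-period comparison tables, deterministic one-way sensitivity
    sweeps over throughput efficiency for capacity-constrained and
    volume-stable EDs, per-visit break-even analysis for intervention pricing,
    and a seeded synthetic visit-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
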