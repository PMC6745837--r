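Package: actbench
Title: Benchmarking Hospital Utilization of Adjuvant Chemotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Provider-profiling tools for benchmarking binary treatment
    utilization (adjuvant chemotherapy after colon cancer resection) across
    hospitals. Decomposes inter-hospital rate variation into random and
    systematic components with a binomial Monte Carlo null for the
    coefficient of variation, computes achievable-benchmarks-of-care
    (pared-mean) and criterion-based benchmark rates with and without
    case-mix adjustment via indirect standardization and a parametric
    bootstrap, and reports utilization shortfalls. Includes a calibrated
    synthetic cohort generator emulating a province-wide registry study so
    the full pipeline is testable without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
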