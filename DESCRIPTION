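Package: cwsfluoride
Title: Community Water System Fluoride Exposure Estimates and County-Level
    Spatial Inequality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds chronic (multi-year) fluoride exposure estimates for
    community water systems (CWSs) from routine compliance monitoring records
    with left-censored nondetects, aggregates them to population-weighted
    county-level mean and upper-percentile concentrations, and quantifies
    inequalities in exposure across water-system subgroups and county
    racial/ethnic composition.  County-level associations are estimated with
    maximum-likelihood spatial error models on queen-contiguity weights,
    reported as geometric mean ratios per 10 percentage-point higher
    subgroup composition, with Moran's I and Lagrange multiplier diagnostics.
    Includes a synthetic-data generator that emulates the monitoring-record,
    system-inventory, county-covariate and adjacency inputs with planted
    effects for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
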