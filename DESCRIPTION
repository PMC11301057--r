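Package: faersignal
Title: Disproportionality Signal Mining for FAERS Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pharmacovigilance signal detection for spontaneous adverse-event
    reporting data in the FDA Adverse Event Reporting System (FAERS) quarterly
    ASCII dialect. Provides schema-validated readers and writers for the seven
    FAERS tables, case deduplication by receipt date, target-drug
    primary-suspect cohort extraction, MedDRA-style preferred-term to
    system-organ-class coding, four disproportionality statistics (reporting
    odds ratio, proportional reporting ratio with chi-squared, the BCPNN
    information component, and the DuMouchel multi-item gamma-Poisson shrinker
    EBGM) with combined signal-retention criteria, demographic subgroup
    re-screening, time-to-onset analysis, and a synthetic FAERS generator with
    implanted signals for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
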