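Package: faersror
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection on FDA Adverse
    Event Reporting System (FAERS) style quarterly ASCII tables: ingestion of
    "$"-delimited DEMO/DRUG/REAC/INDI/OUTC files, deduplication of multi-version
    cases to the latest report, rule-based classification of drug exposure route
    (oral versus topical) from free-text route and dose-form fields, cohort
    construction with indication restriction, per-Preferred-Term reporting odds
    ratios with Woolf 95% confidence intervals and zero-cell continuity
    correction, descriptive demographic and outcome summaries, forest plots,
    and a synthetic FAERS-like data generator with a ground-truth ledger for
    end-to-end validation. Developed around the oral-versus-topical minoxidil
    cardiovascular signal question but general over drug lexicons and
    Preferred-Term watchlists.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
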