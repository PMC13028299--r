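# faersror

Disproportionality signal detection for FAERS-style spontaneous
adverse-event report data, built around formulation-based comparisons — the
motivating case is oral versus topical minoxidil and cardiovascular events.

Spontaneous reporting systems have no exposed-patient denominator, so they
cannot estimate incidence; what they support is asking whether an event is
*reported* disproportionately often with one exposure versus a comparator.
`faersror` implements that workflow end to end for analysts working with
FAERS quarterly ASCII files (or data shaped like them):

- **Ingestion** of the `$`-delimited `DEMO/DRUG/REAC/INDI/OUTC` tables with
  strict header validation, quarantine of malformed/orphan rows, and
  normalization of dates, ages, sex, and Preferred Terms (PTs).
- **Deduplication** of multi-version cases to the latest report per
  `caseid` (max report date, then max `primaryid`), with a full decision log.
- **Rule-based exposure classification** from free-text route and dose-form
  fields into `ORAL` / `TOPICAL` / `BOTH` / `UNKNOWN`, each `UNKNOWN`
  carrying a machine-readable reason for auditing.
- **Cohort construction** with role-code, report-year, and indication
  include/exclude filters, every exclusion tallied.
- **Signal detection**: per-PT reporting odds ratios with Woolf 95%
  confidence intervals and zero-cell continuity correction.
- **Descriptive summaries** (demographics, outcome codes with
  `MISSING`/`BLANK_ONLY` distinguished, yearly counts) and forest plots.
- **A synthetic FAERS-like generator** with a ground-truth ledger, so the
  whole pipeline is testable with no external download.

## The statistic

For each PT, a report-level 2×2 table over the two groups gives

    ROR = (a·d) / (b·c),   95% CI = ROR · exp(±1.96·√(1/a + 1/b + 1/c + 1/d))

where `a`/`c` are index/comparator reports with the PT and `b`/`d` without.
If any cell is zero, 0.5 is added to all four cells before both the
estimate and the interval. A PT is a *signal* when the raw index-group count
is ≥ 3, ROR > 1, and the lower CI bound > 1; results rank by lower CI bound
descending. No multiplicity adjustment or Bayesian shrinkage is applied —
outputs are hypothesis-generating reporting signals, not risk estimates.

## Worked example

Replaying one published contingency table — 34 of 559 oral and 12 of 56,947
topical minoxidil reports listing pericardial effusion:

```r
library(faersror)
tab <- contingency_table("PERICARDIAL EFFUSION", 34, 559, 12, 56947)
ror_ci(tab)
#>                     pt  a   b  c     d corrected      ror   ci_low  ci_high
#> 1 PERICARDIAL EFFUSION 34 525 12 56935     FALSE 307.2683 158.2245 596.7079
```

Oral reports name pericardial effusion about 307 times the odds of topical
reports; even the lower confidence bound (158) is far above 1, so the PT
meets the signal rule. The package ships the full reference Core and
Expanded cardiovascular watchlist counts for that cohort:

```r
res <- signals_from_counts(reference_counts("core"))
head(res[, c("pt", "a", "c", "corrected", "ror", "ci_low", "ci_high", "is_signal")], 5)
#>                       pt  a  c corrected      ror   ci_low   ci_high is_signal
#> 1   Pericardial effusion 34 12     FALSE  307.268 158.2245   596.708      TRUE
#> 2    Hypertensive crisis 10  1     FALSE 1037.268 132.5503  8117.101      TRUE
#> 3 Pulmonary hypertension  9  1     FALSE  931.844 117.8529  7367.933      TRUE
#> 4      Cardiac tamponade  8  0      TRUE 1755.408 101.1905 30452.038      TRUE
#> 5  Stress cardiomyopathy  5  0      TRUE 1129.707  62.3893 20456.037      TRUE
```

The `corrected` rows are the zero-comparator-cell PTs whose estimates exist
only via the continuity correction — numerically enormous, with intervals
spanning orders of magnitude, and to be read as sparse-data artifacts of
extreme group imbalance rather than effect sizes.

For a file-level run, `analysis/` contains numbered drivers:
`01_replay_reported_tables.R` (the replay above, plus forest plots),
`02_simulate_cohort.R` (synthetic quarterly files at study-scale),
`03_pipeline_signals.R` (ingest → dedup → classify → cohorts → signals →
summaries), and `04_estimator_properties.R` (CI coverage and estimator
recovery). Outputs land under `results/`.

## Vignette

`vignettes/faersror-methods.Rmd` documents the model and its assumptions,
the classification and cohort conventions, the generator's design and what
it does and does not emulate, and known limitations.
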