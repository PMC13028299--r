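---
title: "Disproportionality signal detection for FAERS-style report data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for FAERS-style report data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersror)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect voluntary reports of suspected drug
reactions. They have no denominator of exposed patients, so they cannot
estimate incidence; what they can support is *disproportionality analysis* —
asking whether an event is reported more often with one exposure than with a
comparator exposure, within the reporting system itself.

`faersror` implements that workflow for formulation-based comparisons, built
around the motivating question of oral versus topical minoxidil and
cardiovascular events. Oral minoxidil is a systemic vasodilator with known
hemodynamic and fluid-retention liabilities (tachycardia, edema, pericardial
effusion); topical minoxidil is used for alopecia with minimal systemic
exposure. Comparing the two formulations' reporting patterns within one
database gives a pharmacological contrast while holding the reporting system
constant — at the cost of severe confounding by indication, which the
sensitivity-cohort machinery below partially addresses.

## The statistic

For each MedDRA Preferred Term (PT) the package forms a report-level 2×2
table over the two exposure groups:

|              | event | no event |
|--------------|-------|----------|
| index (oral) | a     | b        |
| comparator   | c     | d        |

The reporting odds ratio is ROR = (a·d)/(b·c), with the Woolf (log-normal)
95% confidence interval

ROR × exp(±z·√(1/a + 1/b + 1/c + 1/d)),  z = 1.96.

Counting is report-level: a report listing the PT twice contributes one
event. When any cell is zero, 0.5 is added to **all four cells** before both
the point estimate and the interval (`corrected` flag set); the
pre-correction cells are retained because the signal rule operates on raw
counts. A PT is flagged a *signal* when all three hold:

1. a ≥ 3 (raw, pre-correction index-group events),
2. ROR > 1,
3. lower 95% CI bound > 1.

Results are ranked by the lower CI bound, descending, with alphabetical
tie-breaks — a sparse-data-stable ordering that a point-estimate ranking is
not. No multiplicity adjustment and no Bayesian shrinkage are applied; the
output is hypothesis-generating, and extreme RORs with tiny comparator
counts (especially continuity-corrected zero-cell rows) should be read as
sparse-data behaviour, not effect sizes. An FDR column can be added by the
user from the emitted tables, but it never alters `is_signal`.

`z = 1.96` (not `qnorm(0.975)` ≈ 1.959964) is the package-wide convention:
it is the convention under which every reference ROR/CI pair shipped in
`inst/extdata/` reproduces to the printed 2 decimal places.

## Pipeline stages and their conventions

**Ingestion.** FAERS quarterly ASCII tables are `$`-delimited with one
header row and no quoting; an embedded `$` cannot occur, so no escaping is
implemented. Headers are validated against the post-2014 column vocabulary:
unknown columns are an error naming the column, and the legacy pre-2012Q4
`ISR` schema is rejected outright rather than half-supported. Lines whose
field count disagrees with the header are quarantined with line numbers,
never dropped silently. Trailing empty fields are preserved.

**Assembly.** Child rows join DEMO by `primaryid`; orphans are quarantined
and warned about. `FDA_DT` is authoritative for the report year. Partial
dates (`YYYYMM`, `YYYY`) degrade to year precision; unparseable dates leave
the date missing but keep the case. Ages convert to years via the unit code
(DEC/YR/MON/WK/DY); ages above 120 years are set missing and logged. Where a
`primaryid` carries several DEMO rows the first is kept and the duplicates
are logged — the public files do not define a winner, so the package fixes a
documented convention rather than guessing intent.

**Deduplication.** Follow-up submissions share a `caseid`; the analysis unit
is the case, represented by its most recent version. "Most recent" is not
further defined by the source convention, so the package orders by
`report_date` first (the direct reading of "most current information"), then
by `primaryid` (numeric when all candidates are numeric, else
lexicographic). Every decision is logged with the rule that fired, so audits
can distinguish date-decided from tie-broken cases. Cross-quarter
follow-ups are handled by deduplicating the merged case set.

**Exposure classification.** A dictionary of route terms, dose-form terms,
and non-informative forms drives a per-drug classifier: the route field is
consulted first (it is the reporter's direct assertion), the dose form only
as fallback; route-vs-form disagreement on side makes the drug a
*conflict*. Report-level aggregation over the report's suspect
minoxidil rows yields ORAL, TOPICAL, BOTH, or UNKNOWN with a
machine-readable `unknown_reason`. Two genuinely open choices were fixed as
follows:

* a single internally conflicting drug yields `UNKNOWN
  (conflicting_route_vs_form)`, not BOTH — BOTH is reserved for clean
  evidence of both sides (possible dual exposure), keeping the primary
  comparison free of records whose route assertion contradicts itself;
* a conflicting drug alongside clean single-side evidence still yields
  UNKNOWN unless clean drugs establish both sides, because the conflict
  undermines confidence in the report's route information as a whole.

The shipped word lists (`route_dictionary()`, `minoxidil_lexicon()`) are
deliberately small, editable defaults; the algorithm, not the lexicon, is
the contract, and both are arguments to every classifying function.

**Cohorts.** `cohort_spec()` captures role codes, the report-year window
(2012–2025 by default, the window in which suspect minoxidil reporting is
dense enough for stable estimation), kept exposure labels, and indication
include/exclude PT lists. Filters apply in a fixed order with every
exclusion tallied, so `n_input = n_oral + n_topical + Σ excluded` is an
invariant the tests assert. The year and indication filters touch disjoint
fields and therefore commute; the fixed order only determines which bucket
claims a doubly excludable report. For the alopecia-restricted sensitivity
cohort: the include list is a positive requirement (reports with no
indication record drop out), and a report matching both lists is excluded —
exclusion dominates, the conservative reading for a cohort whose purpose is
removing hypertension-indicated reports.

**Summaries.** Outcome (OUTC) tabulations distinguish `MISSING` (no record)
from `BLANK_ONLY` (record with a blank value); other categories are not
mutually exclusive. They are labelled descriptive-only: outcome capture is
heavily and differentially missing across formulation groups, so these
tallies must not be read comparatively. Demographics use linear-interpolation
quantiles (R type 7) for the median/IQR; age statistics exclude missing
ages.

## The synthetic-data generator

`synth_config()` / `synth_generate()` produce FAERS-like quarterly files
with a per-case ground-truth ledger, so every stage is testable without any
external download. Defaults are the study conditions of the motivating
cohort: 559 oral versus 56,947 topical cases; event probabilities for the
bundled PTs set to that cohort's observed reporting proportions; noise
rates set so that the expected UNKNOWN (≈5.8%) and BOTH (≈0.2%) fractions
match that cohort's descriptive counts; outcome missingness 19% (oral) and
98% (topical); report years 2012–2025 weighted to put roughly 43% of oral
reports at 2022 or later, with a 2019 peak. Follow-up versions (15% of
cases, 1–2 extras) share the `caseid` and carry strictly earlier dates and
lower `primaryid`s, so deduplication must recover exactly the ledger's kept
versions.

The ledger records both the *planted* group and the *expected* label after
noise injection, making the classifier testable at 100% accuracy on both
clean and noisy data — the noise is known, not adversarial. What the
generator does **not** emulate: free-text drug-name misspellings, verbatim
dose text, real MedDRA coding drift, correlated events within reports,
reporter-type effects, and duplicate cases with *different* `caseid`s. A
pipeline that is exact on this synthetic data can still misclassify real
FAERS records; the generator validates the machinery, not the dictionary's
recall on real text.

`implied_true_or()` returns the population odds ratio the rates induce,
(p₁/(1−p₁))/(p₂/(1−p₂)), which anchors the estimator-recovery and CI
coverage tests.

## Numerical and testing choices

* Estimates agree with an independently written Woolf implementation to
  10⁻⁹ relative error over randomized tables; group swap maps ROR to its
  reciprocal exactly and swaps the CI bounds.
* Empirical 95% CI coverage over 2,000 replicates of a moderate-OR scenario
  (true OR ≈ 3.6, 600 vs 5,000 reports) sits within [93%, 97%].
* Log-ROR recovery bias through the full file-level pipeline shrinks with
  cohort size (checked at 80/500 versus 640/4,000 reports, 12 replicates
  each); test problem sizes throughout are a few hundred to a few thousand
  synthetic cases, which keeps the default suite under a minute while still
  exercising every stage at realistic imbalance ratios.
* Degenerate inputs are errors, not NAs: negative cells, event counts above
  denominators, empty watchlists, empty lexicons, cohorts without the
  requested group.

## Limitations

Everything a spontaneous-reporting analysis cannot do, this package also
cannot do: no incidence, no relative risk, no causal contrast. The ROR
inherits reporting biases (stimulated reporting, the Weber effect),
confounding by indication beyond what indication restriction removes, and
sparse-data instability under extreme group imbalance. The continuity
correction makes zero-cell RORs *estimable*, not *stable*; their confidence
intervals span orders of magnitude and should be presented as such. The
exposure classifier is rule-based and unvalidated against chart review;
excluding BOTH/UNKNOWN trades misclassification for possible selection
bias — both are surfaced in the exclusion accounting rather than hidden.
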