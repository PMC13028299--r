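# Independent odds-ratio + Woolf-CI oracle, written against the textbook
# definitions and kept deliberately separate from the package's code path:
# odds computed per group, variance accumulated cell by cell. Uses the same
# z = 1.96 convention the method defines.
oracle_woolf <- function(a, b, c, d, z = 1.96, corr = 0.5) {
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + corr
  odds_index <- cells[1] / cells[2]
  odds_comp <- cells[3] / cells[4]
  or <- odds_index / odds_comp
  v <- 0
  for (x in cells) v <- v + 1 / x
  list(or = or,
       lo = exp(log(or) - z * sqrt(v)),
       hi = exp(log(or) + z * sqrt(v)))
}

# Cell-wise table constructor (a, b, c, d) over the exported surface.
ct4 <- function(a, b, c, d) contingency_table("X", a, a + b, c, c + d)

# Small synthetic dataset helper: noise-free unless rates are passed.
quiet_config <- function(n_oral = 60, n_topical = 300, seed = 11, ...) {
  synth_config(
    n_oral = n_oral, n_topical = n_topical,
    duplicate_version_rate = 0,
    route_missing_rate = 0, form_noninformative_rate = 0,
    conflict_rate = 0, dual_exposure_rate = 0,
    seed = seed, ...)
}

run_pipeline <- function(gen) {
  cases <- assemble_cases(gen$tables)
  dd <- deduplicate_cases(cases)
  calls <- classify_exposure(dd$cases)
  list(cases = dd$cases, calls = calls,
       cohort = build_cohort(dd$cases, calls, cohort_spec()))
}
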