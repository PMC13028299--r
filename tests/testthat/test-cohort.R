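noisy_gen <- function(seed = 31) {
  synth_generate(synth_config(
    n_oral = 120, n_topical = 500, seed = seed,
    route_missing_rate = 0.1, form_noninformative_rate = 0.5,
    conflict_rate = 0.02, dual_exposure_rate = 0.02,
    year_weights = setNames(c(1, 2, 3, 4), as.character(2010:2013))))
}

test_that("cohort partitions the input and matches the generator ledger", {
  gen <- noisy_gen()
  pl <- run_pipeline(gen)
  co <- pl$cohort
  expect_equal(co$n_input,
               length(co$oral_ids) + length(co$topical_ids) +
                 sum(co$excluded_counts))
  led <- gen$ledger
  in_window <- led$year >= 2012 & led$year <= 2025
  expect_equal(length(co$oral_ids),
               sum(led$expected_label == "ORAL" & in_window))
  expect_equal(length(co$topical_ids),
               sum(led$expected_label == "TOPICAL" & in_window))
  expect_equal(unname(co$excluded_counts["out_of_window"]), sum(!in_window))
  expect_length(intersect(co$oral_ids, co$topical_ids), 0)
})

test_that("role, window, and indication filters exclude with full accounting", {
  gen <- synth_generate(quiet_config(n_oral = 50, n_topical = 200, seed = 37))
  cases <- deduplicate_cases(assemble_cases(gen$tables))$cases
  calls <- classify_exposure(cases)

  sens <- cohort_spec(indication_include = alopecia_terms(),
                      indication_exclude = hypertension_terms())
  co <- build_cohort(cases, calls, sens)
  led <- gen$ledger
  keep <- led$indication %in% alopecia_terms()  # include required, excl dominates
  expect_equal(length(co$oral_ids), sum(keep & led$true_group == "ORAL"))
  expect_equal(length(co$topical_ids), sum(keep & led$true_group == "TOPICAL"))
  expect_equal(unname(co$excluded_counts["indication_filtered"]), sum(!keep))

  # narrow year window
  co2 <- build_cohort(cases, calls, cohort_spec(year_min = 2020, year_max = 2021))
  expect_equal(length(co2$oral_ids) + length(co2$topical_ids),
               sum(led$year %in% 2020:2021))

  expect_error(cohort_spec(role_codes = character(0)), "non-empty")
  expect_error(cohort_spec(year_min = 2025, year_max = 2012), "year_min")
})

test_that("a report matching include and exclude lists is excluded", {
  demo <- tibble::tibble(primaryid = c("1", "2"), caseid = c("1", "2"),
                         report_date = as.Date("2020-05-01"),
                         report_year = 2020L, age_yr = NA_real_, sex = "UNK")
  cases <- structure(list(
    demo = demo,
    drugs = tibble::tibble(primaryid = c("1", "2"), role_cod = "PS",
                           drugname = "MINOXIDIL", prod_ai = "", route = "ORAL",
                           dose_form = "", dose_vbm = ""),
    reactions = tibble::tibble(primaryid = character(0), pt = character(0)),
    indications = tibble::tibble(primaryid = c("1", "1", "2"),
                                 indi_pt = c("ALOPECIA", "HYPERTENSION", "ALOPECIA")),
    outcomes = tibble::tibble(primaryid = character(0), outc_cod = character(0)),
    quarantine = list(), audit = list()), class = "faers_cases")
  calls <- classify_exposure(cases)
  co <- build_cohort(cases, calls, cohort_spec(
    indication_include = alopecia_terms(),
    indication_exclude = hypertension_terms()))
  expect_equal(co$oral_ids, "2")
  expect_equal(unname(co$excluded_counts["indication_filtered"]), 1L)
})

test_that("indication and exposure filters commute", {
  gen <- noisy_gen(seed = 41)
  pl <- run_pipeline(gen)
  spec <- cohort_spec(indication_include = alopecia_terms(),
                      indication_exclude = hypertension_terms())
  direct <- build_cohort(pl$cases, pl$calls, spec)
  # exposure-filter first: restrict calls to ORAL/TOPICAL, then indication
  pre <- pl$calls[pl$calls$label %in% c("ORAL", "TOPICAL"), , drop = FALSE]
  swapped <- build_cohort(pl$cases, pre, spec)
  expect_setequal(direct$oral_ids, swapped$oral_ids)
  expect_setequal(direct$topical_ids, swapped$topical_ids)
})

test_that("yearly counts and the recent-share statistic", {
  demo <- tibble::tibble(
    primaryid = as.character(1:5), caseid = as.character(1:5),
    report_date = as.Date(c("2019-01-01", "2019-05-01", "2019-09-01",
                            "2022-02-01", NA)),
    report_year = c(2019L, 2019L, 2019L, 2022L, NA),
    age_yr = NA_real_, sex = "UNK")
  cases <- structure(list(
    demo = demo,
    drugs = tibble::tibble(primaryid = as.character(1:5), role_cod = "PS",
                           drugname = "MINOXIDIL", prod_ai = "", route = "ORAL",
                           dose_form = "", dose_vbm = ""),
    reactions = tibble::tibble(primaryid = character(0), pt = character(0)),
    indications = tibble::tibble(primaryid = character(0), indi_pt = character(0)),
    outcomes = tibble::tibble(primaryid = character(0), outc_cod = character(0)),
    quarantine = list(), audit = list()), class = "faers_cases")
  calls <- classify_exposure(cases)
  co <- build_cohort(cases, calls, cohort_spec())
  yc <- yearly_counts(co, "ORAL", since_year = 2022)
  expect_equal(yc$counts$year, c(2019L, 2022L))
  expect_equal(yc$counts$n, c(3L, 1L))
  expect_equal(yc$share_since, 0.25)
  expect_equal(yc$n_missing_year, 0L)  # NA-year report was excluded upstream

  empty <- build_cohort(cases, calls, cohort_spec(year_min = 1990, year_max = 1991))
  expect_equal(nrow(yearly_counts(empty, "ORAL")$counts), 0L)
})
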