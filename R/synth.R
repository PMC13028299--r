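#' Configuration for the synthetic FAERS-like generator
#'
#' Defaults emulate the oral-versus-topical minoxidil study conditions: a
#' heavily imbalanced cohort (559 oral vs 56,947 topical reports), event
#' probabilities for representative cardiovascular Preferred Terms set to the
#' observed reporting proportions, follow-up versions for a fraction of
#' cases, route/dose-form missingness and conflicts at realistic low rates,
#' alopecia-dominated indications with hypertension indications concentrated
#' in the oral group, outcome missingness far heavier for topical reports,
#' and report years spanning 2012--2025 with reporting concentrated in
#' recent years.
#'
#' @param n_oral,n_topical Number of oral / topical cases.
#' @param pt_rates Named list: Preferred Term -> `c(p_oral, p_topical)` event
#'   probabilities per report.
#' @param duplicate_version_rate Fraction of cases receiving 1--2 extra
#'   earlier versions (follow-up submissions).
#' @param route_missing_rate Fraction of minoxidil drug rows with a blank
#'   route (the dose form then carries the evidence).
#' @param form_noninformative_rate Given a blank route, fraction whose dose
#'   form is also non-informative (report becomes UNKNOWN).
#' @param conflict_rate Fraction of reports given an internally conflicting
#'   minoxidil row (route and form on opposite sides).
#' @param dual_exposure_rate Fraction of reports given a second minoxidil
#'   drug on the other side (classified BOTH).
#' @param indication_mix Named list per group: term -> probability; the
#'   reserved name `NONE` means no indication record.
#' @param outcome_missing_rate Named vector: per-group probability that a
#'   report has no OUTC record.
#' @param outcome_blank_rate Probability that an existing OUTC record has a
#'   blank outcome value.
#' @param year_weights Named numeric: report year -> sampling weight.
#' @param seed Integer; mandatory, all randomness is reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(
    n_oral = 559L, n_topical = 56947L,
    pt_rates = list(
      "PERICARDIAL EFFUSION" = c(34 / 559, 12 / 56947),
      "TACHYCARDIA"          = c(21 / 559, 23 / 56947),
      "HYPOTENSION"          = c(23 / 559, 52 / 56947),
      "HYPERTENSION"         = c(27 / 559, 77 / 56947),
      "HEADACHE"             = c(0.05, 0.05)),
    duplicate_version_rate = 0.15,
    route_missing_rate = 0.12,
    form_noninformative_rate = 0.45,
    conflict_rate = 0.004,
    dual_exposure_rate = 0.002,
    indication_mix = list(
      ORAL = c("ALOPECIA" = 0.40, "ANDROGENETIC ALOPECIA" = 0.15,
               "HYPERTENSION" = 0.25, "NONE" = 0.20),
      TOPICAL = c("ALOPECIA" = 0.55, "ANDROGENETIC ALOPECIA" = 0.30,
                  "HYPERTENSION" = 0.002, "NONE" = 0.148)),
    outcome_missing_rate = c(ORAL = 0.19, TOPICAL = 0.98),
    outcome_blank_rate = 0.02,
    year_weights = stats::setNames(
      c(1, 1, 1, 2, 2, 3, 4, 8, 5, 4, 8, 7, 6, 5), as.character(2012:2025)),
    seed = 1L) {
  probs <- unlist(pt_rates)
  stopifnot(all(probs >= 0 & probs <= 1), n_oral > 0, n_topical > 0,
            !is.null(seed))
  for (g in names(indication_mix)) {
    indication_mix[[g]] <- indication_mix[[g]] / sum(indication_mix[[g]])
  }
  structure(list(
    n_oral = as.integer(n_oral), n_topical = as.integer(n_topical),
    pt_rates = pt_rates,
    duplicate_version_rate = duplicate_version_rate,
    route_missing_rate = route_missing_rate,
    form_noninformative_rate = form_noninformative_rate,
    conflict_rate = conflict_rate,
    dual_exposure_rate = dual_exposure_rate,
    indication_mix = indication_mix,
    outcome_missing_rate = outcome_missing_rate,
    outcome_blank_rate = outcome_blank_rate,
    year_weights = year_weights,
    seed = as.integer(seed)), class = "synth_config")
}

#' True odds ratio implied by the generator's event rates
#'
#' For a Preferred Term with per-report event probabilities `p_oral` and
#' `p_topical`, the population reporting odds ratio the generator induces is
#' `(p_o/(1-p_o)) / (p_t/(1-p_t))`.
#'
#' @param config A [synth_config()].
#' @param pt Preferred Term present in `config$pt_rates`.
#' @return The implied odds ratio.
#' @export
implied_true_or <- function(config, pt) {
  if (!pt %in% names(config$pt_rates)) stop("pt not in pt_rates: ", pt)
  p <- config$pt_rates[[pt]]
  if (any(p <= 0 | p >= 1)) stop("event probabilities must be in (0, 1)")
  (p[1] / (1 - p[1])) / (p[2] / (1 - p[2]))
}

#' Generate a synthetic FAERS-like dataset with a ground-truth ledger
#'
#' Draws per-case truth (exposure group, Preferred-Term events, indication,
#' year, demographics, outcomes), injects route/form missingness, conflicts,
#' dual exposures and follow-up versions at the configured rates, and
#' materializes the five quarterly-style tables. The ledger records, per
#' case, the planted truth and the exposure label the classifier is expected
#' to produce given the injected noise, so every downstream stage can be
#' checked against known answers.
#'
#' Follow-up versions share the `caseid`, carry an earlier `FDA_DT` and a
#' lower `primaryid` than the kept version, and duplicate the child rows, so
#' deduplication must recover exactly the ledger's `kept_primaryid`s.
#'
#' @param config A [synth_config()].
#' @param out_dir Optional directory; when given, the five tables are written
#'   as `$`-delimited ASCII via [write_faers_table()].
#' @return List with `tables` (named list of character tibbles:
#'   `demo`, `drug`, `reac`, `indi`, `outc`) and `ledger` (one row per case:
#'   `caseid`, `kept_primaryid`, `n_versions`, `true_group`,
#'   `expected_label`, `expected_unknown_reason`, `indication`, `year`,
#'   plus one logical column per Preferred Term in `pt_rates`).
#' @export
synth_generate <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)

  n <- config$n_oral + config$n_topical
  group <- c(rep("ORAL", config$n_oral), rep("TOPICAL", config$n_topical))
  caseid <- as.character(seq_len(n) + 1000L)

  pts <- names(config$pt_rates)
  pt_flags <- sapply(pts, function(p) {
    pr <- ifelse(group == "ORAL", config$pt_rates[[p]][1], config$pt_rates[[p]][2])
    stats::runif(n) < pr
  })
  if (n == 1L) pt_flags <- matrix(pt_flags, nrow = 1, dimnames = list(NULL, pts))

  years <- as.integer(sample(names(config$year_weights), n, replace = TRUE,
                             prob = config$year_weights))
  month <- sample(1:12, n, replace = TRUE)
  day <- sample(1:28, n, replace = TRUE)
  fda_dt <- sprintf("%04d%02d%02d", years, month, day)

  ind <- character(n)
  for (g in names(config$indication_mix)) {
    m <- config$indication_mix[[g]]
    sel <- group == g
    ind[sel] <- sample(names(m), sum(sel), replace = TRUE, prob = m)
  }

  sex <- ifelse(group == "ORAL",
                sample(c("F", "M", ""), n, replace = TRUE, prob = c(.38, .49, .13)),
                sample(c("F", "M", ""), n, replace = TRUE, prob = c(.43, .48, .09)))
  age_missing <- stats::runif(n) < ifelse(group == "ORAL", 0.225, 0.725)
  age <- round(pmin(100, pmax(1, stats::rnorm(
    n, mean = ifelse(group == "ORAL", 47, 58),
    sd = ifelse(group == "ORAL", 25, 18)))))
  age_chr <- ifelse(age_missing, "", as.character(age))
  age_cod <- ifelse(age_missing, "", "YR")

  # exposure evidence noise
  u_conflict <- stats::runif(n) < config$conflict_rate
  u_dual <- !u_conflict & stats::runif(n) < config$dual_exposure_rate
  u_route_missing <- stats::runif(n) < config$route_missing_rate
  u_form_noninf <- stats::runif(n) < config$form_noninformative_rate
  u_form_blank <- stats::runif(n) < 0.5  # noninformative split: blank vs UNKNOWN

  expected_label <- group
  expected_reason <- rep("none", n)
  expected_label[u_dual] <- "BOTH"
  expected_label[u_conflict] <- "UNKNOWN"
  expected_reason[u_conflict] <- "conflicting_route_vs_form"
  unk <- !u_conflict & !u_dual & u_route_missing & u_form_noninf
  expected_label[unk] <- "UNKNOWN"
  expected_reason[unk] <- ifelse(u_form_blank[unk], "missing_route_and_form",
                                 "noninformative_form")

  # versions: kept primaryid is highest; earlier versions get lower ids/dates
  n_extra <- ifelse(stats::runif(n) < config$duplicate_version_rate,
                    sample(1:2, n, replace = TRUE), 0L)
  base_id <- 1000000L + seq_len(n) * 10L
  kept_primaryid <- as.character(base_id + n_extra)

  ml <- config$outcome_missing_rate
  outc_missing <- stats::runif(n) < ifelse(group == "ORAL", ml[["ORAL"]],
                                           ml[["TOPICAL"]])
  outc_blank <- !outc_missing & stats::runif(n) < config$outcome_blank_rate
  outc_pool <- c("HO", "OT", "DE", "LT", "DS", "RI", "CA")
  outc_w <- c(.35, .4, .08, .06, .05, .04, .02)
  outc_code1 <- sample(outc_pool, n, replace = TRUE, prob = outc_w)
  outc_code2 <- sample(outc_pool, n, replace = TRUE, prob = outc_w)
  outc_two <- stats::runif(n) < 0.3 & outc_code2 != outc_code1

  # per-case content (identical across that case's versions)
  role <- sample(c("PS", "SS"), n, replace = TRUE, prob = c(.85, .15))
  oral_side <- group == "ORAL"
  dual_side <- ifelse(oral_side, "TOPICAL", "ORAL")
  clean_form_oral <- sample(c("TABLET", ""), n, replace = TRUE)
  clean_form_top <- sample(c("FOAM", "5% SOLUTION", ""), n, replace = TRUE,
                           prob = c(.3, .3, .4))
  route1 <- ifelse(u_conflict | !u_route_missing,
                   ifelse(oral_side, "ORAL", "TOPICAL"), "")
  route1[u_dual] <- ifelse(oral_side[u_dual], "ORAL", "TOPICAL")
  form1 <- ifelse(u_conflict, ifelse(oral_side, "FOAM", "TABLET"),
           ifelse(u_route_missing & u_form_noninf,
                  ifelse(u_form_blank, "", "UNKNOWN"),
           ifelse(u_route_missing,
                  ifelse(oral_side, "TABLET", "5% SOLUTION"),
                  ifelse(oral_side, clean_form_oral, clean_form_top))))
  # dual-exposure reports carry two clean minoxidil rows, one per side
  form1[u_dual] <- ifelse(oral_side[u_dual], clean_form_oral[u_dual],
                          clean_form_top[u_dual])
  drugname1 <- ifelse(oral_side, "MINOXIDIL", "MINOXIDIL 5% TOPICAL SOLUTION")
  bg_pts <- c("HYPERTRICHOSIS", "PRURITUS", "RASH", "FATIGUE")
  bg_pt <- sample(bg_pts, n, replace = TRUE)
  has_conmed <- seq_len(n) %% 7L == 0L

  # expand cases to report versions
  nv <- n_extra + 1L
  idx <- rep(seq_len(n), nv)            # case index per report-version row
  vno <- sequence(nv)                    # 1..k within case
  pid <- as.character(base_id[idx] + vno - 1L)
  d0 <- as.Date(fda_dt, format = "%Y%m%d")
  step <- sample(30:120, length(idx), replace = TRUE)
  v_date <- format(d0[idx] - (nv[idx] - vno) * step, "%Y%m%d")

  demo_tab <- tibble::tibble(
    primaryid = pid, caseid = caseid[idx], fda_dt = v_date,
    age = age_chr[idx], age_cod = age_cod[idx], sex = sex[idx])

  drug_main <- tibble::tibble(
    primaryid = pid, caseid = caseid[idx], drug_seq = "1",
    role_cod = role[idx], drugname = drugname1[idx], prod_ai = "MINOXIDIL",
    route = route1[idx], dose_form = form1[idx], dose_vbm = "")
  dual_rows <- idx[u_dual[idx]]
  drug_dual <- tibble::tibble(
    primaryid = pid[u_dual[idx]], caseid = caseid[dual_rows], drug_seq = "2",
    role_cod = role[dual_rows],
    drugname = ifelse(dual_side[dual_rows] == "ORAL", "MINOXIDIL",
                      "MINOXIDIL 5% TOPICAL SOLUTION"),
    prod_ai = rep("MINOXIDIL", length(dual_rows)),
    route = dual_side[dual_rows],
    dose_form = ifelse(dual_side[dual_rows] == "ORAL", "TABLET", "FOAM"),
    dose_vbm = rep("", length(dual_rows)))
  drug_dual$drugname <- as.character(drug_dual$drugname)
  drug_dual$dose_form <- as.character(drug_dual$dose_form)
  con_rows <- idx[has_conmed[idx]]
  drug_con <- tibble::tibble(
    primaryid = pid[has_conmed[idx]], caseid = caseid[con_rows],
    drug_seq = rep("9", length(con_rows)), role_cod = rep("C", length(con_rows)),
    drugname = rep("BIOTIN", length(con_rows)),
    prod_ai = rep("BIOTIN", length(con_rows)),
    route = rep("ORAL", length(con_rows)),
    dose_form = rep("TABLET", length(con_rows)),
    dose_vbm = rep("", length(con_rows)))
  drug_tab <- dplyr::bind_rows(drug_main, drug_dual, drug_con)

  reac_parts <- lapply(pts, function(p) {
    hit <- pt_flags[idx, p]
    tibble::tibble(primaryid = pid[hit], caseid = caseid[idx[hit]], pt = p)
  })
  reac_tab <- dplyr::bind_rows(
    c(reac_parts,
      list(tibble::tibble(primaryid = pid, caseid = caseid[idx],
                          pt = bg_pt[idx]))))

  has_ind <- ind[idx] != "NONE"
  indi_tab <- tibble::tibble(
    primaryid = pid[has_ind], caseid = caseid[idx[has_ind]],
    indi_drug_seq = "1", indi_pt = ind[idx[has_ind]])

  has_outc <- !outc_missing[idx]
  oc1 <- tibble::tibble(
    primaryid = pid[has_outc], caseid = caseid[idx[has_outc]],
    outc_cod = ifelse(outc_blank[idx[has_outc]], "", outc_code1[idx[has_outc]]))
  two <- has_outc & !outc_blank[idx] & outc_two[idx]
  oc2 <- tibble::tibble(primaryid = pid[two], caseid = caseid[idx[two]],
                        outc_cod = outc_code2[idx[two]])
  outc_tab <- dplyr::bind_rows(oc1, oc2)

  tables <- list(demo = demo_tab, drug = drug_tab, reac = reac_tab,
                 indi = indi_tab, outc = outc_tab)

  ledger <- tibble::tibble(
    caseid = caseid, kept_primaryid = kept_primaryid,
    n_versions = n_extra + 1L, true_group = group,
    expected_label = expected_label,
    expected_unknown_reason = expected_reason,
    indication = ind, year = years,
    outc_missing = outc_missing, outc_blank_only = outc_blank)
  for (p in pts) ledger[[p]] <- pt_flags[, p]

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(tables)) {
      write_faers_table(tables[[nm]],
                        file.path(out_dir, paste0(toupper(nm), ".txt")))
    }
  }
  list(tables = tables, ledger = ledger)
}
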