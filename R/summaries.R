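.outc_labels <- c(DE = "Death", HO = "Hospitalization", LT = "Life-Threatening",
                  DS = "Disability", CA = "Congenital Anomaly",
                  RI = "Required Intervention", OT = "Other Serious")

#' Tabulate patient outcome (OUTC) codes by exposure group
#'
#' Descriptive only: outcome fields in spontaneous reports are heavily and
#' differentially missing, so these tallies must never be read as comparative
#' severity. Categories other than `MISSING`/`BLANK_ONLY` are not mutually
#' exclusive (a report can carry several codes). `MISSING` means the report
#' has no OUTC record at all; `BLANK_ONLY` means OUTC records exist but every
#' outcome value is blank. Percentages are over the group denominator.
#'
#' @param cohort A `faers_cohort`.
#' @return Tibble: `group`, `category`, `n`, `pct`, plus a
#'   `descriptive_only` note column.
#' @export
summarize_outcomes <- function(cohort) {
  oc <- cohort$cases$outcomes
  rows <- list()
  for (g in cohort$spec$keep_labels) {
    ids <- cohort_ids(cohort, g)
    denom <- length(ids)
    sub <- oc[oc$primaryid %in% ids, , drop = FALSE]
    has_rec <- unique(sub$primaryid)
    nonblank <- sub[nzchar(sub$outc_cod), , drop = FALSE]
    has_code <- unique(nonblank$primaryid)
    n_cat <- vapply(names(.outc_labels), function(code) {
      length(unique(nonblank$primaryid[nonblank$outc_cod == code]))
    }, integer(1))
    n_blank_only <- length(setdiff(has_rec, has_code))
    n_missing <- denom - length(has_rec)
    n <- c(n_cat, BLANK_ONLY = n_blank_only, MISSING = n_missing)
    rows[[g]] <- tibble::tibble(
      group = g, category = names(n), n = as.integer(n),
      pct = if (denom > 0) 100 * n / denom else NA_real_)
  }
  out <- dplyr::bind_rows(rows)
  out$descriptive_only <- TRUE
  out
}

#' Demographic and reporting characteristics by exposure group
#'
#' Sex counts and percentages, age missingness, age median (IQR) and
#' mean (SD) computed over non-missing ages only, and the report-year range
#' and median. Quantiles use linear interpolation (R's default type 7).
#'
#' @param cohort A `faers_cohort`.
#' @return Tibble with one row per exposure group.
#' @export
summarize_demographics <- function(cohort) {
  demo <- cohort$cases$demo
  rows <- lapply(cohort$spec$keep_labels, function(g) {
    ids <- cohort_ids(cohort, g)
    d <- demo[match(ids, demo$primaryid), , drop = FALSE]
    n <- nrow(d)
    age <- d$age_yr[!is.na(d$age_yr)]
    yrs <- d$report_year[!is.na(d$report_year)]
    q <- if (length(age) > 0) stats::quantile(age, c(.25, .5, .75), type = 7)
         else rep(NA_real_, 3)
    tibble::tibble(
      group = g, n = n,
      n_female = sum(d$sex == "F"), pct_female = 100 * mean(d$sex == "F"),
      n_male = sum(d$sex == "M"), pct_male = 100 * mean(d$sex == "M"),
      n_sex_unknown = sum(d$sex == "UNK"),
      n_age_missing = sum(is.na(d$age_yr)),
      pct_age_missing = 100 * mean(is.na(d$age_yr)),
      age_median = q[[2]], age_q1 = q[[1]], age_q3 = q[[3]],
      age_mean = if (length(age) > 0) mean(age) else NA_real_,
      age_sd = if (length(age) > 1) stats::sd(age) else NA_real_,
      year_min = if (length(yrs) > 0) min(yrs) else NA_integer_,
      year_max = if (length(yrs) > 0) max(yrs) else NA_integer_,
      year_median = if (length(yrs) > 0) stats::median(yrs) else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Forest plot of top signals on a log ROR scale
#'
#' Takes the output of [detect_signals()] or [signals_from_counts()], keeps
#' the `top_n` rows by lower confidence bound (the ranking those functions
#' already emit), and draws point estimates with CI whiskers on a log10 x
#' axis with a reference line at ROR = 1.
#'
#' @param signals Signal tibble with `pt`, `ror`, `ci_low`, `ci_high`.
#' @param top_n Number of leading rows to draw.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_forest <- function(signals, top_n = 20L, title = "Disproportionality signals") {
  if (nrow(signals) == 0L) stop("no signals to plot")
  df <- rank_signals(signals)
  df <- utils::head(df, top_n)
  df$pt <- factor(df$pt, levels = rev(df$pt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$pt)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (log scale)", y = NULL,
                  title = title) +
    ggplot2::theme_minimal()
}
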