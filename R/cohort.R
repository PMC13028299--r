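#' Declarative cohort specification
#'
#' Captures the filters that turn a deduplicated case set plus exposure calls
#' into an analysis cohort: drug role codes, report-year window, exposure
#' labels kept for comparison, and optional indication include/exclude term
#' lists (exact Preferred-Term match after uppercase normalization).
#'
#' An empty include list means no indication restriction. When the include
#' list is non-empty it is a positive requirement: reports with no indication
#' record are dropped. A report matching both lists is excluded -- exclusion
#' dominates, the conservative reading for a confounding-by-indication
#' sensitivity cohort.
#'
#' @param role_codes Drug role codes defining suspect status.
#' @param year_min,year_max Report-year window (from `FDA_DT`).
#' @param keep_labels Exposure labels entering the comparison.
#' @param indication_include,indication_exclude Preferred-Term lists.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(role_codes = c("PS", "SS"),
                        year_min = 2012L, year_max = 2025L,
                        keep_labels = c("ORAL", "TOPICAL"),
                        indication_include = character(0),
                        indication_exclude = character(0)) {
  if (length(role_codes) == 0L) stop("role_codes must be non-empty")
  if (length(keep_labels) == 0L) stop("keep_labels must be non-empty")
  if (year_min > year_max) stop("year_min must be <= year_max")
  structure(list(role_codes = toupper(role_codes),
                 year_min = as.integer(year_min),
                 year_max = as.integer(year_max),
                 keep_labels = toupper(keep_labels),
                 indication_include = toupper(trimws(indication_include)),
                 indication_exclude = toupper(trimws(indication_exclude))),
            class = "cohort_spec")
}

#' Default alopecia / hypertension indication term lists
#'
#' Starting points for the indication-restricted sensitivity cohort; both are
#' plain character vectors meant to be edited.
#' @name indication_terms
#' @return Character vector of uppercase Preferred Terms.
#' @export
alopecia_terms <- function() {
  c("ALOPECIA", "ANDROGENETIC ALOPECIA", "ALOPECIA AREATA",
    "ALOPECIA TOTALIS", "ALOPECIA UNIVERSALIS", "HAIR LOSS",
    "TELOGEN EFFLUVIUM")
}

#' @rdname indication_terms
#' @export
hypertension_terms <- function() {
  c("HYPERTENSION", "ESSENTIAL HYPERTENSION", "BLOOD PRESSURE INCREASED",
    "HYPERTENSIVE CRISIS", "HYPERTENSIVE EMERGENCY", "BLOOD PRESSURE ABNORMAL",
    "RESISTANT HYPERTENSION")
}

#' Build an analysis cohort
#'
#' Applies the spec's filters in a fixed, fully accounted order:
#' suspect-role target-drug restriction, report-year window (reports with no
#' derivable year are excluded and counted separately), indication
#' include/exclude, then exposure label. Every excluded report is tallied so
#' the partition identity `n_input = n_oral + n_topical + sum(excluded)`
#' holds exactly. The year and indication filters touch disjoint fields, so
#' their order cannot change the result; the fixed order only fixes which
#' bucket a doubly excludable report is counted in.
#'
#' @param cases Deduplicated `faers_cases`.
#' @param calls Exposure calls from [classify_exposure()] run with the same
#'   role codes as `spec`.
#' @param spec A [cohort_spec()].
#' @return A `faers_cohort`: list with `spec`, `oral_ids`, `topical_ids`,
#'   `cases` (restricted to kept reports), `excluded_counts` (named integer
#'   vector: `role_filtered`, `out_of_window`, `year_missing`,
#'   `indication_filtered`, `BOTH`, `UNKNOWN`, plus any non-kept label),
#'   and `n_input`.
#' @export
build_cohort <- function(cases, calls, spec = cohort_spec()) {
  stopifnot(inherits(cases, "faers_cases"), inherits(spec, "cohort_spec"))
  if (length(spec$role_codes) == 0L) stop("spec has an empty role set")
  demo <- cases$demo
  n_input <- nrow(demo)
  excl <- c(role_filtered = 0L, out_of_window = 0L, year_missing = 0L,
            indication_filtered = 0L, BOTH = 0L, UNKNOWN = 0L)

  in_calls <- demo$primaryid %in% calls$primaryid
  excl["role_filtered"] <- sum(!in_calls)
  keep <- demo[in_calls, , drop = FALSE]

  yr_ok <- !is.na(keep$report_year) &
    keep$report_year >= spec$year_min & keep$report_year <= spec$year_max
  excl["year_missing"] <- sum(is.na(keep$report_year))
  excl["out_of_window"] <- sum(!yr_ok) - excl["year_missing"]
  keep <- keep[yr_ok, , drop = FALSE]

  if (length(spec$indication_include) > 0L || length(spec$indication_exclude) > 0L) {
    ind <- cases$indications[cases$indications$primaryid %in% keep$primaryid, ]
    has_excl <- unique(ind$primaryid[ind$indi_pt %in% spec$indication_exclude])
    ok <- !(keep$primaryid %in% has_excl)
    if (length(spec$indication_include) > 0L) {
      has_incl <- unique(ind$primaryid[ind$indi_pt %in% spec$indication_include])
      ok <- ok & keep$primaryid %in% has_incl
    }
    excl["indication_filtered"] <- sum(!ok)
    keep <- keep[ok, , drop = FALSE]
  }

  lab <- calls$label[match(keep$primaryid, calls$primaryid)]
  for (l in setdiff(unique(lab), spec$keep_labels)) {
    excl[l] <- sum(lab == l)
  }
  kept_mask <- lab %in% spec$keep_labels
  keep <- keep[kept_mask, , drop = FALSE]
  lab <- lab[kept_mask]

  sub <- cases
  for (nm in c("demo", "drugs", "reactions", "indications", "outcomes")) {
    sub[[nm]] <- sub[[nm]][sub[[nm]]$primaryid %in% keep$primaryid, , drop = FALSE]
  }

  structure(list(
    spec = spec,
    oral_ids = keep$primaryid[lab == "ORAL"],
    topical_ids = keep$primaryid[lab == "TOPICAL"],
    labels = stats::setNames(lab, keep$primaryid),
    cases = sub,
    excluded_counts = excl,
    n_input = n_input), class = "faers_cohort")
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("<faers_cohort> oral: ", length(x$oral_ids),
      "  topical: ", length(x$topical_ids), "\n", sep = "")
  cat("  excluded:", paste(names(x$excluded_counts), x$excluded_counts,
                           sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Group membership helper
#' @param cohort A `faers_cohort`.
#' @param group `"ORAL"` or `"TOPICAL"` (any kept label).
#' @return Character vector of `primaryid`s.
#' @export
cohort_ids <- function(cohort, group) {
  group <- toupper(group)
  if (!group %in% cohort$spec$keep_labels) {
    stop("group '", group, "' is not a kept label of this cohort")
  }
  if (group == "ORAL") cohort$oral_ids
  else if (group == "TOPICAL") cohort$topical_ids
  else names(cohort$labels)[cohort$labels == group]
}

#' Yearly report counts for one exposure group
#'
#' Counts reports by report year (derived from `FDA_DT`); reports whose year
#' could not be derived are listed separately, and the share of reports at or
#' after `since_year` is returned to characterize recent reporting surges.
#'
#' @param cohort A `faers_cohort`.
#' @param group A kept exposure label.
#' @param since_year Year for the cumulative recent-share statistic.
#' @return List with `counts` (tibble `year`, `n`), `n_missing_year`, and
#'   `share_since` (fraction of dated reports with year >= `since_year`).
#' @export
yearly_counts <- function(cohort, group = "ORAL", since_year = 2022L) {
  ids <- cohort_ids(cohort, group)
  yrs <- cohort$cases$demo$report_year[match(ids, cohort$cases$demo$primaryid)]
  dated <- yrs[!is.na(yrs)]
  counts <- if (length(dated) == 0L) {
    tibble::tibble(year = integer(0), n = integer(0))
  } else {
    tb <- table(dated)
    tibble::tibble(year = as.integer(names(tb)), n = as.integer(tb))
  }
  list(counts = counts,
       n_missing_year = sum(is.na(yrs)),
       share_since = if (length(dated) == 0L) NA_real_
                     else mean(dated >= since_year))
}
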