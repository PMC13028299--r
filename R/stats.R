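#' Build the 2x2 contingency table for one Preferred Term
#'
#' Report-level counting: a report listing the PT several times counts once.
#' Cell layout is `a` = index-group (oral) reports with the PT, `b` = without,
#' `c`/`d` the same for the comparator (topical) group, so `a + b` and
#' `c + d` are the group denominators.
#'
#' @param pt Preferred Term (normalized internally).
#' @param cohort A `faers_cohort` with `ORAL` and `TOPICAL` kept.
#' @return A `contingency_table`: list with integer `a`, `b`, `c`, `d` and
#'   the Preferred Term.
#' @export
make_table <- function(pt, cohort) {
  pt <- toupper(trimws(pt))
  rx <- cohort$cases$reactions
  with_pt <- unique(rx$primaryid[rx$pt == pt])
  a <- sum(cohort$oral_ids %in% with_pt)
  c_ <- sum(cohort$topical_ids %in% with_pt)
  new_contingency_table(pt, a, length(cohort$oral_ids) - a,
                        c_, length(cohort$topical_ids) - c_)
}

new_contingency_table <- function(pt, a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("negative cell count")
  structure(list(pt = pt, a = a, b = b, c = c, d = d), class = "contingency_table")
}

#' Construct a contingency table from explicit counts
#'
#' @param pt Preferred Term label.
#' @param a,c Event counts in the index (oral) and comparator (topical) group.
#' @param n_index,n_comparator Group denominators.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(pt, a, n_index, c, n_comparator) {
  if (a > n_index || c > n_comparator) stop("event count exceeds denominator")
  new_contingency_table(pt, a, n_index - a, c, n_comparator - c)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' ROR = (a d)/(b c); the CI is log-normal (Woolf):
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' When any cell is zero, `correction` (default 0.5) is added to all four
#' cells before both the point estimate and the interval, and the result is
#' flagged `corrected`. The pre-correction cells are retained because the
#' signal rule counts raw index-group events.
#'
#' @param table A `contingency_table` (or anything with `a`,`b`,`c`,`d`).
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @param correction Continuity constant added to every cell on a zero cell.
#' @return A one-row tibble: `pt`, raw cells `a`,`b`,`c`,`d`, `corrected`,
#'   `ror`, `ci_low`, `ci_high`.
#' @export
ror_ci <- function(table, z = 1.96, correction = 0.5) {
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells < 0)) stop("negative cell count")
  corrected <- any(cells == 0)
  use <- if (corrected) cells + correction else cells
  ror <- (use[1] * use[4]) / (use[2] * use[3])
  se <- sqrt(sum(1 / use))
  tibble::tibble(
    pt = if (!is.null(table$pt)) table$pt else NA_character_,
    a = cells[1], b = cells[2], c = cells[3], d = cells[4],
    corrected = corrected,
    ror = ror,
    ci_low = exp(log(ror) - z * se),
    ci_high = exp(log(ror) + z * se))
}

#' Screen a Preferred-Term watchlist for disproportionality signals
#'
#' One [ror_ci()] row per term, with the three-part signal rule evaluated on
#' the pre-correction index-group count: at least `min_index_events` events,
#' ROR above 1, and lower CI bound above 1. Results are ranked by lower CI
#' bound, descending (a stabler ordering than the point estimate for sparse
#' cells), ties broken alphabetically by term.
#'
#' @param cohort A `faers_cohort`.
#' @param pt_list Character vector of Preferred Terms (deduplicated
#'   internally; must be non-empty).
#' @param z,correction Passed to [ror_ci()].
#' @param min_index_events Minimum raw index-group events for signal status.
#' @return A tibble of signal results sorted by `ci_low` descending, with an
#'   `is_signal` flag.
#' @export
detect_signals <- function(cohort, pt_list, z = 1.96, correction = 0.5,
                           min_index_events = 3L) {
  if (length(pt_list) == 0L) stop("pt_list must be non-empty")
  pt_list <- unique(toupper(trimws(pt_list)))
  res <- dplyr::bind_rows(lapply(pt_list, function(p) {
    ror_ci(make_table(p, cohort), z = z, correction = correction)
  }))
  rank_signals(flag_signals(res, min_index_events))
}

flag_signals <- function(res, min_index_events = 3L) {
  res$is_signal <- res$a >= min_index_events & res$ror > 1 & res$ci_low > 1
  res
}

rank_signals <- function(res) {
  res[order(-res$ci_low, res$pt), , drop = FALSE]
}

#' Recompute signals from published contingency counts
#'
#' Replays a signal table directly from per-term counts -- the
#' "from-counts" entry point for auditing previously reported reporting
#' odds ratios without the underlying raw reports. Input is one row per
#' Preferred Term with the index-group events/denominator and
#' comparator-group events/denominator.
#'
#' @param counts Data frame with columns `pt`, `oral_events`, `oral_n`,
#'   `topical_events`, `topical_n` (extra columns are carried through).
#' @param z,correction,min_index_events As in [detect_signals()].
#' @return Tibble as from [detect_signals()], ranked by `ci_low` descending.
#' @export
signals_from_counts <- function(counts, z = 1.96, correction = 0.5,
                                min_index_events = 3L) {
  need <- c("pt", "oral_events", "oral_n", "topical_events", "topical_n")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  res <- dplyr::bind_rows(lapply(seq_len(nrow(counts)), function(i) {
    ror_ci(contingency_table(counts$pt[i],
                             counts$oral_events[i], counts$oral_n[i],
                             counts$topical_events[i], counts$topical_n[i]),
           z = z, correction = correction)
  }))
  rank_signals(flag_signals(res, min_index_events))
}
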