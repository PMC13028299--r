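#' Deduplicate multi-version cases to the latest report
#'
#' FAERS distributes follow-up submissions as new report versions sharing a
#' `caseid`; counting every version inflates disproportionality. This keeps
#' one report per case -- the most recent version, taken as the maximum
#' `report_date`, with ties (and missing dates) broken by the maximum
#' `primaryid` (numeric comparison when every contender is numeric, otherwise
#' lexicographic). Follow-ups spanning quarterly files are handled naturally
#' because selection operates on the merged case set.
#'
#' @param cases A `faers_cases` object (see [assemble_cases()]).
#' @return A list with `cases` (a `faers_cases` filtered to the kept
#'   `primaryid`s) and `decisions`, a tibble logging every case:
#'   `caseid`, `kept_primaryid`, `dropped_primaryids` (comma-joined),
#'   `rule_used` (`max_report_date`, `tie_broken`, or `single_version`).
#' @export
deduplicate_cases <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  demo <- cases$demo
  if (any(is.na(demo$caseid) | !nzchar(demo$caseid))) {
    stop("every report must carry a non-empty caseid")
  }

  pick <- function(ids, dates) {
    if (length(ids) == 1L) return(list(keep = ids, rule = "single_version"))
    # order on date; NA dates sort before any real date
    key <- ifelse(is.na(dates), -Inf, as.numeric(dates))
    best <- which(key == max(key))
    if (length(best) == 1L) {
      list(keep = ids[best], rule = "max_report_date")
    } else {
      cand <- ids[best]
      num <- suppressWarnings(as.numeric(cand))
      keep <- if (!anyNA(num)) cand[which.max(num)] else max(cand)
      list(keep = keep, rule = "tie_broken")
    }
  }

  split_idx <- split(seq_len(nrow(demo)), demo$caseid)
  # stable iteration order regardless of input row order
  split_idx <- split_idx[order(names(split_idx))]
  m <- length(split_idx)
  kept <- dropped <- rules <- character(m)
  for (i in seq_len(m)) {
    idx <- split_idx[[i]]
    ids <- demo$primaryid[idx]
    res <- pick(ids, demo$report_date[idx])
    kept[i] <- res$keep
    rules[i] <- res$rule
    dropped[i] <- paste(sort(setdiff(ids, res$keep)), collapse = ",")
  }
  decisions <- tibble::tibble(
    caseid = names(split_idx), kept_primaryid = kept,
    dropped_primaryids = dropped, rule_used = rules)

  kept <- decisions$kept_primaryid
  out <- cases
  for (nm in c("demo", "drugs", "reactions", "indications", "outcomes")) {
    out[[nm]] <- out[[nm]][out[[nm]]$primaryid %in% kept, , drop = FALSE]
  }
  list(cases = out, decisions = decisions)
}
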