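#' Default route / dose-form dictionary
#'
#' The exposure classifier is driven entirely by this dictionary; the rule
#' logic, not the word lists, is the contract. All entries are matched after
#' trimming and case-folding. `topical_form_patterns` are regular expressions
#' for dose forms that only imply a side in combination (a strength-percent
#' solution is a scalp preparation; a plain "SOLUTION" is uninformative).
#'
#' @param oral_routes,topical_routes Route strings asserting a side directly.
#' @param oral_forms,topical_forms Dose-form strings implying a side.
#' @param topical_form_patterns Regexes applied to the normalized dose form.
#' @param noninformative_forms Forms carrying no route information.
#' @return A `route_dictionary` list.
#' @export
route_dictionary <- function(
    oral_routes = c("ORAL", "PO", "BY MOUTH", "ORALLY"),
    topical_routes = c("TOPICAL", "CUTANEOUS", "TRANSDERMAL", "SCALP"),
    oral_forms = c("TABLET", "CAPSULE", "ORAL SOLUTION"),
    topical_forms = c("FOAM", "SPRAY", "LOTION", "GEL", "TOPICAL SOLUTION"),
    topical_form_patterns = "[0-9]+(\\.[0-9]+)?\\s*%.*SOLUTION|SOLUTION.*[0-9]+(\\.[0-9]+)?\\s*%",
    noninformative_forms = c("UNKNOWN", "NOS", "NOT SPECIFIED")) {
  norm <- function(x) toupper(trimws(x))
  d <- list(oral_routes = norm(oral_routes),
            topical_routes = norm(topical_routes),
            oral_forms = norm(oral_forms),
            topical_forms = norm(topical_forms),
            topical_form_patterns = topical_form_patterns,
            noninformative_forms = norm(noninformative_forms))
  if (length(intersect(d$oral_routes, d$topical_routes)) > 0L ||
      length(intersect(d$oral_forms, d$topical_forms)) > 0L) {
    stop("oral and topical dictionary entries must be disjoint")
  }
  structure(d, class = "route_dictionary")
}

#' Default minoxidil name lexicon
#'
#' Generic name plus common brand strings, matched at word boundaries against
#' `drugname` and `prod_ai`. Editable: pass your own character vector to the
#' classification functions for other drugs.
#'
#' @return Character vector of normalized lexicon terms.
#' @export
minoxidil_lexicon <- function() {
  c("MINOXIDIL", "LONITEN", "ROGAINE", "REGAINE")
}

#' Does a drug row name the target drug?
#'
#' Word-boundary containment of any lexicon term in the normalized
#' `drugname` or `prod_ai`, so "MINOXIDIL 5% TOPICAL SOLUTION" matches while
#' "AMINOXIDILLE" does not.
#'
#' @param drugname,prod_ai Character vectors (recycled to common length).
#' @param lexicon Character vector of drug name synonyms; must be non-empty.
#' @return Logical vector.
#' @export
is_target_drug <- function(drugname, prod_ai = "", lexicon = minoxidil_lexicon()) {
  if (length(lexicon) == 0L) stop("drug name lexicon is empty")
  pat <- paste0("\\b(", paste(toupper(trimws(lexicon)), collapse = "|"), ")\\b")
  hay <- toupper(paste(drugname, prod_ai))
  grepl(pat, hay, perl = TRUE)
}

#' Classify one drug row's route evidence
#'
#' The route field is consulted first (it is the reporter's direct
#' assertion); the dose form is a fallback when the route is missing or
#' uninformative. A drug whose route and form point to opposite sides is a
#' `conflict`; one with no usable evidence on either field is
#' `uninformative`.
#'
#' @param route,dose_form Character vectors (recycled).
#' @param dict A [route_dictionary()].
#' @return Character vector over `{"oral","topical","conflict",
#'   "uninformative_missing","uninformative_form"}`; the two uninformative
#'   codes distinguish "both fields blank" from "a form was recorded but
#'   carries no route information".
#' @export
classify_drug_route <- function(route, dose_form, dict = route_dictionary()) {
  n <- max(length(route), length(dose_form))
  route <- rep_len(toupper(trimws(route)), n)
  form <- rep_len(toupper(trimws(dose_form)), n)

  route_side <- rep("none", n)
  route_side[route %in% dict$oral_routes] <- "oral"
  route_side[route %in% dict$topical_routes] <- "topical"

  form_side <- rep("none", n)
  form_side[form %in% dict$oral_forms] <- "oral"
  form_side[form %in% dict$topical_forms] <- "topical"
  pat_hit <- form_side == "none" & nzchar(form) &
    grepl(dict$topical_form_patterns, form, perl = TRUE)
  form_side[pat_hit] <- "topical"

  out <- character(n)
  conflict <- route_side != "none" & form_side != "none" & route_side != form_side
  out[conflict] <- "conflict"
  decided <- !conflict & (route_side != "none" | form_side != "none")
  out[decided] <- ifelse(route_side[decided] != "none",
                         route_side[decided], form_side[decided])
  open <- !nzchar(out)
  out[open] <- ifelse(nzchar(form[open]), "uninformative_form",
                      "uninformative_missing")
  out
}

#' Assign each report an exposure label
#'
#' Aggregates per-drug route evidence over a report's target-drug rows
#' (restricted to the given role codes) into one of four mutually exclusive
#' labels:
#' \describe{
#'   \item{ORAL}{at least one oral-evidence drug and none topical}
#'   \item{TOPICAL}{the mirror image}
#'   \item{BOTH}{clean oral and clean topical evidence across the report's
#'     drugs (possible dual exposure)}
#'   \item{UNKNOWN}{no decisive evidence, with a machine-readable
#'     `unknown_reason`: `conflicting_route_vs_form` when any single drug is
#'     internally contradictory and clean evidence does not already establish
#'     dual exposure, `noninformative_form` when a form was recorded but
#'     carries no route information, `missing_route_and_form` otherwise}
#' }
#' A single internally conflicting drug yields UNKNOWN, not BOTH: BOTH is
#' reserved for evidence split across drugs or clean dual evidence.
#'
#' @param cases A `faers_cases` object.
#' @param dict A [route_dictionary()].
#' @param lexicon Drug name lexicon, see [is_target_drug()].
#' @param roles Role codes whose drug rows count as exposure evidence.
#' @return A tibble with one row per report that has at least one target-drug
#'   row in `roles`: `primaryid`, `label`, `unknown_reason` (`"none"` unless
#'   `label == "UNKNOWN"`), and per-report evidence tallies
#'   (`n_oral_drugs`, `n_topical_drugs`, `n_conflict_drugs`).
#' @export
classify_exposure <- function(cases, dict = route_dictionary(),
                              lexicon = minoxidil_lexicon(),
                              roles = c("PS", "SS")) {
  stopifnot(inherits(cases, "faers_cases"))
  dr <- cases$drugs
  dr <- dr[dr$role_cod %in% roles &
             is_target_drug(dr$drugname, dr$prod_ai, lexicon), , drop = FALSE]
  if (nrow(dr) == 0L) {
    return(tibble::tibble(primaryid = character(0), label = character(0),
                          unknown_reason = character(0),
                          n_oral_drugs = integer(0), n_topical_drugs = integer(0),
                          n_conflict_drugs = integer(0)))
  }
  ev <- classify_drug_route(dr$route, dr$dose_form, dict)
  per <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(primaryid = dr$primaryid, ev = ev),
                    .data$primaryid),
    n_oral_drugs = sum(.data$ev == "oral"),
    n_topical_drugs = sum(.data$ev == "topical"),
    n_conflict_drugs = sum(.data$ev == "conflict"),
    n_uninf_form = sum(.data$ev == "uninformative_form"),
    .groups = "drop")

  label <- with(per, ifelse(
    n_oral_drugs > 0 & n_topical_drugs > 0, "BOTH", ifelse(
      n_conflict_drugs > 0, "UNKNOWN", ifelse(
        n_oral_drugs > 0, "ORAL", ifelse(
          n_topical_drugs > 0, "TOPICAL", "UNKNOWN")))))
  reason <- rep("none", nrow(per))
  unk <- label == "UNKNOWN"
  reason[unk] <- ifelse(
    per$n_conflict_drugs[unk] > 0, "conflicting_route_vs_form", ifelse(
      per$n_uninf_form[unk] > 0, "noninformative_form",
      "missing_route_and_form"))
  tibble::tibble(primaryid = per$primaryid, label = label,
                 unknown_reason = reason,
                 n_oral_drugs = per$n_oral_drugs,
                 n_topical_drugs = per$n_topical_drugs,
                 n_conflict_drugs = per$n_conflict_drugs)
}
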