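#' Reference contingency counts for the minoxidil oral-vs-topical cohort
#'
#' Per-Preferred-Term event counts and group denominators (559 oral /
#' 56,947 topical reports, report years 2012--2025) from the published
#' FAERS minoxidil cardiovascular analysis, for the Core cardiovascular
#' watchlist and the Expanded list (Core plus edema/volume-related terms and
#' dizziness); top 20 terms each, ranked by lower confidence bound. The
#' `*_reported` columns carry the published ROR and 95% CI so recomputation
#' via [signals_from_counts()] can be audited against them.
#'
#' @param list_name `"core"` or `"expanded"`.
#' @return Tibble in the [signals_from_counts()] input layout plus
#'   `ror_reported`, `ci_low_reported`, `ci_high_reported`.
#' @export
reference_counts <- function(list_name = c("core", "expanded")) {
  list_name <- match.arg(list_name)
  path <- system.file("extdata", paste0(list_name, "_pt_counts.csv"),
                      package = "faersror", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = TRUE,
                                    stringsAsFactors = FALSE))
}
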