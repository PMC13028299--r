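#' @importFrom rlang .data
NULL

# Known column vocabulary per table (post-2014 FAERS quarterly schema).
# Columns not listed here cause read_faers_table() to fail loudly: silent
# header drift is how route/dose-form fields get lost.
.faers_columns <- list(
  DEMO = c("primaryid", "caseid", "caseversion", "i_f_code", "event_dt",
           "mfr_dt", "init_fda_dt", "fda_dt", "rept_cod", "auth_num",
           "mfr_num", "mfr_sndr", "lit_ref", "age", "age_cod", "age_grp",
           "sex", "e_sub", "wt", "wt_cod", "rept_dt", "to_mfr", "occp_cod",
           "reporter_country", "occr_country"),
  DRUG = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "prod_ai", "val_vbm", "route", "dose_vbm", "cum_dose_chr",
           "cum_dose_unit", "dechal", "rechal", "lot_num", "exp_dt",
           "nda_num", "dose_amt", "dose_unit", "dose_form", "dose_freq"),
  REAC = c("primaryid", "caseid", "pt", "drug_rec_act"),
  INDI = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
  OUTC = c("primaryid", "caseid", "outc_cod")
)

.faers_required <- list(
  DEMO = c("primaryid", "caseid"),
  DRUG = c("primaryid", "caseid", "drugname"),
  REAC = c("primaryid", "caseid", "pt"),
  INDI = c("primaryid", "caseid", "indi_pt"),
  OUTC = c("primaryid", "caseid", "outc_cod")
)

#' Read one FAERS-style quarterly ASCII table
#'
#' Parses a `$`-delimited FAERS quarterly file (one header row, no quoting or
#' escaping -- the public FAERS convention; a literal `$` cannot occur inside a
#' field). Trailing empty fields are preserved. Lines whose field count does
#' not match the header are collected with their line numbers and reported via
#' a warning, never silently dropped.
#'
#' @param path Path to the ASCII file.
#' @param table_name One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"INDI"`, `"OUTC"`.
#' @return A tibble with the file's columns (all character; empty string means
#'   missing), one row per well-formed data line. Malformed lines, if any, are
#'   attached as attribute `"malformed"` (tibble of `line` and `text`).
#' @export
read_faers_table <- function(path, table_name) {
  table_name <- toupper(table_name)
  if (!table_name %in% names(.faers_columns)) {
    stop("unknown table '", table_name, "'; expected one of ",
         paste(names(.faers_columns), collapse = ", "))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)

  header <- .split_dollar(lines[[1]])
  if (length(header) == 1L && grepl("[\t,|]", lines[[1]])) {
    stop("expected '$'-delimited header but got: ", lines[[1]])
  }
  header <- tolower(trimws(header))
  if (any(header == "isr")) {
    stop("legacy AERS schema detected (ISR identifier); only the ",
         "primaryid-era quarterly format is supported")
  }
  unknown <- setdiff(header, .faers_columns[[table_name]])
  if (length(unknown) > 0L) {
    stop("unknown ", table_name, " column(s): ", paste(unknown, collapse = ", "))
  }
  missing_req <- setdiff(.faers_required[[table_name]], header)
  if (length(missing_req) > 0L) {
    stop(table_name, " header lacks required column(s): ",
         paste(missing_req, collapse = ", "))
  }

  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(header)), header))
    attr(out, "malformed") <- tibble::tibble(line = integer(0), text = character(0))
    return(out)
  }

  # strsplit drops trailing empties; the true field count is n_delim + 1
  nfield <- .count_dollar(body) + 1L
  ok <- nfield == length(header)
  if (any(!ok)) {
    warning(sum(!ok), " malformed line(s) in ", basename(path),
            " (field count != ", length(header), "); see attr 'malformed'")
  }
  parts <- .split_dollar(body[ok])
  if (length(body[ok]) == 1L) parts <- list(parts)
  mat <- matrix("", nrow = sum(ok), ncol = length(header))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    mat[i, seq_along(p)] <- p
  }
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  names(out) <- header
  attr(out, "malformed") <- tibble::tibble(
    line = which(!ok) + 1L,  # 1-based file line number (header is line 1)
    text = body[!ok])
  out
}

.split_dollar <- function(x) {
  if (length(x) == 1L) strsplit(x, "$", fixed = TRUE)[[1]]
  else strsplit(x, "$", fixed = TRUE)
}

.count_dollar <- function(x) {
  nchar(x) - nchar(gsub("$", "", x, fixed = TRUE))
}

#' Write a FAERS-style quarterly ASCII table
#'
#' Inverse of [read_faers_table()]: one `$`-delimited header row followed by
#' one line per record, no quoting. Values containing `$` are rejected
#' because the dialect has no escape mechanism.
#'
#' @param df Data frame of character columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(df, path) {
  mat <- as.matrix(as.data.frame(lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }), stringsAsFactors = FALSE, check.names = FALSE))
  if (any(grepl("$", mat, fixed = TRUE))) {
    stop("field values must not contain '$' (no escaping in this dialect)")
  }
  lines <- c(paste(names(df), collapse = "$"),
             if (nrow(df) > 0) apply(mat, 1L, paste, collapse = "$"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directory of FAERS-style tables
#'
#' Convenience wrapper locating `DEMO/DRUG/REAC/INDI/OUTC` files (matched
#' case-insensitively by name prefix) in `dir` and reading each with
#' [read_faers_table()].
#'
#' @param dir Directory containing the five table files.
#' @return Named list of tibbles (`demo`, `drug`, `reac`, `indi`, `outc`).
#' @export
read_faers_dir <- function(dir) {
  tabs <- c("DEMO", "DRUG", "REAC", "INDI", "OUTC")
  out <- list()
  for (tb in tabs) {
    hits <- list.files(dir, pattern = paste0("^", tb), ignore.case = TRUE,
                       full.names = TRUE)
    if (length(hits) == 0L) stop("no ", tb, " file found in ", dir)
    out[[tolower(tb)]] <- read_faers_table(hits[[1]], tb)
  }
  out
}

#' Assemble per-report case records from raw FAERS tables
#'
#' Joins DRUG/REAC/INDI/OUTC rows to their DEMO parent by `primaryid` and
#' normalizes the fields downstream stages rely on:
#' \itemize{
#'   \item `fda_dt` parsed as `YYYYMMDD`; partial dates (`YYYYMM`, `YYYY`)
#'     degrade to year precision (`report_year` kept, `report_date` `NA`);
#'     unparseable dates leave both missing and the case is retained.
#'   \item age converted to years via the `age_cod` unit (DEC/YR/MON/WK/DY);
#'     implausible ages (> 120 y) are set missing and logged in the audit.
#'   \item sex normalized to `F`/`M`/`UNK`.
#'   \item reaction and indication Preferred Terms uppercased, trimmed, and
#'     deduplicated within each report.
#'   \item OUTC rows with a blank outcome code are kept so summaries can
#'     distinguish "record exists but blank" from "no record at all".
#' }
#' Child rows whose `primaryid` has no DEMO parent are quarantined (kept in
#' the result, reported with a warning), never silently dropped. If a
#' `primaryid` has several DEMO rows the first is used and the duplicates are
#' recorded in the audit.
#'
#' @param tables Named list of tibbles as returned by [read_faers_dir()].
#' @return A `faers_cases` object: list with tibbles `demo` (one row per
#'   report: `primaryid`, `caseid`, `report_date`, `report_year`, `age_yr`,
#'   `sex`), `drugs`, `reactions`, `indications`, `outcomes`, plus
#'   `quarantine` (orphan child rows by table) and `audit` (field-level notes).
#' @export
assemble_cases <- function(tables) {
  stopifnot(all(c("demo", "drug", "reac", "indi", "outc") %in% names(tables)))
  demo_raw <- tables$demo
  audit <- list()

  dup_ids <- unique(demo_raw$primaryid[duplicated(demo_raw$primaryid)])
  if (length(dup_ids) > 0L) {
    audit$duplicate_demo <- dup_ids
    demo_raw <- demo_raw[!duplicated(demo_raw$primaryid), , drop = FALSE]
  }

  dt <- .parse_fda_dt(if ("fda_dt" %in% names(demo_raw)) demo_raw$fda_dt
                      else rep("", nrow(demo_raw)))
  age <- .age_years(
    if ("age" %in% names(demo_raw)) demo_raw$age else rep("", nrow(demo_raw)),
    if ("age_cod" %in% names(demo_raw)) demo_raw$age_cod else rep("", nrow(demo_raw)))
  over <- which(!is.na(age) & age > 120)
  if (length(over) > 0L) {
    audit$age_out_of_range <- demo_raw$primaryid[over]
    age[over] <- NA_real_
  }
  sx <- if ("sex" %in% names(demo_raw)) toupper(trimws(demo_raw$sex))
        else rep("", nrow(demo_raw))
  sx[!sx %in% c("F", "M")] <- "UNK"

  demo <- tibble::tibble(
    primaryid = demo_raw$primaryid,
    caseid = demo_raw$caseid,
    report_date = dt$date,
    report_year = dt$year,
    age_yr = age,
    sex = sx)

  known <- demo$primaryid
  qtn <- list()
  take <- function(df, tab) {
    orphan <- !(df$primaryid %in% known)
    if (any(orphan)) qtn[[tab]] <<- df[orphan, , drop = FALSE]
    df[!orphan, , drop = FALSE]
  }

  drugs <- take(tables$drug, "DRUG")
  drugs <- tibble::tibble(
    primaryid = drugs$primaryid,
    role_cod = if ("role_cod" %in% names(drugs)) toupper(trimws(drugs$role_cod)) else "",
    drugname = drugs$drugname,
    prod_ai = if ("prod_ai" %in% names(drugs)) drugs$prod_ai else "",
    route = if ("route" %in% names(drugs)) drugs$route else "",
    dose_form = if ("dose_form" %in% names(drugs)) drugs$dose_form else "",
    dose_vbm = if ("dose_vbm" %in% names(drugs)) drugs$dose_vbm else "")

  reac <- take(tables$reac, "REAC")
  reactions <- dplyr::distinct(tibble::tibble(
    primaryid = reac$primaryid,
    pt = toupper(trimws(reac$pt))))
  reactions <- reactions[nzchar(reactions$pt), , drop = FALSE]

  indi <- take(tables$indi, "INDI")
  indications <- dplyr::distinct(tibble::tibble(
    primaryid = indi$primaryid,
    indi_pt = toupper(trimws(indi$indi_pt))))
  indications <- indications[nzchar(indications$indi_pt), , drop = FALSE]

  outc <- take(tables$outc, "OUTC")
  outcomes <- tibble::tibble(
    primaryid = outc$primaryid,
    outc_cod = toupper(trimws(outc$outc_cod)))

  n_orphan <- sum(vapply(qtn, nrow, integer(1)))
  if (n_orphan > 0L) {
    warning(n_orphan, " child row(s) had no DEMO parent and were quarantined")
  }

  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 indications = indications, outcomes = outcomes,
                 quarantine = qtn, audit = audit),
            class = "faers_cases")
}

.parse_fda_dt <- function(x) {
  x <- trimws(x)
  year <- rep(NA_integer_, length(x))
  date <- rep(as.Date(NA), length(x))
  full <- grepl("^[0-9]{8}$", x)
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")  # invalid calendar dates -> NA
    date[full] <- d
    year[full] <- ifelse(is.na(d), suppressWarnings(as.integer(substr(x[full], 1, 4))),
                         as.integer(format(d, "%Y")))
  }
  partial <- !full & grepl("^[0-9]{4}([0-9]{2})?$", x)
  year[partial] <- as.integer(substr(x[partial], 1, 4))
  list(date = date, year = year)
}

.age_years <- function(age, cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(cod))
  mult <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.143, DY = 1 / 365.25,
            HR = 1 / 8766)
  m <- mult[cod]
  m[is.na(m) & nzchar(cod)] <- NA_real_   # unknown unit code -> missing
  m[!nzchar(cod)] <- 1                    # blank unit: FAERS default is years
  out <- unname(v * m)
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$demo), " reports (",
      length(unique(x$demo$caseid)), " cases)\n", sep = "")
  cat("  drugs: ", nrow(x$drugs), "  reactions: ", nrow(x$reactions),
      "  indications: ", nrow(x$indications), "  outcomes: ",
      nrow(x$outcomes), "\n", sep = "")
  nq <- sum(vapply(x$quarantine, nrow, integer(1)))
  if (nq > 0) cat("  quarantined child rows: ", nq, "\n", sep = "")
  invisible(x)
}

#' Ingest report for an assembled case set
#'
#' Row counts per table plus quarantine tallies, as a list convertible to
#' JSON (machine-readable audit trail of the ingest step).
#'
#' @param cases A `faers_cases` object.
#' @return A list with per-table row counts, report/case counts, and
#'   quarantined-row counts per table.
#' @export
ingest_report <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  list(
    n_reports = nrow(cases$demo),
    n_cases = length(unique(cases$demo$caseid)),
    rows = list(drug = nrow(cases$drugs), reac = nrow(cases$reactions),
                indi = nrow(cases$indications), outc = nrow(cases$outcomes)),
    quarantined = lapply(cases$quarantine, nrow),
    audit = lapply(cases$audit, length))
}
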