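write_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

test_that("dollar-delimited parsing maps fields and keeps trailing empties", {
  f <- write_lines(c("primaryid$caseid$drugname$route",
                     "100001$1000$MINOXIDIL$ORAL",
                     "100002$1001$MINOXIDIL$$"))  # malformed: 5 fields
  expect_warning(tab <- read_faers_table(f, "DRUG"), "malformed")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$route, "ORAL")
  mal <- attr(tab, "malformed")
  expect_equal(mal$line, 3L)

  f2 <- write_lines(c("primaryid$caseid$drugname$route",
                      "100003$1002$MINOXIDIL$"))
  tab2 <- read_faers_table(f2, "DRUG")
  expect_equal(tab2$route, "")
  f3 <- write_lines(c("primaryid$caseid$pt$drug_rec_act",
                      "100004$1003$$"))
  tab3 <- read_faers_table(f3, "REAC")
  expect_equal(unname(unlist(tab3[1, 3:4])), c("", ""))
})

test_that("header validation rejects unknown columns, legacy schema, wrong delimiter", {
  f <- write_lines(c("primaryid$caseid$bogus_col", "1$2$3"))
  expect_error(read_faers_table(f, "DEMO"), "bogus_col")
  f2 <- write_lines(c("isr$caseid$pt", "1$2$X"))
  expect_error(read_faers_table(f2, "REAC"), "legacy")
  f3 <- write_lines(c("primaryid,caseid,pt", "1,2,X"))
  expect_error(read_faers_table(f3, "REAC"), "delimited")
  f4 <- write_lines(c("primaryid$caseid", "1$2"))
  expect_error(read_faers_table(f4, "DRUG"), "required")
})

test_that("write-then-read round-trips a generated fixture exactly", {
  gen <- synth_generate(quiet_config(n_oral = 3, n_topical = 5, seed = 3),
                        out_dir = td <- tempfile())
  reread <- read_faers_dir(td)
  for (nm in names(gen$tables)) {
    expect_equal(as.data.frame(reread[[nm]]), as.data.frame(gen$tables[[nm]]),
                 ignore_attr = TRUE)
  }
  # byte-level: writing the reread table reproduces the file
  f1 <- file.path(td, "DEMO.txt")
  f2 <- tempfile()
  write_faers_table(reread$demo, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("assemble_cases joins child tables, normalizes PTs, quarantines orphans", {
  tabs <- list(
    demo = tibble::tibble(primaryid = "1", caseid = "10", fda_dt = "20190315",
                          age = "45", age_cod = "YR", sex = "f"),
    drug = tibble::tibble(primaryid = c("1", "1", "99"), caseid = "10",
                          role_cod = c("PS", "C", "PS"),
                          drugname = c("MINOXIDIL", "BIOTIN", "MINOXIDIL"),
                          prod_ai = "", route = c("ORAL", "", ""),
                          dose_form = "", dose_vbm = ""),
    reac = tibble::tibble(primaryid = "1", caseid = "10",
                          pt = c("tachycardia", "Tachycardia", "Headache")),
    indi = tibble::tibble(primaryid = "1", caseid = "10", indi_drug_seq = "1",
                          indi_pt = "alopecia"),
    outc = tibble::tibble(primaryid = "1", caseid = "10", outc_cod = ""))
  expect_warning(cases <- assemble_cases(tabs), "quarantined")
  expect_equal(nrow(cases$demo), 1L)
  expect_equal(nrow(cases$drugs), 2L)           # orphan drug row removed
  expect_equal(nrow(cases$quarantine$DRUG), 1L) # ...but kept in quarantine
  expect_setequal(cases$reactions$pt, c("TACHYCARDIA", "HEADACHE"))  # deduped, uppercased
  expect_equal(cases$indications$indi_pt, "ALOPECIA")
  expect_equal(cases$demo$sex, "F")
  expect_equal(cases$demo$report_year, 2019L)
  expect_equal(cases$demo$report_date, as.Date("2019-03-15"))
  # blank OUTC code row survives so summaries can mark BLANK_ONLY
  expect_equal(nrow(cases$outcomes), 1L)
  expect_equal(cases$outcomes$outc_cod, "")
  # no row silently lost
  expect_equal(nrow(tabs$drug), nrow(cases$drugs) + nrow(cases$quarantine$DRUG))
})

test_that("partial and invalid dates degrade gracefully; ages convert by unit", {
  tabs <- list(
    demo = tibble::tibble(primaryid = as.character(1:6), caseid = as.character(1:6),
                          fda_dt = c("201907", "2019", "20191340", "", "20200229", "nonsense"),
                          age = c("60", "6", "18", "720", "150", "30"),
                          age_cod = c("YR", "DEC", "MON", "DY", "YR", ""),
                          sex = "M"),
    drug = tibble::tibble(primaryid = character(0), caseid = character(0),
                          role_cod = character(0), drugname = character(0),
                          prod_ai = character(0), route = character(0),
                          dose_form = character(0), dose_vbm = character(0)),
    reac = tibble::tibble(primaryid = character(0), caseid = character(0),
                          pt = character(0)),
    indi = tibble::tibble(primaryid = character(0), caseid = character(0),
                          indi_drug_seq = character(0), indi_pt = character(0)),
    outc = tibble::tibble(primaryid = character(0), caseid = character(0),
                          outc_cod = character(0)))
  cases <- assemble_cases(tabs)
  expect_equal(cases$demo$report_year, c(2019L, 2019L, 2019L, NA, 2020L, NA))
  expect_true(all(is.na(cases$demo$report_date[c(1, 2, 4, 6)])))
  expect_equal(cases$demo$age_yr[1:4], c(60, 60, 1.5, 720 / 365.25))
  expect_true(is.na(cases$demo$age_yr[5]))      # >120 y audited out
  expect_equal(cases$demo$age_yr[6], 30)        # blank unit defaults to years
  expect_equal(cases$audit$age_out_of_range, "5")
})

test_that("assemble_cases is invariant to input row order", {
  gen <- synth_generate(synth_config(n_oral = 20, n_topical = 60, seed = 5))
  shuffled <- lapply(gen$tables, function(df) df[sample(nrow(df)), , drop = FALSE])
  a <- assemble_cases(gen$tables)
  b <- assemble_cases(shuffled)
  ord <- function(df) df[do.call(order, df), , drop = FALSE]
  for (nm in c("demo", "drugs", "reactions", "indications", "outcomes")) {
    expect_equal(ord(as.data.frame(a[[nm]])), ord(as.data.frame(b[[nm]])),
                 ignore_attr = TRUE)
  }
})

test_that("ingest report reconciles counts", {
  gen <- synth_generate(quiet_config(n_oral = 10, n_topical = 30, seed = 9))
  cases <- assemble_cases(gen$tables)
  rep <- ingest_report(cases)
  expect_equal(rep$n_cases, 40L)
  expect_equal(rep$rows$drug, nrow(cases$drugs))
  expect_true(nzchar(jsonlite::toJSON(rep, auto_unbox = TRUE)))
})
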