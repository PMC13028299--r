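#!/usr/bin/env Rscript
# Generate a synthetic FAERS-like dataset at the study-condition defaults
# (559 oral / 56,947 topical cases before label noise; follow-up versions,
# route/form missingness, conflicts, dual exposures) and write the five
# quarterly-style ASCII tables plus the ground-truth ledger.

library(faersror)
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(seed = 20260101)
gen <- synth_generate(cfg, out_dir = "scratch/synth")
utils::write.csv(gen$ledger, "scratch/synth_ledger.csv", row.names = FALSE)

cases <- assemble_cases(read_faers_dir("scratch/synth"))
rep <- ingest_report(cases)
jsonlite::write_json(rep, "results/ingest_report.json", auto_unbox = TRUE)

cat("synthetic dataset:", rep$n_reports, "report versions over",
    rep$n_cases, "cases\n")
cat("expected labels:\n")
print(table(gen$ledger$expected_label))
cat("files under scratch/synth/, ledger in scratch/synth_ledger.csv\n")
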