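#!/usr/bin/env Rscript
# Clean the synthetic quarter: single missing-value imputation across
# case versions, two-step de-duplication, under-18 exclusion. Reads the
# ASCII files written by 01_simulate.R (round-tripping through the FAERS
# layout on purpose) and writes the cleaned bundle + cleaning report.

library(faerspv)

paths <- list(
  demo = "results/synthetic_quarter/DEMO23Q1.txt",
  drug = "results/synthetic_quarter/DRUG23Q1.txt",
  reac = "results/synthetic_quarter/REAC23Q1.txt",
  ther = "results/synthetic_quarter/THER23Q1.txt",
  indi = "results/synthetic_quarter/INDI23Q1.txt",
  outc = "results/synthetic_quarter/OUTC23Q1.txt")
stopifnot(all(file.exists(unlist(paths))))

raw <- read_quarter(paths)
cleaned <- clean_bundle(raw)
print(cleaned$report)

dir.create("results/cleaned_quarter", showWarnings = FALSE)
write_quarter(cleaned$bundle, "results/cleaned_quarter", quarter = "23Q1")
jsonlite::write_json(unclass(cleaned$report),
                     "results/cleaning_report.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("imputation counts: %s\n",
            paste(names(cleaned$report$imputation_counts),
                  unlist(cleaned$report$imputation_counts),
                  sep = "=", collapse = ", ")))
cat("cleaned bundle written to results/cleaned_quarter/\n")
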