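#!/usr/bin/env Rscript
# Time-to-onset and cumulative-dose characterization of the ILD cases:
# per-drug medians and quartiles, the 4-week / 8-week onset fractions,
# and cumulative dose at onset (daily dose x TTO / weight, mg/kg).

library(faerspv)
library(data.table)

paths <- as.list(setNames(
  sprintf("results/cleaned_quarter/%s23Q1.txt",
          c("DEMO", "DRUG", "REAC", "THER", "INDI", "OUTC")),
  c("demo", "drug", "reac", "ther", "indi", "outc")))
bundle <- read_quarter(paths)
smq <- load_smq()

flags <- flag_cases(bundle, smq)
study <- select_study_reports(bundle)
cases <- study[flags, on = "primaryid", nomatch = NULL][is_case == TRUE]

recs <- onset_records(bundle, cases[, .(primaryid, drug)])
pooled <- onset_summary(recs, by = NULL)
per_drug <- onset_summary(recs)

summary_tab <- rbind(
  pooled[, .(group, n_tto, median_days, q1_days, q3_days,
             pct_within_4wk, pct_within_8wk, n_dose, median_dose_mg_kg)],
  per_drug[, .(group = drug, n_tto, median_days, q1_days, q3_days,
               pct_within_4wk, pct_within_8wk, n_dose,
               median_dose_mg_kg)])
fwrite(summary_tab, "results/onset_dose_summary.csv")

cat("onset and cumulative dose of ILD cases by suspect drug:\n")
print(summary_tab[, .(group, n_tto, median_days,
                      iqr = sprintf("(%.0f, %.0f)", q1_days, q3_days),
                      pct_4wk = round(pct_within_4wk, 1),
                      pct_8wk = round(pct_within_8wk, 1),
                      median_dose_mg_kg = round(median_dose_mg_kg, 0))],
      row.names = FALSE)
cat("\nwritten to results/onset_dose_summary.csv\n")
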