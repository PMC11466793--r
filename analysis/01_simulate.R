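#!/usr/bin/env Rscript
# Build the worked synthetic FAERS quarter for the ALK TKI / ILD study.
#
# 200,000 reports puts the five ALK TKIs at ~20,000 primary-suspect
# reports (their real-world report volumes), and the planted
# drug-specific relative risks on the two most-reported ILD SMQ PTs
# mirror the reported per-drug signal strengths, so downstream stages
# see a database with the study's qualitative structure and a known
# ground truth. Output: FAERS-layout ASCII files plus the truth ledger
# under results/synthetic_quarter/.

library(faerspv)
library(data.table)

dir.create("results/synthetic_quarter", showWarnings = FALSE,
           recursive = TRUE)

planted <- CJ(drug = alk_drugs(), pt_code = c("10022611", "10035742"))
planted[, rr := c(alectinib = 4.8, brigatinib = 6.4, ceritinib = 3.8,
                  crizotinib = 4.7, lorlatinib = 2.6)[drug]]

cfg <- synth_config(n_reports = 200000L, planted_rr = planted, seed = 20240101L)
bundle <- simulate_faers(cfg)

paths <- write_synthetic_quarter(bundle, "results/synthetic_quarter",
                                 quarter = "23Q1")
led <- truth_ledger(bundle)

cat(sprintf("emitted %d report versions (%d unique cases)\n",
            nrow(bundle$demo), uniqueN(bundle$demo$caseid)))
cat(sprintf("injected exact duplicates: %d; follow-up versions: %d\n",
            sum(led$is_injected_duplicate), sum(led$is_followup)))
cat(sprintf("ALK TKI primary-suspect share: %.2f%%\n",
            100 * mean(led$ps_drug %in% alk_drugs())))
cat("files:\n"); for (p in paths) cat(" ", p, "\n")
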