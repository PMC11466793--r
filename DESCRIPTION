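Package: faerspv
Title: Pharmacovigilance Disproportionality Analysis of ALK Inhibitor
    Interstitial Lung Disease in FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pharmacovigilance pipeline for spontaneous adverse
    event report databases distributed in the FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII layout: reading and writing the
    dollar-delimited DEMO/DRUG/REAC/THER/INDI/OUTC tables, single
    missing-value imputation across case versions, two-step case
    de-duplication, MedDRA SMQ case finding at the preferred-term level,
    four disproportionality algorithms (reporting odds ratio, proportional
    reporting ratio with Pearson chi-square, Bayesian confidence propagation
    information component, and the multi-item gamma-Poisson shrinker
    empirical Bayes geometric mean with a fitted two-component gamma mixture
    prior), time-to-onset and cumulative-dose characterization, and logistic
    regression risk modelling with a points-based nomogram. Includes a
    synthetic FAERS generator with planted drug-event relative risks,
    duplicates and missingness, plus a truth ledger, so every stage can be
    validated against known ground truth. The worked study is interstitial
    lung disease under the five ALK tyrosine kinase inhibitors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
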