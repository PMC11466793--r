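#!/usr/bin/env Rscript
# Risk-factor analysis among ALK TKI reports: case/non-case covariate
# matrix, univariate cross-product odds ratios, multivariate logistic
# regression (lorlatinib as the reference drug), and the derived
# points-based nomogram with a worked high-risk profile.

library(faerspv)
library(data.table)

paths <- as.list(setNames(
  sprintf("results/cleaned_quarter/%s23Q1.txt",
          c("DEMO", "DRUG", "REAC", "THER", "INDI", "OUTC")),
  c("demo", "drug", "reac", "ther", "indi", "outc")))
bundle <- read_quarter(paths)
smq <- load_smq()

cm <- build_case_control(bundle, smq)
cat(sprintf("covariate matrix: %d ALK TKI reports, %d ILD cases (%.1f%%)\n",
            nrow(cm), sum(cm$ild), 100 * mean(cm$ild)))

covs <- estimable_covariates(cm, min_n = 2L)
uni <- rbindlist(lapply(covs, function(cv) {
  u <- univariate_or(cm, cv)
  data.table(term = cv, or = u$or, lo = u$lo, hi = u$hi, p = u$p)
}))
fwrite(uni, "results/univariate_or.csv")

fit <- fit_risk_model(cm, covs)
if (length(fit$dropped) > 0) {
  cat("dropped (separated / inestimable):",
      paste(fit$dropped, collapse = ", "), "\n")
}
fwrite(fit$table, "results/multivariate_fit.csv")
cat("\nmultivariate logistic regression (Wald CIs):\n")
print(fit$table[term != "(Intercept)",
                .(term, or = round(or, 3),
                  ci = sprintf("(%.2f, %.2f)", lo, hi),
                  p = signif(p, 3))], row.names = FALSE)

nom <- build_nomogram(fit)
jsonlite::write_json(
  list(table = nom$table, scale = nom$scale, base_lp = nom$base_lp,
       intercept = nom$intercept),
  "results/nomogram.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
cat("\nnomogram point scales (largest contribution = 100 points):\n")
print(nom$table[order(-max_points),
                .(term, beta = round(beta, 3),
                  max_points = round(max_points, 1))], row.names = FALSE)

# worked profiles: baseline vs a female patient on brigatinib with
# amlodipine co-medication
terms <- nom$table$term
base_profile <- as.list(setNames(rep(0, length(terms)), terms))
risky <- base_profile
for (tm in intersect(c("sex_female", "drug_brigatinib",
                       "con_amlodipine"), terms)) risky[[tm]] <- 1
cat(sprintf("\npredicted ILD risk, all-reference profile: %.4f\n",
            predict_risk(nom, base_profile)))
cat(sprintf("predicted ILD risk, female + brigatinib + amlodipine: %.4f\n",
            predict_risk(nom, risky)))
cat("\nwritten: results/univariate_or.csv, results/multivariate_fit.csv,",
    "results/nomogram.json\n")
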