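# Case/non-case risk modelling among primary-suspect study reports:
# covariate construction, univariate cross-product odds ratios,
# multivariate logistic regression, and a simulation generator for
# parameter-recovery checks.

#' Concomitant drugs tracked as risk-model covariates
#' @return character vector of drug names.
#' @export
concomitant_drug_covariates <- function() {
  c("amlodipine", "furosemide", "magnesium oxide", "lansoprazole",
    "pantoprazole", "acetaminophen", "oxycodone", "metoclopramide")
}

#' Concomitant-disease categories and their indication PTs
#'
#' Spontaneous-report databases carry no comorbidity table; concomitant
#' diseases are derived from the indication PTs of non-suspect drugs.
#'
#' @return `data.table(category, pt_code, pt_name)`.
#' @export
concomitant_disease_map <- function() {
  data.table::data.table(
    category = c("hypertension", "diabetes_mellitus", "dyslipidemia",
                 "gastric_disorder", "pain", "nausea", "constipation"),
    pt_code = c("10020772", "10012601", "10058108", "10017944",
                "10033371", "10028813", "10010774"),
    pt_name = c("Hypertension", "Diabetes mellitus", "Dyslipidaemia",
                "Gastric disorder", "Pain", "Nausea", "Constipation"))
}

#' Build the case/non-case covariate matrix
#'
#' One row per cleaned study report (primary-suspect drug in the study
#' set). Outcome is the SMQ case flag. Covariates: age group (18-64
#' reference, 65-84, >=85 -- age 85 joins the upper group -- and
#' unknown), sex (female; unknown), per-drug indicators with lorlatinib
#' as the reference level, concomitant-disease indicators from the
#' indication PTs of non-suspect drugs, and concomitant-drug indicators
#' from DRUG rows with role other than PS.
#'
#' @param bundle a cleaned `faers_bundle`.
#' @param smq an [load_smq()] definition defining the outcome.
#' @param synonyms study-drug synonym list (default ALK TKIs).
#' @param reference_drug study drug used as the reference level.
#' @return a `data.table`: `primaryid`, `ild` (0/1 outcome), and binary
#'   covariate columns.
#' @export
build_case_control <- function(bundle, smq = load_smq(),
                               synonyms = load_drug_synonyms(),
                               reference_drug = "lorlatinib") {
  study <- select_study_reports(bundle, synonyms)
  study <- study[!duplicated(primaryid)]
  if (nrow(study) == 0) return(data.table::data.table())
  flags <- flag_cases(bundle, smq)
  m <- data.table::data.table(primaryid = study$primaryid,
                              drug = study$drug)
  m[flags, on = "primaryid", ild := as.integer(i.is_case)]

  demo <- bundle$demo[, .(primaryid, age_yr, sex)]
  m[demo, on = "primaryid", `:=`(age_yr = i.age_yr, sex = i.sex)]
  m[, `:=`(age_65_84 = as.integer(!is.na(age_yr) & age_yr >= 65 &
                                    age_yr < 85),
           age_ge85 = as.integer(!is.na(age_yr) & age_yr >= 85),
           age_unknown = as.integer(is.na(age_yr)),
           sex_female = as.integer(!is.na(sex) & sex == "F"),
           sex_unknown = as.integer(is.na(sex)))]
  m[, c("age_yr", "sex") := NULL]

  for (dg in setdiff(sort(names(synonyms)), reference_drug)) {
    m[, (paste0("drug_", gsub("[^a-z0-9]+", "_", tolower(dg)))) :=
        as.integer(drug == dg)]
  }

  # concomitant diseases: indication PTs of non-suspect drug rows
  dmap <- concomitant_disease_map()
  non_ps_seq <- bundle$drug[role_cod != "PS",
                            .(primaryid, drug_seq)]
  indi <- bundle$indi[non_ps_seq,
                      on = c("primaryid", indi_drug_seq = "drug_seq"),
                      nomatch = NULL]
  indi[, category := dmap$category[match(indi_pt_code, dmap$pt_code)]]
  for (cat in dmap$category) {
    with_cat <- unique(indi[category == cat, primaryid])
    m[, (paste0("dis_", cat)) := as.integer(primaryid %chin% with_cat)]
  }

  # concomitant drugs: non-PS rows matched by name
  con <- bundle$drug[role_cod != "PS", .(primaryid, drugname)]
  con[, drugname := tolower(trimws(drugname))]
  for (cd in concomitant_drug_covariates()) {
    with_cd <- unique(con[drugname == cd, primaryid])
    m[, (paste0("con_", gsub("[^a-z0-9]+", "_", cd))) :=
        as.integer(primaryid %chin% with_cd)]
  }
  m[, drug := NULL]
  m[]
}

#' Covariates with finite maximum-likelihood estimates
#'
#' A binary covariate whose exposed stratum contains only cases or only
#' non-cases has an infinite logistic MLE (quasi-separation). This
#' screens the covariate matrix down to covariates with at least `min_n`
#' cases and `min_n` non-cases among the exposed, which keeps the
#' multivariate fit estimable on small databases.
#'
#' @param matrix covariate matrix with an `ild` outcome column.
#' @param min_n minimum exposed cases and exposed non-cases.
#' @return character vector of covariate names.
#' @export
estimable_covariates <- function(matrix, min_n = 1L) {
  covs <- setdiff(names(matrix), c("primaryid", "ild"))
  keep <- vapply(covs, function(cv) {
    x <- matrix[[cv]]
    sum(x == 1 & matrix$ild == 1) >= min_n &&
      sum(x == 1 & matrix$ild == 0) >= min_n &&
      any(x == 0)
  }, TRUE)
  covs[keep]
}

#' Fit the risk model with automatic handling of separation
#'
#' Screens covariates with [estimable_covariates()], fits the
#' multivariate logistic model, and on a separation error drops the
#' offending covariate and refits, until the fit converges with finite
#' estimates or no covariates remain.
#'
#' @param matrix covariate matrix with an `ild` outcome column.
#' @param covariates starting covariate set (default: all estimable).
#' @param min_n passed to [estimable_covariates()].
#' @return a `logistic_fit` (with dropped covariates recorded in
#'   `$dropped`), or `NULL` if nothing is estimable.
#' @export
fit_risk_model <- function(matrix, covariates = NULL, min_n = 2L) {
  if (is.null(covariates)) {
    covariates <- estimable_covariates(matrix, min_n = min_n)
  }
  removed <- character()
  while (length(covariates) > 0) {
    res <- tryCatch(suppressWarnings(multivariate_fit(matrix, covariates)),
                    error = function(e) e)
    if (!inherits(res, "error")) {
      res$dropped <- union(res$dropped, removed)
      return(res)
    }
    bad <- sub(".*covariate: ([^)]+)\\).*", "\\1", conditionMessage(res))
    if (!bad %in% covariates) stop(res)
    covariates <- setdiff(covariates, bad)
    removed <- c(removed, bad)
  }
  NULL
}

#' Univariate odds ratio for one binary covariate
#'
#' Cross-product odds ratio of the covariate-by-outcome 2x2 table with a
#' Woolf (log-scale Wald) 95% CI and Wald p-value. For a binary
#' covariate this equals the single-covariate logistic regression OR
#' exactly (saturated-model identity). An empty stratum yields `NA`
#' markers.
#'
#' @param matrix covariate matrix from [build_case_control()] (must
#'   contain an `ild` outcome column).
#' @param covariate name of the covariate column.
#' @return list with `or`, `lo`, `hi`, `p` and the 2x2 cells.
#' @export
univariate_or <- function(matrix, covariate) {
  x <- matrix[[covariate]]
  y <- matrix[["ild"]]
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  if (a == 0 || b == 0 || cc == 0 || d == 0) {
    return(list(or = NA_real_, lo = NA_real_, hi = NA_real_, p = NA_real_,
                a = a, b = b, c = cc, d = d))
  }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  p <- 2 * stats::pnorm(-abs(log(or)) / se)
  list(or = or, lo = ci[1], hi = ci[2], p = p, a = a, b = b, c = cc, d = d)
}

#' Multivariate logistic regression fit
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`) of the outcome
#' on the given covariates, with Wald CIs and p-values. Covariates with
#' no variation are dropped with a warning; perfect separation raises an
#' error naming the offending covariate; fewer than 10 observations per
#' covariate triggers a warning.
#'
#' @param matrix covariate matrix with an `ild` outcome column.
#' @param covariates covariate names (default: every column except
#'   `primaryid` and `ild`).
#' @return a `logistic_fit` list: `table` (term, estimate, se, or, lo,
#'   hi, p), `coef`, `vcov`, `n`, `converged`, `dropped`.
#' @export
multivariate_fit <- function(matrix, covariates = NULL) {
  matrix <- data.table::as.data.table(matrix)
  if (is.null(covariates)) {
    covariates <- setdiff(names(matrix), c("primaryid", "ild"))
  }
  dropped <- covariates[vapply(covariates, function(cv)
    length(unique(matrix[[cv]])) < 2, TRUE)]
  if (length(dropped) > 0) {
    warning("dropping covariate(s) with no variation: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    covariates <- setdiff(covariates, dropped)
  }
  if (length(covariates) == 0) stop("no usable covariates", call. = FALSE)
  n <- nrow(matrix)
  if (n <= 10 * length(covariates)) {
    warning(sprintf(
      "only %d observations for %d covariates (< 10 per covariate)",
      n, length(covariates)), call. = FALSE)
  }
  fml <- stats::as.formula(paste("ild ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, data = matrix, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("perfectly collinear (covariate: ",
         names(cf)[which(is.na(cf))[1]], ")", call. = FALSE)
  }
  # a diverging coefficient marks (quasi-)separation: the MLE is infinite
  if (any(abs(cf[-1]) > 10, na.rm = TRUE)) {
    worst <- names(which.max(abs(cf[-1])))
    stop("perfect separation detected (covariate: ", worst, ")",
         call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.table::data.table(
    term = names(cf), estimate = unname(cf), se = unname(se))
  tab[, `:=`(or = exp(estimate),
             lo = exp(estimate - 1.96 * se),
             hi = exp(estimate + 1.96 * se),
             p = 2 * stats::pnorm(-abs(estimate / se)))]
  structure(list(table = tab, coef = cf, vcov = stats::vcov(fit),
                 n = n, converged = fit$converged, dropped = dropped),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d converged=%s\n", x$n, x$converged))
  print(x$table[, .(term, or = round(or, 3), lo = round(lo, 3),
                    hi = round(hi, 3), p = signif(p, 3))])
  invisible(x)
}

#' Predicted probabilities from a logistic fit
#' @param fit a `logistic_fit`.
#' @param newdata data with the fit's covariate columns.
#' @return numeric probabilities.
#' @export
predict_logistic <- function(fit, newdata) {
  terms <- setdiff(names(fit$coef), "(Intercept)")
  x <- as.matrix(data.table::as.data.table(newdata)[, terms, with = FALSE])
  stats::plogis(drop(fit$coef["(Intercept)"] + x %*% fit$coef[terms]))
}

#' Simulate covariates and outcome from a known logistic model
#'
#' Independent Bernoulli covariates with given prevalences; outcome drawn
#' from the logistic model with the given coefficients. Used for
#' parameter-recovery and calibration checks.
#'
#' @param n number of observations.
#' @param beta named coefficient vector including `"(Intercept)"`.
#' @param prevalence named vector of covariate prevalences in (0,1)
#'   (names must match `beta`'s non-intercept terms).
#' @param seed integer seed.
#' @return `data.table` with covariate columns and outcome `ild`.
#' @export
simulate_logistic_data <- function(n, beta, prevalence, seed = 1L) {
  set.seed(seed)
  terms <- setdiff(names(beta), "(Intercept)")
  stopifnot(all(terms %in% names(prevalence)))
  out <- data.table::as.data.table(
    lapply(stats::setNames(terms, terms),
           function(tm) stats::rbinom(n, 1, prevalence[[tm]])))
  lp <- beta[["(Intercept)"]] +
    as.matrix(out) %*% beta[terms]
  out[, ild := stats::rbinom(n, 1, stats::plogis(drop(lp)))]
  out[]
}
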