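test_that("covariate matrix encodes outcome, drugs and concomitants", {
  b <- example_bundle()
  m <- build_case_control(b)
  expect_equal(nrow(m), 2L) # two ALK TKI reports; comparator excluded
  r1 <- m[m$primaryid == "1"]
  expect_equal(r1$ild, 1L)
  expect_equal(r1$drug_crizotinib, 1L)
  expect_equal(r1$con_amlodipine, 0L)
  r2 <- m[m$primaryid == "2"]
  expect_equal(r2$ild, 0L)
  expect_equal(r2$drug_alectinib, 1L)
  expect_equal(r2$con_amlodipine, 1L)
  expect_equal(r2$dis_hypertension, 1L) # from amlodipine's indication PT
  expect_equal(r2$sex_female, 1L)
  # lorlatinib is the reference: no indicator column
  expect_false("drug_lorlatinib" %in% names(m))
})

test_that("planted covariate prevalences are recovered within binomial
           bounds", {
  cfg <- small_null_config(n = 5000, seed = 301)
  b <- generate_bundle(cfg)
  m <- build_case_control(b)
  n <- nrow(m)
  expect_gt(n, 300)
  # amlodipine planted at 8% inclusion
  k <- sum(m$con_amlodipine)
  expect_gte(k, qbinom(0.005, n, 0.08))
  expect_lte(k, qbinom(0.995, n, 0.08))
  # female share planted at 52%
  kf <- sum(m$sex_female)
  expect_gte(kf, qbinom(0.005, n, 0.52))
  expect_lte(kf, qbinom(0.995, n, 0.52))
})

test_that("univariate OR is the cross-product with Woolf CI and equals the
           logistic fit", {
  m <- data.table::data.table(
    ild = rep(c(1, 0, 1, 0), c(20, 80, 10, 90)),
    exposed = rep(c(1, 1, 0, 0), c(20, 80, 10, 90)))
  u <- univariate_or(m, "exposed")
  expect_equal(u$or, (20 * 90) / (80 * 10), tolerance = 1e-12)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(u$lo, exp(log(2.25) - 1.96 * se), tolerance = 1e-12)
  # saturated-model identity with glm
  fit <- glm(ild ~ exposed, data = m, family = binomial())
  expect_equal(u$or, unname(exp(coef(fit)["exposed"])), tolerance = 1e-6)
  # balanced null table
  m0 <- data.table::data.table(ild = c(1, 0, 1, 0),
                               exposed = c(1, 1, 0, 0))
  expect_equal(univariate_or(m0, "exposed")$or, 1)
  # empty stratum -> undefined marker
  m1 <- data.table::data.table(ild = c(1, 1, 0), exposed = c(1, 1, 1))
  expect_true(is.na(univariate_or(m1, "exposed")$or))
})

test_that("multivariate fit handles degenerate covariates and separation", {
  set.seed(5)
  m <- data.table::data.table(
    x1 = rbinom(500, 1, 0.4), flat = 0L)
  m[, ild := rbinom(500, 1, plogis(-2 + 0.8 * x1))]
  expect_warning(fit <- multivariate_fit(m), "no variation")
  expect_false("flat" %in% fit$table$term)
  # perfect separation errors with the covariate named
  ms <- data.table::data.table(x1 = rep(0:1, each = 50))
  ms[, ild := x1]
  expect_error(suppressWarnings(multivariate_fit(ms)), "x1")
})

test_that("duplicating the dataset keeps estimates, scales SEs by 1/sqrt(2)", {
  set.seed(6)
  m <- data.table::data.table(x1 = rbinom(2000, 1, 0.3),
                              x2 = rbinom(2000, 1, 0.5))
  m[, ild := rbinom(2000, 1, plogis(-2 + x1 + 0.5 * x2))]
  f1 <- multivariate_fit(m)
  f2 <- multivariate_fit(rbind(m, m))
  expect_equal(f2$table$estimate, f1$table$estimate, tolerance = 1e-8)
  expect_equal(f2$table$se, f1$table$se / sqrt(2), tolerance = 1e-6)
})

test_that("coefficients of a known logistic model are recovered", {
  beta <- c("(Intercept)" = -3.2, x1 = 1.1, x2 = 0.7, x3 = 1.8)
  prev <- c(x1 = 0.3, x2 = 0.5, x3 = 0.08)
  est <- sapply(1:5, function(s) {
    m <- simulate_logistic_data(20000, beta, prev, seed = 400 + s)
    multivariate_fit(m)$coef[names(beta)]
  })
  bias <- rowMeans(est) - beta
  expect_lt(max(abs(bias)), 0.05)
})

test_that("mean predicted risk matches the empirical event rate", {
  beta <- c("(Intercept)" = -3.5, x1 = 1.2, x2 = 2.0)
  prev <- c(x1 = 0.3, x2 = 0.1)
  m <- simulate_logistic_data(20000, beta, prev, seed = 77)
  fit <- multivariate_fit(m)
  pred <- predict_logistic(fit, m)
  # calibration-in-the-large, overall and among the exposed
  expect_equal(mean(pred), mean(m$ild), tolerance = 1e-6)
  exposed <- m$x2 == 1
  expect_lt(abs(mean(pred[exposed]) - mean(m$ild[exposed])), 0.02)
})
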