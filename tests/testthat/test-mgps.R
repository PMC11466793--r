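test_that("EBGM and posterior quantiles match the quadrature oracle", {
  prior <- structure(list(alpha1 = 0.7, beta1 = 0.9, alpha2 = 2.2,
                          beta2 = 0.6, p = 0.6, converged = TRUE,
                          loglik = 0, n_pairs = 0), class = "mgps_prior")
  set.seed(5)
  a <- c(0, 1, 3, rpois(47, 20))
  E <- c(0.3, 2, 0.8, runif(47, 0.5, 30))
  got <- ebgm(a, E, prior)
  for (i in seq_along(a)) {
    oracle <- ebgm_quadrature(prior, a[i], E[i])
    expect_equal(got$ebgm[i], oracle$ebgm, tolerance = 2e-3)
    expect_equal(got$eb05[i], oracle$eb05, tolerance = 2e-3)
    expect_equal(got$eb95[i], oracle$eb95, tolerance = 2e-3)
  }
})

test_that("posterior quantities are invariant to component exchange", {
  p1 <- structure(list(alpha1 = 0.5, beta1 = 0.8, alpha2 = 3, beta2 = 1.2,
                       p = 0.3, converged = TRUE, loglik = 0, n_pairs = 0),
                  class = "mgps_prior")
  p2 <- structure(list(alpha1 = 3, beta1 = 1.2, alpha2 = 0.5, beta2 = 0.8,
                       p = 0.7, converged = TRUE, loglik = 0, n_pairs = 0),
                  class = "mgps_prior")
  a <- c(0, 2, 10, 40); E <- c(1, 1.5, 4, 9)
  e1 <- ebgm(a, E, p1)
  e2 <- ebgm(a, E, p2)
  expect_equal(e1$ebgm, e2$ebgm, tolerance = 1e-10)
  expect_equal(e1$eb05, e2$eb05, tolerance = 1e-8)
  expect_equal(e1$eb95, e2$eb95, tolerance = 1e-8)
})

test_that("shrinkage keeps a = 0 positive and vanishes at large counts", {
  prior <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 2, beta2 = 2,
                          p = 0.5, converged = TRUE, loglik = 0,
                          n_pairs = 0), class = "mgps_prior")
  e0 <- ebgm(0, 0.1, prior)
  expect_gt(e0$ebgm, 0)
  expect_lt(e0$ebgm, 1.5) # shrunk toward the prior mean
  # large a with a/E = 4: EBGM -> 4, EB05 -> 4
  ebig <- ebgm(40000, 10000, prior)
  expect_equal(ebig$ebgm, 4, tolerance = 0.01)
  expect_equal(ebig$eb05, 4, tolerance = 0.05)
  expect_true(ebig$eb05 <= ebig$ebgm && ebig$ebgm <= ebig$eb95)
})

test_that("fitting requires data and a converged prior is enforced", {
  expect_error(fit_mgps(data.table::data.table(a = 1, E = 1)),
               "at least 2")
  bad <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1,
                        p = 0.5, converged = FALSE, loglik = 0,
                        n_pairs = 0), class = "mgps_prior")
  expect_error(ebgm(1, 1, bad), "converge")
})

test_that("duplicating every table leaves the fitted prior unchanged", {
  set.seed(3)
  E <- runif(400, 0.5, 20)
  lam <- rgamma(400, 2, rate = 2)
  a <- rpois(400, lam * E)
  f1 <- fit_mgps(a, E)
  f2 <- fit_mgps(c(a, a), c(E, E))
  # component labels may swap; compare label-invariant quantities
  expect_equal(
    mgps_prior_cdf(f1, c(0.5, 1, 2, 4)),
    mgps_prior_cdf(f2, c(0.5, 1, 2, 4)), tolerance = 1e-3)
})

test_that("a null database concentrates the prior near lambda = 1", {
  # lambda == 1 truth: >= 95% of fitted prior mass in (0.5, 2)
  for (s in 1:5) {
    set.seed(100 + s)
    E <- runif(5000, 0.5, 25)
    a <- rpois(5000, E)
    f <- fit_mgps(a, E)
    mass <- mgps_prior_cdf(f, 2) - mgps_prior_cdf(f, 0.5)
    expect_gte(mass, 0.95)
  }
})

test_that("single-gamma truth is recovered in predictive distribution", {
  # all pairs from one gamma component: the fitted two-component
  # mixture's predictive must match the true single-gamma predictive
  # within total variation 0.05 at a representative E
  set.seed(11)
  E <- rep(2, 4000)
  lam <- rgamma(4000, shape = 2, rate = 2)
  a <- rpois(4000, lam * E)
  f <- fit_mgps(a, E)
  grid <- 0:60
  p_true <- dnbinom(grid, size = 2, prob = 2 / (2 + 2))
  p_fit <- mgps_predictive(f, grid, rep(2, length(grid)))
  tv <- 0.5 * sum(abs(p_true - p_fit))
  expect_lt(tv, 0.05)
})
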