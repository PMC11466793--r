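# Multi-item gamma-Poisson shrinker (MGPS). Observed pair counts a_i are
# modelled as Poisson(lambda_i * E_i) with the reporting-rate ratio
# lambda drawn from a two-component gamma mixture prior
#   lambda ~ p Gamma(alpha1, beta1) + (1-p) Gamma(alpha2, beta2)
# (shape/rate). Marginally a_i follows a mixture of two negative
# binomials; the prior is fitted by maximum marginal likelihood and the
# posterior for each pair is again a two-component gamma mixture with
# conjugate updates (alpha_k + a, beta_k + E) and weights proportional to
# prior weight times the negative-binomial marginal. EBGM is the
# posterior geometric mean 2^{E[log2 lambda | a, E]}.

.mgps_loglik <- function(theta, a, E) {
  if (any(!is.finite(theta)) || any(abs(theta[1:4]) > 60)) return(-1e12)
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  p <- stats::plogis(theta[5])
  l1 <- suppressWarnings(
    stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE))
  l2 <- suppressWarnings(
    stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE))
  if (any(!is.finite(c(l1, l2)))) return(-1e12)
  m <- pmax(l1, l2)
  ll <- sum(m + log(p * exp(l1 - m) + (1 - p) * exp(l2 - m)))
  if (!is.finite(ll)) -1e12 else ll
}

.mgps_starts <- function() {
  # deterministic multi-start grid around the classical MGPS start
  # (alpha1 .2, beta1 .1, alpha2 2, beta2 4, p 1/3) plus spread-out
  # alternatives covering null-concentrated and diffuse priors
  list(
    c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1 / 3)),
    c(log(1), log(1), log(2), log(2), stats::qlogis(0.5)),
    c(log(5), log(5), log(1), log(0.5), stats::qlogis(0.7)),
    c(log(10), log(10), log(0.5), log(0.2), stats::qlogis(0.9)),
    c(log(2), log(2), log(0.2), log(0.05), stats::qlogis(0.8)),
    c(log(0.5), log(0.5), log(4), log(1), stats::qlogis(0.3)),
    c(log(20), log(20), log(2), log(0.4), stats::qlogis(0.95)),
    c(log(1), log(2), log(1), log(0.25), stats::qlogis(0.5))
  )
}

#' Fit the MGPS two-component gamma mixture prior
#'
#' Maximizes the marginal likelihood of observed pair counts under the
#' negative-binomial mixture, by quasi-Newton (BFGS) optimization on
#' log/logit-transformed parameters from eight deterministic starts.
#'
#' @param pairs a `data.table`/`data.frame` with columns `a` (observed
#'   report count) and `E` (expected count), e.g. from [pair_counts()];
#'   or a numeric vector `a` with `E` supplied separately.
#' @param E expected counts when `pairs` is a numeric vector.
#' @return an `mgps_prior` list: `alpha1, beta1, alpha2, beta2, p`,
#'   `converged`, `loglik`, `n_pairs`.
#' @export
fit_mgps <- function(pairs, E = NULL) {
  if (is.numeric(pairs) && !is.null(E)) {
    a <- pairs
  } else {
    pairs <- data.table::as.data.table(pairs)
    stopifnot(all(c("a", "E") %in% names(pairs)))
    a <- pairs$a
    E <- pairs$E
  }
  keep <- is.finite(a) & is.finite(E) & E > 0
  a <- as.numeric(a[keep]); E <- as.numeric(E[keep])
  if (length(a) < 2) stop("need at least 2 drug-event pairs", call. = FALSE)

  best <- NULL
  any_conv <- FALSE
  for (st in .mgps_starts()) {
    fit <- tryCatch(
      stats::optim(st, .mgps_loglik, a = a, E = E, method = "BFGS",
                   control = list(fnscale = -1, maxit = 500,
                                  reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  if (is.null(best)) stop("MGPS optimization failed from all starts",
                          call. = FALSE)
  th <- best$par
  prior <- structure(list(
    alpha1 = exp(th[1]), beta1 = exp(th[2]),
    alpha2 = exp(th[3]), beta2 = exp(th[4]),
    p = stats::plogis(th[5]),
    converged = any_conv, loglik = best$value, n_pairs = length(a)),
    class = "mgps_prior")
  if (!any_conv) {
    stop(errorCondition(
      "MGPS fit did not converge from any start",
      class = c("faerspv_mgps_error", "error", "condition"),
      best = prior))
  }
  prior
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(paste0(
    "<mgps_prior> p=%.3f Gamma(%.3g, %.3g) + %.3f Gamma(%.3g, %.3g)\n",
    "  logLik %.2f on %d pairs (converged: %s)\n"),
    x$p, x$alpha1, x$beta1, 1 - x$p, x$alpha2, x$beta2,
    x$loglik, x$n_pairs, x$converged))
  invisible(x)
}

#' Prior CDF of the reporting-rate ratio
#' @param prior an `mgps_prior`.
#' @param q quantile(s) at which to evaluate the mixture CDF.
#' @return numeric vector of prior probabilities `P(lambda <= q)`.
#' @export
mgps_prior_cdf <- function(prior, q) {
  prior$p * stats::pgamma(q, prior$alpha1, rate = prior$beta1) +
    (1 - prior$p) * stats::pgamma(q, prior$alpha2, rate = prior$beta2)
}

#' Marginal (predictive) probability of an observed count
#' @param prior an `mgps_prior`.
#' @param a observed count(s).
#' @param E expected count(s).
#' @return predictive probability `P(a | E)` under the prior.
#' @export
mgps_predictive <- function(prior, a, E) {
  prior$p * stats::dnbinom(a, size = prior$alpha1,
                           prob = prior$beta1 / (prior$beta1 + E)) +
    (1 - prior$p) * stats::dnbinom(a, size = prior$alpha2,
                                   prob = prior$beta2 / (prior$beta2 + E))
}

# posterior mixture parameters and weights for (a, E) vectors
.mgps_posterior <- function(prior, a, E) {
  lw1 <- log(prior$p) +
    stats::dnbinom(a, size = prior$alpha1,
                   prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  lw2 <- log(1 - prior$p) +
    stats::dnbinom(a, size = prior$alpha2,
                   prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  m <- pmax(lw1, lw2)
  w1 <- exp(lw1 - m) / (exp(lw1 - m) + exp(lw2 - m))
  list(w1 = w1,
       shape1 = prior$alpha1 + a, rate1 = prior$beta1 + E,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + E)
}

#' Empirical Bayes geometric mean with posterior interval
#'
#' Posterior summaries of the reporting-rate ratio lambda for each
#' (a, E) pair under a fitted MGPS prior: `EBGM = 2^{E[log2 lambda]}`
#' (equivalently `exp(E[ln lambda])`), and EB05/EB95 the posterior 5th
#' and 95th percentiles obtained by root-finding on the posterior mixture
#' CDF.
#'
#' @param a observed count(s).
#' @param E expected count(s) (> 0).
#' @param prior a converged [fit_mgps()] prior.
#' @return list of numeric vectors `ebgm`, `eb05`, `eb95`.
#' @export
ebgm <- function(a, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  if (!isTRUE(prior$converged)) {
    stop("MGPS prior did not converge; refusing to compute EBGM",
         call. = FALSE)
  }
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  post <- .mgps_posterior(prior, a, E)
  elog <- post$w1 * (digamma(post$shape1) - log(post$rate1)) +
    (1 - post$w1) * (digamma(post$shape2) - log(post$rate2))
  est <- exp(elog)

  q_post <- function(i, pr) {
    cdf <- function(x) {
      post$w1[i] * stats::pgamma(x, post$shape1[i], rate = post$rate1[i]) +
        (1 - post$w1[i]) * stats::pgamma(x, post$shape2[i],
                                         rate = post$rate2[i]) - pr
    }
    lo <- min(stats::qgamma(pr, post$shape1[i], rate = post$rate1[i]),
              stats::qgamma(pr, post$shape2[i], rate = post$rate2[i]))
    hi <- max(stats::qgamma(pr, post$shape1[i], rate = post$rate1[i]),
              stats::qgamma(pr, post$shape2[i], rate = post$rate2[i]))
    if (hi - lo < .Machine$double.eps * 4) return(lo)
    stats::uniroot(cdf, c(lo, hi), tol = 1e-10, extendInt = "yes")$root
  }
  n <- length(a)
  eb05 <- vapply(seq_len(n), q_post, 0, pr = 0.05)
  eb95 <- vapply(seq_len(n), q_post, 0, pr = 0.95)
  list(ebgm = est, eb05 = eb05, eb95 = eb95)
}
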