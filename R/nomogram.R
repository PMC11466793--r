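# Points-based nomogram derived from a multivariate logistic fit. Each
# covariate contributes points proportional to |coefficient x range|;
# the largest such contribution spans exactly 100 points, and total
# points map back to predicted probability through the reconstructed
# linear predictor.

#' Build a nomogram from a logistic fit
#'
#' For covariate i with coefficient beta_i over range
#' [xmin_i, xmax_i], the point scale is
#' `points_i(x) = 100 (beta_i x - min(beta_i xmin_i, beta_i xmax_i)) / M`
#' with `M = max_j |beta_j| (xmax_j - xmin_j)`, so points are
#' non-negative, the most influential covariate reaches exactly 100
#' points at its risk-maximizing level, and the total maps to probability
#' via the inverse logit of `base_lp + total M / 100`, where `base_lp`
#' is the linear predictor of the all-minimum-points profile.
#'
#' @param fit a converged [multivariate_fit()].
#' @param ranges optional named list of `c(min, max)` per covariate;
#'   defaults to `c(0, 1)` (binary indicators).
#' @return a `nomogram_spec` list: per-covariate `table` (term, beta,
#'   ref_value, max_points), `scale` (M), `base_lp`, `intercept`.
#' @export
build_nomogram <- function(fit, ranges = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!isTRUE(fit$converged)) {
    stop("logistic fit did not converge; refusing to build nomogram",
         call. = FALSE)
  }
  terms <- setdiff(names(fit$coef), "(Intercept)")
  if (is.null(ranges)) {
    ranges <- stats::setNames(rep(list(c(0, 1)), length(terms)), terms)
  }
  stopifnot(all(terms %in% names(ranges)))
  beta <- fit$coef[terms]
  lo <- vapply(ranges[terms], `[`, 0, 1)
  hi <- vapply(ranges[terms], `[`, 0, 2)
  contrib <- abs(beta) * (hi - lo)
  m <- max(contrib)
  if (m <= 0) stop("all coefficients are zero over their ranges",
                   call. = FALSE)
  ref <- ifelse(beta >= 0, lo, hi) # level with the smallest beta*x
  tab <- data.table::data.table(
    term = terms, beta = unname(beta), ref_value = unname(ref),
    max_points = unname(100 * contrib / m))
  base_lp <- unname(fit$coef["(Intercept)"] + sum(beta * ref))
  structure(list(table = tab, scale = m, base_lp = base_lp,
                 intercept = unname(fit$coef["(Intercept)"])),
            class = "nomogram_spec")
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat("<nomogram_spec>\n")
  print(x$table[, .(term, beta = round(beta, 3),
                    max_points = round(max_points, 1))])
  cat(sprintf("  baseline probability %.4f\n", stats::plogis(x$base_lp)))
  invisible(x)
}

#' Points contributed by each covariate of a profile
#' @param nomogram a `nomogram_spec`.
#' @param profile named vector/list of covariate values.
#' @return named numeric vector of points (same order as the nomogram
#'   table).
#' @export
nomogram_points <- function(nomogram, profile) {
  tab <- nomogram$table
  missing_cov <- setdiff(tab$term, names(profile))
  if (length(missing_cov) > 0) {
    stop("profile does not cover covariate(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  x <- vapply(tab$term, function(tm) as.numeric(profile[[tm]]), 0)
  pts <- 100 * (tab$beta * x - tab$beta * tab$ref_value) / nomogram$scale
  if (any(pts < -1e-9 | pts > tab$max_points + 1e-9)) {
    stop("out-of-range covariate level in profile", call. = FALSE)
  }
  stats::setNames(pts, tab$term)
}

#' Predicted probability from a nomogram
#'
#' Sums the per-covariate points of the profile and maps the total
#' through the points-to-probability curve. Strictly increasing in any
#' covariate with positive coefficient, and identical (to numerical
#' precision) to the direct logistic prediction.
#'
#' @param nomogram a `nomogram_spec`.
#' @param profile named vector/list covering every nomogram covariate.
#' @return probability in (0, 1).
#' @export
predict_risk <- function(nomogram, profile) {
  total <- sum(nomogram_points(nomogram, profile))
  points_to_probability(nomogram, total)
}

#' The points-to-probability mapping
#' @param nomogram a `nomogram_spec`.
#' @param total total points (numeric vector).
#' @return probabilities; monotone increasing in `total`.
#' @export
points_to_probability <- function(nomogram, total) {
  stats::plogis(nomogram$base_lp + total * nomogram$scale / 100)
}
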