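# Independent oracles, implemented before the tests that use them and
# kept independent of the code paths they check.

# Brute-force posterior summaries by quadrature on a fine log-spaced
# lambda grid: posterior density proportional to
# prior_pdf(lambda) * Poisson(a; lambda * E). Never uses the conjugate
# gamma-mixture update the package relies on.
ebgm_quadrature <- function(prior, a, E, n_grid = 60000) {
  prior_pdf <- function(l) {
    prior$p * stats::dgamma(l, prior$alpha1, rate = prior$beta1) +
      (1 - prior$p) * stats::dgamma(l, prior$alpha2, rate = prior$beta2)
  }
  # grid wide enough to hold all posterior mass for either component
  qlo <- min(stats::qgamma(1e-8, prior$alpha1 + a, rate = prior$beta1 + E),
             stats::qgamma(1e-8, prior$alpha2 + a, rate = prior$beta2 + E))
  qhi <- max(stats::qgamma(1 - 1e-8, prior$alpha1 + a,
                           rate = prior$beta1 + E),
             stats::qgamma(1 - 1e-8, prior$alpha2 + a,
                           rate = prior$beta2 + E))
  grid <- exp(seq(log(max(qlo, 1e-12)), log(qhi), length.out = n_grid))
  lw <- log(prior_pdf(grid)) + stats::dpois(a, grid * E, log = TRUE)
  lw[!is.finite(lw)] <- -Inf
  w <- exp(lw - max(lw))
  dl <- c(diff(grid), 0)
  mass <- w * dl
  mass <- mass / sum(mass)
  est <- exp(sum(log(grid) * mass))
  cdf <- cumsum(mass)
  q <- function(pr) grid[which.max(cdf >= pr)]
  list(ebgm = est, eb05 = q(0.05), eb95 = q(0.95))
}

# Exact enumeration of the two-step dedup removal counts from raw field
# vectors, using base R paste/duplicated instead of the package's
# data.table grouping.
dedup_counts_oracle <- function(demo, drugsets, outcsets, reacsets) {
  age_yr <- faerspv::age_to_years(demo$age, demo$age_cod)
  k1 <- paste(demo$caseid, demo$i_f_code, demo$event_dt, age_yr,
              demo$sex, demo$reporter_country, drugsets, outcsets,
              sep = "\r")
  step1_removed <- sum(duplicated(k1))
  # survivor per key-1 group = largest primaryid; membership in the
  # retained set is what matters for step-2 counting
  ord <- order(as.numeric(demo$primaryid))
  k1o <- k1[ord]
  keep_idx <- ord[!duplicated(k1o, fromLast = TRUE)]
  k2 <- paste(demo$event_dt, age_yr, demo$sex, demo$reporter_country,
              drugsets, reacsets, sep = "\r")[keep_idx]
  step2_removed <- sum(duplicated(k2))
  ord2 <- order(as.numeric(demo$primaryid[keep_idx]))
  k2o <- k2[ord2]
  retained_idx <- keep_idx[ord2][!duplicated(k2o, fromLast = TRUE)]
  list(step1 = step1_removed, step2 = step2_removed,
       retained = demo$primaryid[retained_idx])
}

report_sets_oracle <- function(bundle) {
  set_of <- function(tab, col) {
    sp <- split(tab[[col]], tab$primaryid)
    vapply(sp, function(v) paste(sort(unique(v)), collapse = "|"), "")
  }
  ids <- bundle$demo$primaryid
  d <- set_of(bundle$drug, "drugname")
  o <- set_of(bundle$outc, "outc_cod")
  r <- set_of(bundle$reac, "pt_code")
  pick <- function(s) ifelse(ids %in% names(s), s[ids], "")
  list(drugsets = unname(pick(d)), outcsets = unname(pick(o)),
       reacsets = unname(pick(r)))
}
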