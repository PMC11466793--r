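test_that("build_table partitions a small enumerated universe", {
  # 10 reports, 4 with drug, 2 of those with event, 1 other event report
  all_ids <- as.character(1:10)
  drug_ids <- as.character(1:4)
  case_ids <- c("1", "2", "5")
  tb <- build_table(case_ids, drug_ids, all_ids)
  expect_equal(unlist(tb[c("a", "b", "c", "d")]),
               c(a = 2, b = 2, c = 1, d = 5))
  expect_error(build_table(case_ids, drug_ids, character()), "empty")
})

test_that("a degenerate comparator (drug set = universe) is undefined", {
  tb <- build_table(c("1", "2"), as.character(1:6), as.character(1:6))
  expect_equal(tb$c + tb$d, 0)
  expect_true(is.na(prr(tb)$prr))
  expect_true(is.na(ror(tb, correction = FALSE)$ror))
})

test_that("ROR matches direct formula evaluation", {
  r <- ror(c(5, 95, 10, 890))
  expect_equal(r$ror, (5 * 890) / (95 * 10), tolerance = 1e-12)
  se <- sqrt(1 / 5 + 1 / 95 + 1 / 10 + 1 / 890)
  expect_equal(r$lo, exp(log(4450 / 950) - 1.96 * se), tolerance = 1e-12)
  expect_equal(r$hi, exp(log(4450 / 950) + 1.96 * se), tolerance = 1e-12)
  # symmetric table
  r1 <- ror(c(10, 10, 10, 10))
  expect_equal(r1$ror, 1)
  expect_true(r1$lo < 1 && r1$hi > 1)
  # zero cell: 0.5 correction forced by the stated rule
  r0 <- ror(c(0, 10, 10, 100))
  expect_equal(r0$ror, (0.5 * 100.5) / (10.5 * 10.5), tolerance = 1e-12)
  expect_true(is.na(ror(c(0, 10, 10, 100), correction = FALSE)$ror))
})

test_that("PRR and chi-square match direct formula evaluation", {
  p <- prr(c(5, 95, 10, 890))
  expect_equal(p$prr, (5 / 100) / (10 / 900), tolerance = 1e-12)
  expect_equal(p$chisq,
               1000 * (5 * 890 - 95 * 10)^2 / (100 * 900 * 15 * 985),
               tolerance = 1e-12)
  expect_equal(prr(c(10, 10, 10, 10)), list(prr = 1, chisq = 0))
  # cell scaling: PRR invariant, chi-square scales linearly
  p10 <- prr(10 * c(5, 95, 10, 890))
  expect_equal(p10$prr, p$prr, tolerance = 1e-12)
  expect_equal(p10$chisq, 10 * p$chisq, tolerance = 1e-9)
})

test_that("PRR and chi-square agree with stats oracles on a random table", {
  set.seed(42)
  for (i in 1:20) {
    x <- matrix(rpois(4, 40) + 1, 2)
    p <- prr(c(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
    cs <- suppressWarnings(chisq.test(x, correct = FALSE))
    expect_equal(p$chisq, unname(cs$statistic), tolerance = 1e-9)
    r <- ror(c(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
    ft <- fisher.test(x)
    # conditional MLE differs from the cross-product OR, but both must
    # fall on the same side of 1
    expect_equal(sign(log(r$ror)), sign(log(ft$estimate)),
                 ignore_attr = TRUE)
  }
})

test_that("information component matches formula and its asymptotic limit", {
  ic <- information_component(c(5, 95, 10, 890))
  expect_equal(ic$E, 100 * 15 / 1000)
  expect_equal(ic$ic, log2(5.5 / 2.0), tolerance = 1e-12)
  expect_equal(ic$ic025, log2(5.5 / 2.0) - 3.3 / sqrt(5.5) - 2 / 5.5^1.5,
               tolerance = 1e-12)
  # observed equals expected -> IC = 0 exactly (symmetric margins)
  ic0 <- information_component(c(20, 20, 20, 20))
  expect_equal(ic0$ic, 0)
  # large a at fixed a/E: correction terms vanish, IC025 -> IC
  big <- information_component(c(40000, 10000, 10000, 140000))
  expect_lt(big$ic - big$ic025, 0.02)
})

test_that("estimators are null on symmetric a = E tables", {
  for (k in c(5, 50, 500)) {
    tb <- c(k, k, k, k)
    expect_equal(ror(tb)$ror, 1)
    expect_equal(prr(tb)$prr, 1)
    expect_equal(information_component(tb)$ic, 0)
  }
})

test_that("transposition symmetry and ROR >= PRR hold on random tables", {
  set.seed(7)
  for (i in 1:200) {
    x <- rpois(4, c(20, 200, 200, 2000)) + 1
    r <- ror(x)$ror
    r_t <- ror(x[c(1, 3, 2, 4)])$ror # swap drug/event roles
    expect_equal(r, r_t, tolerance = 1e-12)
    p <- prr(x)$prr
    if (!is.na(p) && p > 1) expect_gte(r, p - 1e-12)
  }
})

test_that("signal flags respect the minimum-count gate", {
  # a = 2 with an enormous ROR must never be flagged jointly
  b <- generate_bundle(small_null_config(n = 3000, seed = 71))
  prior <- fit_mgps(pair_counts(b))
  tab <- data.table::data.table(drug = "x", event = "y", event_type = "pt",
                                a = 2L, b = 3L, c = 4L, d = 4000L)
  res <- faerspv:::.signal_stats(tab, prior, signal_thresholds())
  expect_gt(res$ror, 100)
  expect_false(res$flag_joint)
})

test_that("detect_signals reports pooled and per-drug rows that partition
           the universe", {
  cfg <- small_null_config(
    n = 8000, seed = 81,
    planted_rr = data.table::data.table(drug = "crizotinib",
                                        pt_code = "10022611", rr = 8))
  b <- generate_bundle(cfg)
  sig <- detect_signals(b)
  smq_rows <- sig[sig$event_type == "smq"]
  expect_setequal(smq_rows$drug, c(alk_drugs(), "ALK TKIs"))
  n <- n_reports(b)
  expect_true(all(smq_rows$a + smq_rows$b + smq_rows$c + smq_rows$d == n))
  # the planted pair carries the strongest PT-level ROR
  pt_rows <- sig[sig$event_type == "pt" & sig$drug == "crizotinib"]
  expect_equal(pt_rows$event[which.max(pt_rows$ror)],
               "Interstitial lung disease")
})
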