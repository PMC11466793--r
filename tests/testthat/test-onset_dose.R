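test_that("time to onset is calendar arithmetic with anomaly handling", {
  expect_equal(as.integer(time_to_onset("20200101", "20200203")), 33L)
  # event before start: missing + anomaly counted
  tto <- time_to_onset("20200301", "20200101")
  expect_true(is.na(tto))
  expect_equal(attr(tto, "n_anomalies"), 1L)
  # partial start date uses the month midpoint
  expect_equal(as.integer(time_to_onset("202006", "20200720")), 35L)
  expect_true(is.na(time_to_onset("bad", "20200720")))
})

test_that("onset summary uses interpolated quartiles and correct fractions", {
  rec <- data.table::data.table(
    primaryid = as.character(1:3), drug = "x",
    tto_days = c(10L, 20L, 30L), within_4wk = c(TRUE, TRUE, FALSE),
    within_8wk = c(TRUE, TRUE, TRUE), cumulative_dose = NA_real_)
  s <- onset_summary(rec)
  expect_equal(s$median_days, 20)
  expect_equal(s$q1_days, unname(quantile(c(10, 20, 30), 0.25)))
  expect_equal(s$pct_within_4wk, 100 * 2 / 3)
  expect_equal(s$pct_within_8wk, 100)
  # all under 28 days -> both fractions 100
  rec2 <- data.table::copy(rec)[, tto_days := c(1L, 5L, 20L)]
  s2 <- onset_summary(rec2)
  expect_equal(s2$pct_within_4wk, 100)
  # quartiles match the reference implementation on random samples
  set.seed(9)
  x <- as.integer(round(rlnorm(101, 3, 1)))
  s3 <- onset_summary(data.table::data.table(
    primaryid = as.character(seq_along(x)), drug = "y", tto_days = x,
    within_4wk = x <= 28, within_8wk = x <= 56,
    cumulative_dose = NA_real_))
  expect_equal(s3$median_days, unname(quantile(x, 0.5, type = 7)))
  expect_equal(s3$q3_days, unname(quantile(x, 0.75, type = 7)))
})

test_that("empty groups yield an empty summary, not an error", {
  rec <- data.table::data.table(
    primaryid = "1", drug = "x", tto_days = NA_integer_,
    within_4wk = NA, within_8wk = NA, cumulative_dose = NA_real_)
  s <- onset_summary(rec)
  expect_equal(s$n_tto, 0L)
  expect_true(is.na(s$median_days))
})

test_that("fractions are monotone in the time threshold", {
  b <- generate_bundle(small_null_config(n = 2000, seed = 91))
  study <- data.table::data.table(
    primaryid = b$demo$primaryid,
    drug = b$drug[b$drug$role_cod == "PS"]$drugname[
      match(b$demo$primaryid, b$drug[b$drug$role_cod == "PS"]$primaryid)])
  recs <- onset_records(b, study)
  s <- onset_summary(recs)
  expect_true(all(s$pct_within_4wk <= s$pct_within_8wk + 1e-9))
})

test_that("cumulative dose is dose rate x TTO / weight with missing rules", {
  expect_equal(cumulative_dose(500, 28, 64), 218.75)
  expect_equal(cumulative_dose(500, 0, 64), 0)
  expect_true(is.na(cumulative_dose(500, 28, NA)))
  expect_true(is.na(cumulative_dose(NA, 28, 64)))
})

test_that("a planted log-normal onset median is recovered", {
  # drugs with median 30 d onset at n = 500 known-TTO cases: the sample
  # median over 10 seeds stays within (24, 37)
  drug_names <- synth_config(n_reports = 1)$drugs$drug
  for (s in 1:10) {
    cfg <- small_null_config(
      n = 500, seed = 200 + s,
      onset = data.table::data.table(drug = drug_names,
                                     meanlog = log(30), sdlog = 1.0))
    b <- generate_bundle(cfg)
    led <- truth_ledger(b)
    study <- data.table::data.table(primaryid = led$primaryid,
                                    drug = led$ps_drug)
    recs <- onset_records(b, study)
    med <- onset_summary(recs, by = NULL)$median_days
    expect_gte(med, 24)
    expect_lte(med, 37)
  }
})
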