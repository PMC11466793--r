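test_that("config validation rejects invalid probabilities and sizes", {
  expect_error(synth_config(n_reports = 0), "positive")
  expect_error(synth_config(duplicate_rate = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(planted_rr = data.table::data.table(
    drug = "crizotinib", pt_code = "10022611", rr = -1)), ">= 0")
  expect_error(synth_config(planted_rr = data.table::data.table(
    drug = "nosuchdrug", pt_code = "10022611", rr = 2)), "unknown drug")
})

test_that("same seed and config give byte-identical serialized output", {
  cfg <- synth_config(n_reports = 500, seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_synthetic_quarter(simulate_faers(cfg), d1)
  p2 <- write_synthetic_quarter(simulate_faers(cfg), d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), info = nm)
  }
})

test_that("generated bundles have referential integrity and PS structure", {
  b <- simulate_faers(synth_config(n_reports = 800, seed = 3))
  expect_silent(validate_bundle(b))
  # exactly one primary-suspect drug per report
  ps <- b$drug[b$drug$role_cod == "PS"]
  expect_equal(sort(unique(ps$primaryid)), sort(b$demo$primaryid))
  expect_equal(anyDuplicated(ps$primaryid), 0L)
  # every report has at least one reaction
  expect_setequal(unique(b$reac$primaryid), b$demo$primaryid)
  # ledger covers every emitted version
  led <- truth_ledger(b)
  expect_setequal(led$primaryid, b$demo$primaryid)
})

test_that("zero duplicate rate and missingness leave the bundle unchanged", {
  cfg <- small_null_config(n = 400, seed = 5)
  b0 <- generate_bundle(cfg)
  b1 <- inject_duplicates_and_missingness(b0, cfg)
  for (tab in c("demo", "drug", "reac", "ther", "indi", "outc")) {
    expect_equal(as.data.frame(b1[[tab]]), as.data.frame(b0[[tab]]),
                 info = tab)
  }
})

test_that("duplicate counts follow Binomial(n, rate) within exact 99% bounds", {
  # qbinom(c(.005,.995), 1000, .1) = (76, 125)
  cfg <- synth_config(n_reports = 1000, duplicate_rate = 0.1,
                      followup_rate = 0, seed = 21)
  led <- truth_ledger(simulate_faers(cfg))
  d <- sum(led$is_injected_duplicate)
  expect_gte(d, stats::qbinom(0.005, 1000, 0.1))
  expect_lte(d, stats::qbinom(0.995, 1000, 0.1))
})

test_that("full missingness blanks the field while the ledger keeps truth", {
  cfg <- synth_config(n_reports = 300, duplicate_rate = 0,
                      followup_rate = 0,
                      missingness = c(event_dt = 0, age = 1, sex = 0,
                                      reporter_country = 0, wt = 0,
                                      dose_amt = 0),
                      seed = 9)
  b <- simulate_faers(cfg)
  expect_true(all(is.na(b$demo$age)))
  led <- truth_ledger(b)
  expect_true(all(!is.na(led$true_age_yr)))
})

test_that("follow-up versions share the case id and are at least as complete", {
  cfg <- synth_config(n_reports = 600, duplicate_rate = 0,
                      followup_rate = 0.3, seed = 13)
  b <- simulate_faers(cfg)
  fu <- b$demo[b$demo$i_f_code == "F"]
  expect_gt(nrow(fu), 0)
  expect_true(all(fu$caseid %in% b$demo[b$demo$i_f_code == "I"]$caseid))
  expect_true(all(fu$primaryid != fu$caseid))
  # follow-ups are never blanked: all four demographic fields populated
  expect_true(all(!is.na(fu$event_dt) & !is.na(fu$age) & !is.na(fu$sex) &
                    !is.na(fu$reporter_country)))
})

test_that("planted relative risks shift pair-level event rates as configured", {
  # crizotinib ILD PT at rr = 4: observed a should be near
  # n_crizotinib * min(1, 4 * 0.004), far above the null expectation
  cfg <- small_null_config(
    n = 20000, seed = 17,
    planted_rr = data.table::data.table(drug = "crizotinib",
                                        pt_code = "10022611", rr = 4))
  b <- generate_bundle(cfg)
  pc <- pair_counts(b)
  row <- pc[pc$drug == "crizotinib" & pc$pt_code == "10022611"]
  expect_gt(row$a / row$E, 2.5)
  null_row <- pc[pc$drug == "alectinib" & pc$pt_code == "10022611"]
  expect_lt(null_row$a / max(null_row$E, 1), 2.5)
})
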