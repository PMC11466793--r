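test_that("imputation fills a single missing field from the max donor", {
  # case 10: donor A(60, complete), recipient B(age missing, 3 present)
  b <- faers_bundle(demo = rbind(
    demo_row("10", caseid = "10", age = "60"),
    demo_row("11", caseid = "10", age = NA_character_,
             age_cod = NA_character_)))
  out <- impute_missing(b)
  expect_equal(out$demo[out$demo$primaryid == "11"]$age, "60")
  expect_equal(out$demo[out$demo$primaryid == "11"]$age_yr, 60)
  expect_equal(attr(out, "imputation_counts")[["age"]], 1L)
})

test_that("two complete donors donate the maximum value", {
  b <- faers_bundle(demo = rbind(
    demo_row("20", caseid = "20", age = "55"),
    demo_row("21", caseid = "20", age = "62"),
    demo_row("22", caseid = "20", age = NA_character_)))
  out <- impute_missing(b)
  expect_equal(out$demo[out$demo$primaryid == "22"]$age_yr, 62)
})

test_that("imputation is strictly single-field and needs a complete donor", {
  b <- faers_bundle(demo = rbind(
    # case 30: recipient missing two fields -> untouched
    demo_row("30", caseid = "30"),
    demo_row("31", caseid = "30", age = NA_character_, sex = NA_character_),
    # case 40: only version, missing one field -> no donor, untouched
    demo_row("40", caseid = "40", sex = NA_character_),
    # case 50: donor itself incomplete -> no donation
    demo_row("50", caseid = "50", age = NA_character_),
    demo_row("51", caseid = "50", sex = NA_character_)))
  out <- impute_missing(b)
  expect_true(is.na(out$demo[out$demo$primaryid == "31"]$age))
  expect_true(is.na(out$demo[out$demo$primaryid == "31"]$sex))
  expect_true(is.na(out$demo[out$demo$primaryid == "40"]$sex))
  expect_true(is.na(out$demo[out$demo$primaryid == "50"]$age))
  expect_true(is.na(out$demo[out$demo$primaryid == "51"]$sex))
  expect_equal(sum(unlist(attr(out, "imputation_counts"))), 0L)
})

test_that("step 1 collapses identical versions keeping the largest id", {
  b <- faers_bundle(
    demo = rbind(demo_row("100", caseid = "100"),
                 demo_row("101", caseid = "100")),
    drug = rbind(drug_row("100", "crizotinib"),
                 drug_row("101", "crizotinib")),
    reac = rbind(reac_row("100", "10028813"), reac_row("101", "10028813")))
  dd <- deduplicate(b)
  expect_equal(dd$report$step1_removed, 1L)
  expect_equal(dd$bundle$demo$primaryid, "101")
})

test_that("versions differing in a key field are both retained by step 1", {
  b <- faers_bundle(
    demo = rbind(demo_row("100", caseid = "100", age = "60"),
                 demo_row("101", caseid = "100", age = "61")),
    reac = rbind(reac_row("100", "10028813"), reac_row("101", "10019211")))
  dd <- deduplicate(b)
  expect_equal(dd$report$step1_removed, 0L)
  expect_equal(dd$report$step2_removed, 0L)
  expect_equal(sort(dd$bundle$demo$primaryid), c("100", "101"))
})

test_that("step 2 collapses cross-case rows identical on demographics,
           drugs and reactions", {
  b <- faers_bundle(
    demo = rbind(demo_row("200", caseid = "200"),
                 demo_row("300", caseid = "300")),
    drug = rbind(drug_row("200", "crizotinib"),
                 drug_row("300", "crizotinib")),
    reac = rbind(reac_row("200", "10022611"), reac_row("300", "10022611")))
  dd <- deduplicate(b)
  expect_equal(dd$report$step1_removed, 0L)
  expect_equal(dd$report$step2_removed, 1L)
  expect_equal(dd$bundle$demo$primaryid, "300")
})

test_that("dedup is idempotent and order-independent", {
  b <- simulate_faers(synth_config(n_reports = 1500, seed = 31))
  dd1 <- deduplicate(impute_missing(b))
  dd2 <- deduplicate(dd1$bundle)
  expect_equal(dd2$report$duplicates_removed, 0L)
  expect_setequal(dd2$bundle$demo$primaryid, dd1$bundle$demo$primaryid)
  # shuffle input row order: retained set unchanged
  shuf <- b
  set.seed(1)
  for (tab in c("demo", "drug", "reac", "ther", "indi", "outc")) {
    shuf[[tab]] <- shuf[[tab]][sample(nrow(shuf[[tab]]))]
  }
  dd3 <- deduplicate(impute_missing(shuf))
  expect_setequal(dd3$bundle$demo$primaryid, dd1$bundle$demo$primaryid)
})

test_that("removal counts match the brute-force enumeration oracle", {
  b <- simulate_faers(synth_config(n_reports = 1200, duplicate_rate = 0.08,
                                   followup_rate = 0.05, seed = 41))
  imp <- impute_missing(b)
  sets <- report_sets_oracle(imp)
  oracle <- dedup_counts_oracle(imp$demo, sets$drugsets, sets$outcsets,
                                sets$reacsets)
  dd <- deduplicate(imp)
  expect_equal(dd$report$step1_removed, oracle$step1)
  expect_equal(dd$report$step2_removed, oracle$step2)
})

test_that("the under-18 exclusion is a strict boundary on known ages", {
  b <- faers_bundle(demo = rbind(
    demo_row("1", age = "17.9"),
    demo_row("2", age = "18"),
    demo_row("3", age = NA_character_, age_cod = NA_character_),
    demo_row("4", age = "215", age_cod = "MON")))  # 17.9 yr
  ex <- apply_exclusions(b)
  expect_setequal(ex$bundle$demo$primaryid, c("2", "3"))
  expect_equal(ex$report$under18_removed, 2L)
  # idempotent
  ex2 <- apply_exclusions(ex$bundle)
  expect_equal(ex2$report$under18_removed, 0L)
})

test_that("study selection requires primary-suspect role", {
  b <- faers_bundle(
    demo = rbind(demo_row("1"), demo_row("2")),
    drug = rbind(drug_row("1", "pembrolizumab"),
                 drug_row("1", "Crizotinib ", role_cod = "C",
                          drug_seq = "2"),
                 drug_row("2", "XALKORI")))
  study <- select_study_reports(b)
  expect_equal(study$primaryid, "2")  # brand name, PS role
  expect_equal(study$drug, "crizotinib")
})

test_that("the cleaning report satisfies count conservation", {
  b <- simulate_faers(synth_config(n_reports = 2000, seed = 51))
  cl <- clean_bundle(b)
  r <- cl$report
  expect_equal(r$retained,
               r$input_reports - r$duplicates_removed - r$under18_removed)
  expect_equal(r$retained, nrow(cl$bundle$demo))
})
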