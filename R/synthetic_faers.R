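# Synthetic FAERS generator. Emits quarterly bundles with known planted
# structure -- drug-event relative risks, duplicates, missingness, onset
# distributions -- plus a truth ledger, so cleaning, signal detection and
# risk modelling can all be validated against ground truth.

#' The five ALK tyrosine kinase inhibitors
#' @return character vector of generic drug names.
#' @export
alk_drugs <- function() {
  c("crizotinib", "ceritinib", "alectinib", "brigatinib", "lorlatinib")
}

.default_drugs <- function() {
  # PS-use shares: the five ALK TKIs proportional to their FAERS report
  # volumes, scaled to ~10% of all reports so desk-scale bundles contain
  # enough TKI reports; the rest split over oncology comparators.
  data.table::data.table(
    drug = c(alk_drugs(),
             "gefitinib", "osimertinib", "pembrolizumab", "carboplatin",
             "docetaxel"),
    p_use = c(0.0455, 0.0096, 0.0233, 0.0107, 0.0124,
              0.16, 0.18, 0.22, 0.18, 0.1585)
  )
}

.default_events <- function() {
  # Background per-report reporting probabilities. The first six PTs are
  # the interstitial lung disease SMQ (20000042) terms; their background
  # rates sum to ~0.9%, near the ILD share observed among non-TKI reports.
  data.table::data.table(
    pt_code = c("10022611", "10035742", "10037383", "10066728", "10078268",
                "10087834",
                "10028813", "10012735", "10019211", "10016256", "10047700",
                "10013968", "10037660", "10037844", "10010774"),
    pt_name = c("Interstitial lung disease", "Pneumonitis",
                "Pulmonary fibrosis", "Acute interstitial pneumonitis",
                "Idiopathic interstitial pneumonia",
                "Interstitial lung abnormality",
                "Nausea", "Diarrhoea", "Headache", "Fatigue", "Vomiting",
                "Dyspnoea", "Pyrexia", "Rash", "Constipation"),
    p_background = c(0.004, 0.003, 0.0012, 0.0004, 0.0002, 0.0002,
                     0.05, 0.04, 0.03, 0.03, 0.025,
                     0.02, 0.02, 0.02, 0.015)
  )
}

.default_concomitants <- function() {
  # Concomitant (role C) drugs with the indication PT recorded in INDI;
  # these drive the concomitant-disease and concomitant-drug covariates
  # of the risk model.
  data.table::data.table(
    drug = c("amlodipine", "furosemide", "magnesium oxide", "lansoprazole",
             "pantoprazole", "acetaminophen", "oxycodone", "metoclopramide",
             "metformin", "atorvastatin"),
    p_use = c(0.08, 0.05, 0.06, 0.05, 0.05, 0.10, 0.04, 0.05, 0.07, 0.08),
    indi_pt_code = c("10020772", "10020772", "10010774", "10017944",
                     "10017944", "10033371", "10033371", "10028813",
                     "10012601", "10058108"),
    indi_pt_name = c("Hypertension", "Hypertension", "Constipation",
                     "Gastric disorder", "Gastric disorder", "Pain", "Pain",
                     "Nausea", "Diabetes mellitus", "Dyslipidaemia")
  )
}

.default_onset <- function(drugs) {
  # Log-normal time-to-onset per primary-suspect drug. Medians for the
  # ALK TKIs follow the reported per-drug ILD onset medians (29/70/49/7/36
  # days); comparators get a generic 40-day median. sdlog 1.4 gives the
  # heavy right tail typical of spontaneous-report onset data.
  med <- c(crizotinib = 29, ceritinib = 70, alectinib = 49,
           brigatinib = 7, lorlatinib = 36)
  m <- ifelse(drugs %in% names(med), med[drugs], 40)
  data.table::data.table(drug = drugs, meanlog = log(m), sdlog = 1.4)
}

.default_doses <- function(drugs) {
  # Label daily doses (mg/day) for the ALK TKIs; 300 mg/day generic
  # placeholder for comparators.
  dd <- c(crizotinib = 500, ceritinib = 750, alectinib = 1200,
          brigatinib = 180, lorlatinib = 100)
  data.table::data.table(
    drug = drugs,
    daily_dose_mg = ifelse(drugs %in% names(dd), dd[drugs], 300))
}

#' Configuration for the synthetic FAERS generator
#'
#' The defaults emulate a desk-scale FAERS slice: five ALK TKIs at use
#' shares proportional to their report volumes plus oncology comparators,
#' interstitial lung disease SMQ preferred terms at ~1% total background
#' reporting probability alongside common background PTs, an adult-heavy
#' two-component age mixture with a small pediatric fraction, per-drug
#' log-normal onset models and label daily doses. All planted relative
#' risks default to 1 (null).
#'
#' @param n_reports number of base reports (case versions before
#'   duplicate/follow-up injection).
#' @param drugs `data.table(drug, p_use)` of candidate primary-suspect
#'   drugs and their sampling weights.
#' @param events `data.table(pt_code, pt_name, p_background)` of reaction
#'   PTs and background per-report probabilities.
#' @param planted_rr `data.table(drug, pt_code, rr)` of planted relative
#'   risks (missing pairs have rr = 1); the event probability for a report
#'   whose primary suspect is `drug` is `min(1, rr * p_background)`.
#' @param concomitants `data.table(drug, p_use, indi_pt_code,
#'   indi_pt_name)` of concomitant drugs, inclusion probabilities and
#'   indication PTs.
#' @param offlabel_indication_rate fraction of concomitant-drug INDI
#'   rows recorded with an unspecified-indication PT instead of the
#'   drug's usual indication, as in real reports where the indication is
#'   not stated; keeps disease indicators from being deterministic
#'   functions of drug indicators.
#' @param duplicate_rate fraction of cases emitted as an extra exact
#'   duplicate version (new report id, same case id).
#' @param followup_rate fraction of cases receiving a follow-up version
#'   (`i_f_code` "F", new report id, same case id) with equal-or-larger
#'   field completeness than the initial.
#' @param missingness named rates in `[0,1]` for blanking `event_dt`,
#'   `age`, `sex`, `reporter_country`, `wt`, `dose_amt`.
#' @param partial_date_rate fraction of event dates truncated to `YYYYMM`.
#' @param pediatric_rate fraction of reports drawn with age < 18 years
#'   (uniform 2-17), exercising the under-18 exclusion.
#' @param age_mix adult age mixture: list with `mean`, `sd`, `w` vectors.
#' @param sex_p,country_p,source_p,outcome_p named category probabilities
#'   for sex, reporter country, report source and outcome code.
#' @param outcome_any_rate probability that a report carries an outcome
#'   record at all.
#' @param onset `data.table(drug, meanlog, sdlog)` log-normal onset model
#'   per primary-suspect drug (days).
#' @param doses `data.table(drug, daily_dose_mg)` daily dose per drug.
#' @param weight_mean,weight_sd adult body-weight model (kg).
#' @param quarter quarter tag, e.g. `"23Q1"`, fixing the therapy-start
#'   date window.
#' @param seed integer RNG seed; identical seed + config gives
#'   byte-identical output.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_reports = 10000L,
                         drugs = .default_drugs(),
                         events = .default_events(),
                         planted_rr = NULL,
                         concomitants = .default_concomitants(),
                         offlabel_indication_rate = 0.15,
                         duplicate_rate = 0.05,
                         followup_rate = 0.10,
                         missingness = c(event_dt = 0.05, age = 0.10,
                                         sex = 0.05, reporter_country = 0.05,
                                         wt = 0.25, dose_amt = 0.20),
                         partial_date_rate = 0.05,
                         pediatric_rate = 0.02,
                         age_mix = list(mean = c(48, 66), sd = c(13, 10),
                                        w = c(0.4, 0.6)),
                         sex_p = c(M = 0.48, F = 0.52),
                         country_p = c(US = 0.60, JP = 0.12, FR = 0.06,
                                       DE = 0.06, GB = 0.05, CN = 0.05,
                                       IT = 0.06),
                         source_p = c(MD = 0.50, PH = 0.09, CN = 0.20,
                                      OT = 0.21),
                         outcome_p = c(HO = 0.38, DS = 0.02, LT = 0.10,
                                       DE = 0.18, OT = 0.32),
                         outcome_any_rate = 0.8,
                         onset = NULL,
                         doses = NULL,
                         weight_mean = 65, weight_sd = 15,
                         quarter = "23Q1",
                         seed = 1L) {
  drugs <- data.table::as.data.table(drugs)
  events <- data.table::as.data.table(events)
  concomitants <- data.table::as.data.table(concomitants)
  if (is.null(onset)) onset <- .default_onset(drugs$drug)
  if (is.null(doses)) doses <- .default_doses(drugs$drug)
  if (is.null(planted_rr)) {
    planted_rr <- data.table::data.table(drug = character(),
                                         pt_code = character(),
                                         rr = numeric())
  } else {
    planted_rr <- data.table::as.data.table(planted_rr)
  }
  cfg <- list(
    n_reports = as.integer(n_reports), drugs = drugs, events = events,
    planted_rr = planted_rr, concomitants = concomitants,
    offlabel_indication_rate = offlabel_indication_rate,
    duplicate_rate = duplicate_rate, followup_rate = followup_rate,
    missingness = missingness, partial_date_rate = partial_date_rate,
    pediatric_rate = pediatric_rate, age_mix = age_mix, sex_p = sex_p,
    country_p = country_p, source_p = source_p, outcome_p = outcome_p,
    outcome_any_rate = outcome_any_rate,
    onset = data.table::as.data.table(onset),
    doses = data.table::as.data.table(doses),
    weight_mean = weight_mean, weight_sd = weight_sd,
    quarter = quarter, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' @rdname synth_config
#' @param config a `synth_config`.
#' @export
validate_synth_config <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (is.na(config$n_reports) || config$n_reports <= 0) {
    stop("n_reports must be a positive integer", call. = FALSE)
  }
  probs <- c(config$drugs$p_use, config$events$p_background,
             config$concomitants$p_use, config$offlabel_indication_rate,
             config$duplicate_rate,
             config$followup_rate, config$missingness,
             config$partial_date_rate, config$pediatric_rate,
             config$sex_p, config$country_p, config$source_p,
             config$outcome_p, config$outcome_any_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities and rates must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(config$planted_rr) > 0 && any(config$planted_rr$rr < 0)) {
    stop("planted relative risks must be >= 0", call. = FALSE)
  }
  miss_fields <- c("event_dt", "age", "sex", "reporter_country", "wt",
                   "dose_amt")
  if (!all(miss_fields %in% names(config$missingness))) {
    stop("missingness must name rates for: ",
         paste(miss_fields, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(config$planted_rr$drug, config$drugs$drug)
  if (length(bad) > 0) {
    stop("planted_rr names unknown drug(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

.quarter_window <- function(quarter) {
  yy <- as.integer(substr(quarter, 1, 2))
  q <- as.integer(substr(quarter, 4, 4))
  start <- as.Date(sprintf("20%02d-%02d-01", yy, (q - 1) * 3 + 1))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1
  c(start, end)
}

.sample_cat <- function(n, p) {
  names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
}

#' Generate a synthetic FAERS quarter bundle
#'
#' Draws `n_reports` single-version reports: one primary-suspect drug per
#' report (role "PS"), concomitant drugs (role "C") with indication PTs in
#' INDI, reaction PTs drawn per (drug, PT) with probability
#' `min(1, rr * background)` (reports drawing no PT receive one filler PT
#' sampled from the background distribution, independent of drug), a
#' therapy-start record for the suspect drug, and an event date equal to
#' the therapy start plus a log-normal onset draw. Report ids are
#' synthetic integers; `caseid` equals the `primaryid` of the (only)
#' version. The attached truth ledger records the pre-noise demographics.
#'
#' @param config a [synth_config()].
#' @return a `faers_bundle` with attribute `"ledger"` (a `data.table`
#'   keyed by `primaryid`) and attribute `"config"`.
#' @export
generate_bundle <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  n <- config$n_reports
  ids <- as.character(100000000L + seq_len(n))

  ps_drug <- .sample_cat(
    n, stats::setNames(config$drugs$p_use, config$drugs$drug))

  # age: pediatric fraction + two-component adult normal mixture
  ped <- stats::runif(n) < config$pediatric_rate
  comp <- sample.int(length(config$age_mix$w), n, replace = TRUE,
                     prob = config$age_mix$w)
  age <- stats::rnorm(n, config$age_mix$mean[comp], config$age_mix$sd[comp])
  age <- pmin(pmax(round(age), 18), 100)
  age[ped] <- sample(2:17, sum(ped), replace = TRUE)

  sex <- .sample_cat(n, config$sex_p)
  country <- .sample_cat(n, config$country_p)
  occp <- .sample_cat(n, config$source_p)
  wt <- round(pmin(pmax(stats::rnorm(n, config$weight_mean,
                                     config$weight_sd), 35), 150), 1)

  win <- .quarter_window(config$quarter)
  start_date <- win[1] + sample.int(as.integer(win[2] - win[1]) + 1L, n,
                                    replace = TRUE) - 1L
  onset <- config$onset[match(ps_drug, drug)]
  tto <- round(stats::rlnorm(n, onset$meanlog, onset$sdlog))
  event_date <- start_date + tto
  event_dt <- format(event_date, "%Y%m%d")
  partial <- stats::runif(n) < config$partial_date_rate
  event_dt[partial] <- substr(event_dt[partial], 1, 6)

  # reaction draws: per event PT, probability min(1, rr * background)
  ev <- config$events
  rr_mat <- matrix(1, nrow = nrow(config$drugs), ncol = nrow(ev),
                   dimnames = list(config$drugs$drug, ev$pt_code))
  if (nrow(config$planted_rr) > 0) {
    for (k in seq_len(nrow(config$planted_rr))) {
      rr_mat[config$planted_rr$drug[k], config$planted_rr$pt_code[k]] <-
        config$planted_rr$rr[k]
    }
  }
  p_event <- pmin(1, rr_mat[ps_drug, , drop = FALSE] *
                    matrix(ev$p_background, n, nrow(ev), byrow = TRUE))
  hits <- matrix(stats::runif(n * nrow(ev)), n) < p_event
  none <- rowSums(hits) == 0L
  if (any(none)) {
    # a spontaneous report always lists at least one reaction; reports
    # drawing none receive a common background PT (>= 1% background
    # rate), drug-independently, so rare-event rates stay at their
    # configured values
    common <- which(ev$p_background >= 0.01)
    if (length(common) == 0) common <- seq_len(nrow(ev))
    filler <- common[sample.int(length(common), sum(none), replace = TRUE,
                                prob = ev$p_background[common])]
    hits[cbind(which(none), filler)] <- TRUE
  }
  idx <- which(hits, arr.ind = TRUE)
  reac <- data.table::data.table(
    primaryid = ids[idx[, 1]],
    pt_code = ev$pt_code[idx[, 2]],
    pt_name = ev$pt_name[idx[, 2]])
  data.table::setorder(reac, primaryid, pt_code)

  # drugs: PS row + concomitant rows with INDI indications
  dose <- config$doses[match(ps_drug, drug), daily_dose_mg]
  drug_tab <- data.table::data.table(
    primaryid = ids, drug_seq = "1", role_cod = "PS", drugname = ps_drug,
    dose_amt = as.character(dose), dose_unit = "MG")
  cc <- config$concomitants
  chits <- matrix(stats::runif(n * nrow(cc)), n) <
    matrix(cc$p_use, n, nrow(cc), byrow = TRUE)
  cidx <- which(chits, arr.ind = TRUE)
  if (nrow(cidx) > 0) {
    ord <- order(cidx[, 1], cidx[, 2])
    cidx <- cidx[ord, , drop = FALSE]
    seqno <- as.character(1L + stats::ave(cidx[, 1], cidx[, 1],
                                          FUN = seq_along))
    con_tab <- data.table::data.table(
      primaryid = ids[cidx[, 1]], drug_seq = seqno, role_cod = "C",
      drugname = cc$drug[cidx[, 2]], dose_amt = NA_character_,
      dose_unit = NA_character_)
    indi <- data.table::data.table(
      primaryid = ids[cidx[, 1]], indi_drug_seq = seqno,
      indi_pt_code = cc$indi_pt_code[cidx[, 2]],
      indi_pt_name = cc$indi_pt_name[cidx[, 2]])
    offlabel <- stats::runif(nrow(indi)) < config$offlabel_indication_rate
    indi[offlabel, `:=`(indi_pt_code = "10070592",
                        indi_pt_name = "Product used for unknown indication")]
    drug_tab <- rbind(drug_tab, con_tab)
  } else {
    indi <- NULL
  }
  data.table::setorder(drug_tab, primaryid, drug_seq)

  ther <- data.table::data.table(
    primaryid = ids, dsg_drug_seq = "1",
    start_dt = format(start_date, "%Y%m%d"), end_dt = NA_character_)

  has_outc <- stats::runif(n) < config$outcome_any_rate
  outc <- data.table::data.table(
    primaryid = ids[has_outc],
    outc_cod = .sample_cat(sum(has_outc), config$outcome_p))

  demo <- data.table::data.table(
    primaryid = ids, caseid = ids, caseversion = "1", i_f_code = "I",
    event_dt = event_dt, age = as.character(age), age_cod = "YR",
    sex = sex, wt = as.character(wt), wt_cod = "KG",
    reporter_country = country, occp_cod = occp)

  bundle <- faers_bundle(demo = demo, drug = drug_tab, reac = reac,
                         ther = ther, indi = indi, outc = outc,
                         validate = FALSE)
  ledger <- data.table::data.table(
    primaryid = ids, caseid = ids, version = 1L,
    is_injected_duplicate = FALSE, is_followup = FALSE,
    ps_drug = ps_drug, true_event_dt = event_dt,
    true_age_yr = as.numeric(age), true_sex = sex, true_country = country,
    true_wt_kg = as.numeric(wt), tto_days = as.numeric(tto))
  data.table::setattr(bundle, "ledger", ledger)
  data.table::setattr(bundle, "config", config)
  bundle
}

#' Inject duplicate case versions and field missingness
#'
#' Adds noise of the kind the cleaning pipeline removes. A
#' `duplicate_rate` fraction of cases is re-emitted as an exact duplicate
#' version (same case id and fields, new larger report id); a
#' `followup_rate` fraction receives a follow-up version (`i_f_code` "F",
#' `caseversion` 2). Demographic fields of initial versions and singleton
#' reports are then blanked at the configured rates; follow-up versions
#' are never blanked, so later versions carry equal-or-larger completeness
#' by construction. The pre-blanking truth is kept in the `"ledger"`
#' attribute.
#'
#' @param bundle output of [generate_bundle()].
#' @param config the same [synth_config()].
#' @return a `faers_bundle` with updated `"ledger"` attribute.
#' @export
inject_duplicates_and_missingness <- function(bundle, config) {
  stopifnot(inherits(bundle, "faers_bundle"))
  ledger <- attr(bundle, "ledger")
  set.seed(config$seed + 1000003L)
  demo <- data.table::copy(bundle$demo)
  base_ids <- demo$primaryid
  n <- length(base_ids)
  next_id <- max(as.integer(base_ids)) + 1L

  clone_children <- function(src_ids, new_ids) {
    map <- stats::setNames(new_ids, src_ids)
    out <- list()
    for (nm in c("drug", "reac", "ther", "indi", "outc")) {
      child <- bundle[[nm]][primaryid %chin% src_ids]
      child[, primaryid := unname(map[primaryid])]
      out[[nm]] <- child
    }
    out
  }

  # exact duplicate versions: same caseid and all fields, new primaryid
  dup <- stats::runif(n) < config$duplicate_rate
  dup_src <- base_ids[dup]
  extra <- list(drug = NULL, reac = NULL, ther = NULL, indi = NULL,
                outc = NULL)
  if (length(dup_src) > 0) {
    dup_ids <- as.character(next_id + seq_along(dup_src) - 1L)
    next_id <- next_id + length(dup_src)
    dup_demo <- demo[match(dup_src, primaryid)]
    dup_demo[, primaryid := dup_ids]
    demo <- rbind(demo, dup_demo)
    extra <- clone_children(dup_src, dup_ids)
    led_dup <- ledger[match(dup_src, primaryid)]
    led_dup[, `:=`(primaryid = dup_ids, version = 2L,
                   is_injected_duplicate = TRUE)]
    ledger <- rbind(ledger, led_dup)
  }

  # follow-up versions: i_f_code "F", caseversion 2, new primaryid
  fu <- stats::runif(n) < config$followup_rate
  fu_src <- base_ids[fu]
  if (length(fu_src) > 0) {
    fu_ids <- as.character(next_id + seq_along(fu_src) - 1L)
    fu_demo <- demo[match(fu_src, primaryid)]
    fu_demo[, `:=`(primaryid = fu_ids, caseversion = "2", i_f_code = "F")]
    demo <- rbind(demo, fu_demo)
    fu_children <- clone_children(fu_src, fu_ids)
    for (nm in names(extra)) {
      extra[[nm]] <- rbind(extra[[nm]], fu_children[[nm]])
    }
    led_fu <- ledger[match(fu_src, primaryid)]
    led_fu[, `:=`(primaryid = fu_ids, version = 2L, is_followup = TRUE)]
    ledger <- rbind(ledger, led_fu)
  }

  # blank demographic fields on initial versions only
  blankable <- which(demo$i_f_code == "I")
  mr <- config$missingness
  blank_field <- function(col, rate) {
    hit <- blankable[stats::runif(length(blankable)) < rate]
    if (length(hit) > 0) data.table::set(demo, i = hit, j = col,
                                         value = NA_character_)
  }
  blank_field("event_dt", mr[["event_dt"]])
  blank_field("age", mr[["age"]])
  blank_field("sex", mr[["sex"]])
  blank_field("reporter_country", mr[["reporter_country"]])
  blank_field("wt", mr[["wt"]])
  demo[is.na(age), age_cod := NA_character_]
  demo[is.na(wt), wt_cod := NA_character_]

  drug_tab <- rbind(bundle$drug, extra$drug)
  ps_rows <- which(drug_tab$role_cod == "PS")
  hit <- ps_rows[stats::runif(length(ps_rows)) < mr[["dose_amt"]]]
  if (length(hit) > 0) {
    data.table::set(drug_tab, i = hit, j = "dose_amt",
                    value = NA_character_)
  }

  out <- faers_bundle(
    demo = demo, drug = drug_tab,
    reac = rbind(bundle$reac, extra$reac),
    ther = rbind(bundle$ther, extra$ther),
    indi = rbind(bundle$indi, extra$indi),
    outc = rbind(bundle$outc, extra$outc))
  data.table::setattr(out, "ledger", ledger)
  data.table::setattr(out, "config", config)
  out
}

#' Simulate a complete noisy FAERS bundle
#'
#' Convenience wrapper: [generate_bundle()] followed by
#' [inject_duplicates_and_missingness()].
#'
#' @param config a [synth_config()].
#' @return a `faers_bundle` with `"ledger"` and `"config"` attributes.
#' @export
simulate_faers <- function(config) {
  inject_duplicates_and_missingness(generate_bundle(config), config)
}

#' Truth ledger of a synthetic bundle
#' @param bundle a bundle produced by the synthetic generator.
#' @return the ledger `data.table` (one row per emitted report version).
#' @export
truth_ledger <- function(bundle) {
  led <- attr(bundle, "ledger")
  if (is.null(led)) stop("bundle carries no truth ledger", call. = FALSE)
  led
}

#' Write a synthetic bundle and its truth ledger to disk
#'
#' Emits the quarterly ASCII layout via [write_quarter()] plus a JSON
#' truth-ledger file (`truth_ledger.json`).
#'
#' @param bundle a synthetic `faers_bundle`.
#' @param dir output directory.
#' @param quarter quarter tag for the file names.
#' @return named vector of file paths, invisibly.
#' @export
write_synthetic_quarter <- function(bundle, dir, quarter = "23Q1") {
  paths <- write_quarter(bundle, dir, quarter)
  lpath <- file.path(dir, "truth_ledger.json")
  jsonlite::write_json(truth_ledger(bundle), lpath, dataframe = "rows",
                       na = "null", digits = NA)
  invisible(c(paths, ledger = lpath))
}
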