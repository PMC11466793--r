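# Time-to-onset and cumulative-dose characterization of cases.

#' Time to onset in days
#'
#' Event date minus the earliest therapy start date, in whole days, after
#' midpoint imputation of partial dates. Negative intervals (event before
#' start) are anomalies and become `NA`; the anomaly count is returned as
#' an attribute.
#'
#' @param start_dt character vector of therapy start date strings.
#' @param event_dt character vector of event date strings.
#' @return integer days (`NA` where either date is unparseable or the
#'   interval is negative), with attribute `"n_anomalies"`.
#' @export
time_to_onset <- function(start_dt, event_dt) {
  s <- parse_faers_date(start_dt)
  e <- parse_faers_date(event_dt)
  tto <- as.integer(e - s)
  neg <- !is.na(tto) & tto < 0
  tto[neg] <- NA_integer_
  structure(tto, n_anomalies = sum(neg))
}

#' Per-case onset and cumulative dose records
#'
#' For each report in the study set, computes the time to onset (event
#' date minus the earliest therapy start of the primary-suspect drug),
#' the 4-week (28 d) / 8-week (56 d) flags, and the cumulative dose at
#' onset `daily dose (mg/day) x TTO (days) / weight (kg)`, missing
#' whenever any input is missing.
#'
#' @param bundle a cleaned `faers_bundle`.
#' @param study `data.table(primaryid, drug)` from
#'   [select_study_reports()].
#' @return `data.table(primaryid, drug, tto_days, within_4wk, within_8wk,
#'   cumulative_dose)`.
#' @export
onset_records <- function(bundle, study) {
  ther <- bundle$ther[dsg_drug_seq == "1",
                      .(start_dt = {
                        d <- parse_faers_date(start_dt)
                        if (all(is.na(d))) NA_character_ else
                          start_dt[which.min(d)]
                      }), by = primaryid]
  rec <- data.table::as.data.table(study)
  rec[ther, on = "primaryid", start_date := i.start_dt]
  demo <- bundle$demo[, .(primaryid, event_dt, wt_kg)]
  rec[demo, on = "primaryid", `:=`(event_dt = i.event_dt,
                                   weight_kg = i.wt_kg)]
  dose <- bundle$drug[role_cod == "PS",
                      .(dose_mg = suppressWarnings(
                        as.numeric(dose_amt[1]))), by = primaryid]
  rec[dose, on = "primaryid", dose_mg := i.dose_mg]
  rec[, tto_days := as.integer(time_to_onset(start_date, event_dt))]
  rec[, `:=`(within_4wk = tto_days <= 28, within_8wk = tto_days <= 56)]
  rec[, cumulative_dose := cumulative_dose(dose_mg, tto_days, weight_kg)]
  rec[, .(primaryid, drug, tto_days, within_4wk, within_8wk,
          cumulative_dose)]
}

#' Cumulative dose at onset
#'
#' `dose_amount (mg/day) x tto (days) / weight (kg)`, in mg/kg. Missing
#' whenever any input is missing.
#'
#' @param dose_mg_day daily dose in mg.
#' @param tto_days time to onset in days.
#' @param weight_kg body weight in kg.
#' @return numeric mg/kg.
#' @export
cumulative_dose <- function(dose_mg_day, tto_days, weight_kg) {
  out <- dose_mg_day * tto_days / weight_kg
  out[!is.finite(out)] <- NA_real_
  out
}

#' Summarize onset times per drug group
#'
#' Median and quartiles (linear interpolation on the sorted sample,
#' `stats::quantile` type 7) plus the fractions of cases with onset
#' within 4 weeks (28 d) and 8 weeks (56 d), over records with known
#' onset only. Cumulative-dose medians are computed over records with
#' known dose.
#'
#' @param records output of [onset_records()].
#' @param by grouping column (default `"drug"`); use `NULL` for a single
#'   pooled summary.
#' @return `data.table` with `n_tto, median_days, q1_days, q3_days,
#'   pct_within_4wk, pct_within_8wk, n_dose, median_dose_mg_kg` per
#'   group. Groups with no known onset yield an empty summary row with
#'   `n_tto = 0`.
#' @export
onset_summary <- function(records, by = "drug") {
  records <- data.table::as.data.table(records)
  summ <- function(sd) {
    tto <- sd$tto_days[!is.na(sd$tto_days)]
    dose <- sd$cumulative_dose[!is.na(sd$cumulative_dose)]
    if (length(tto) == 0) {
      q <- c(NA_real_, NA_real_, NA_real_)
      p4 <- NA_real_; p8 <- NA_real_
    } else {
      q <- unname(stats::quantile(tto, c(0.25, 0.5, 0.75), type = 7))
      p4 <- 100 * mean(tto <= 28)
      p8 <- 100 * mean(tto <= 56)
    }
    list(n_tto = length(tto), median_days = q[2], q1_days = q[1],
         q3_days = q[3], pct_within_4wk = p4, pct_within_8wk = p8,
         n_dose = length(dose),
         median_dose_mg_kg = if (length(dose)) stats::median(dose)
         else NA_real_)
  }
  if (is.null(by)) {
    out <- records[, summ(.SD)]
    out[, group := "all"]
    data.table::setcolorder(out, "group")
    out
  } else {
    records[, summ(.SD), by = by]
  }
}
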