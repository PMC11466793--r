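# Cleaning pipeline: single missing-value imputation across case
# versions, two-step de-duplication, and the age/primary-suspect
# selection filters.

.report_sets <- function(bundle) {
  # per-report sorted sets of drug names, outcome codes and reaction PTs,
  # used as de-duplication key components
  paste_set <- function(tab, col) {
    out <- tab[, .(set = paste(sort(unique(.SD[[1]])), collapse = "|")),
               by = primaryid, .SDcols = col]
    out
  }
  ids <- bundle$demo$primaryid
  res <- data.table::data.table(primaryid = ids)
  for (spec in list(c("drug", "drugname", "drugset"),
                    c("outc", "outc_cod", "outcset"),
                    c("reac", "pt_code", "reacset"))) {
    s <- paste_set(bundle[[spec[1]]], spec[2])
    res[, (spec[3]) := s$set[match(primaryid, s$primaryid)]]
    res[is.na(get(spec[3])), (spec[3]) := ""]
  }
  res
}

#' Single missing-value imputation across case versions
#'
#' For each case with more than one version, a version missing exactly one
#' of the four demographic fields (event date, age, sex, reporter country)
#' receives that field's maximum value among versions of the same case
#' that have all four fields populated. Versions missing two or more
#' fields are left untouched ("single" imputation). The maximum is
#' numeric for age (after unit normalization) and lexicographic for the
#' other fields.
#'
#' @param bundle a `faers_bundle`.
#' @return the bundle with imputed DEMO fields; imputation counts per
#'   field are in the `"imputation_counts"` attribute.
#' @export
impute_missing <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  demo <- data.table::copy(bundle$demo)
  fields <- c("event_dt", "age", "sex", "reporter_country")
  miss <- is.na(demo$event_dt) + is.na(demo$age) + is.na(demo$sex) +
    is.na(demo$reporter_country)
  demo[, n_missing := miss]
  donors <- demo[n_missing == 0L,
                 .(max_event_dt = max(event_dt),
                   max_age_yr = max(age_yr),
                   max_sex = max(sex),
                   max_country = max(reporter_country)),
                 by = caseid]
  counts <- stats::setNames(integer(length(fields)), fields)
  demo[donors, on = "caseid", `:=`(
    max_event_dt = i.max_event_dt, max_age_yr = i.max_age_yr,
    max_sex = i.max_sex, max_country = i.max_country)]
  elig <- demo$n_missing == 1L & !is.na(demo$max_sex)

  fill <- elig & is.na(demo$event_dt)
  counts["event_dt"] <- sum(fill)
  demo[fill, event_dt := max_event_dt]

  fill <- elig & is.na(demo$age)
  counts["age"] <- sum(fill)
  demo[fill, `:=`(age = as.character(max_age_yr), age_cod = "YR",
                  age_yr = max_age_yr)]

  fill <- elig & is.na(demo$sex)
  counts["sex"] <- sum(fill)
  demo[fill, sex := max_sex]

  fill <- elig & is.na(demo$reporter_country)
  counts["reporter_country"] <- sum(fill)
  demo[fill, reporter_country := max_country]

  demo[, c("n_missing", "max_event_dt", "max_age_yr", "max_sex",
           "max_country") := NULL]
  out <- bundle
  out$demo <- demo
  data.table::setattr(out, "imputation_counts", counts)
  out
}

#' Two-step case de-duplication
#'
#' Step 1 (version collapse): among rows sharing identical case id,
#' initial/follow-up code, event date, age, sex, reporter country, sorted
#' drug-name set and sorted outcome set, only the most recent case
#' version is retained. Step 2 (cross-case collapse): across the retained
#' set, rows identical on event date, age, sex, reporter country, sorted
#' drug-name set and sorted reaction set collapse to one representative.
#' "Most recent" is operationalized as the largest report id, which FAERS
#' assigns monotonically and which stays well-defined when dates are
#' partial. Missing key fields compare equal to missing.
#'
#' @param bundle a `faers_bundle` (imputation should be applied first).
#' @return `list(bundle, report)` where `report` carries `input_reports`,
#'   `step1_removed`, `step2_removed`, `duplicates_removed` and
#'   `retained`.
#' @export
deduplicate <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  sets <- .report_sets(bundle)
  demo <- bundle$demo[sets, on = "primaryid"]
  demo[, id_num := as.numeric(primaryid)]
  n_in <- nrow(demo)

  key1 <- c("caseid", "i_f_code", "event_dt", "age_yr", "sex",
            "reporter_country", "drugset", "outcset")
  data.table::setorderv(demo, "id_num")
  keep1 <- demo[, .(primaryid = primaryid[.N]), by = key1]$primaryid
  step1_removed <- n_in - length(keep1)

  demo2 <- demo[primaryid %chin% keep1]
  key2 <- c("event_dt", "age_yr", "sex", "reporter_country", "drugset",
            "reacset")
  keep2 <- demo2[, .(primaryid = primaryid[.N]), by = key2]$primaryid
  step2_removed <- length(keep1) - length(keep2)

  out <- subset_bundle(bundle, keep2)
  report <- list(input_reports = n_in,
                 step1_removed = step1_removed,
                 step2_removed = step2_removed,
                 duplicates_removed = step1_removed + step2_removed,
                 retained = length(keep2))
  list(bundle = out, report = report)
}

#' Exclusion filters
#'
#' Removes reports with known age under 18 years; reports with unknown
#' age are retained (the exclusion applies only to known ages).
#'
#' @param bundle a deduplicated `faers_bundle`.
#' @return `list(bundle, report)` with `under18_removed` and `retained`
#'   counts.
#' @export
apply_exclusions <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  n_in <- nrow(bundle$demo)
  keep <- bundle$demo[is.na(age_yr) | age_yr >= 18, primaryid]
  out <- subset_bundle(bundle, keep)
  report <- list(input_reports = n_in,
                 under18_removed = n_in - length(keep),
                 retained = length(keep))
  list(bundle = out, report = report)
}

#' Run the full cleaning pipeline
#'
#' Imputation, two-step de-duplication and the under-18 exclusion, with a
#' consolidated cleaning report satisfying
#' `retained = input_reports - duplicates_removed - under18_removed`.
#'
#' @param bundle a raw `faers_bundle`.
#' @return `list(bundle, report)`; `report` is a `cleaning_report` list
#'   with counts and per-field imputation counts.
#' @export
clean_bundle <- function(bundle) {
  imputed <- impute_missing(bundle)
  dd <- deduplicate(imputed)
  ex <- apply_exclusions(dd$bundle)
  report <- structure(list(
    input_reports = dd$report$input_reports,
    duplicates_removed = dd$report$duplicates_removed,
    step1_removed = dd$report$step1_removed,
    step2_removed = dd$report$step2_removed,
    under18_removed = ex$report$under18_removed,
    retained = ex$report$retained,
    imputation_counts = as.list(attr(imputed, "imputation_counts"))
  ), class = "cleaning_report")
  stopifnot(report$retained ==
              report$input_reports - report$duplicates_removed -
              report$under18_removed)
  list(bundle = ex$bundle, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat(sprintf("  input reports      %d\n", x$input_reports))
  cat(sprintf("  duplicates removed %d (step1 %d, step2 %d)\n",
              x$duplicates_removed, x$step1_removed, x$step2_removed))
  cat(sprintf("  under-18 removed   %d\n", x$under18_removed))
  cat(sprintf("  retained           %d\n", x$retained))
  invisible(x)
}

#' Select the study set: primary-suspect reports for given drugs
#'
#' @param bundle a cleaned `faers_bundle`.
#' @param synonyms named list mapping a canonical drug name to a character
#'   vector of synonyms (generic + brand), matched case-insensitively
#'   after trimming; defaults to the bundled ALK TKI synonym table.
#' @return `data.table(primaryid, drug)` of reports whose primary-suspect
#'   drug matches, with the canonical drug name.
#' @export
select_study_reports <- function(bundle, synonyms = load_drug_synonyms()) {
  ps <- bundle$drug[role_cod == "PS"]
  ps[, drug := match_drug(drugname, synonyms)]
  unique(ps[!is.na(drug), .(primaryid, drug)])
}
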