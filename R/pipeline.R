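# End-to-end study pipeline: ingest -> impute -> dedup -> exclude ->
# flag -> signal -> onset -> risk, with per-stage logging and
# machine-readable report output.

#' Pipeline configuration
#'
#' @param input either a named vector of quarterly file paths (see
#'   [read_quarter()]) or a [synth_config()] for synthetic input.
#' @param smq_file SMQ definition CSV (default: bundled interstitial
#'   lung disease SMQ 20000042).
#' @param synonym_file study-drug synonym CSV (default: bundled ALK TKI
#'   table).
#' @param thresholds [signal_thresholds()].
#' @param out_dir optional output directory for CSV/JSON reports.
#' @param seed integer seed (required for synthetic input).
#' @return a validated `pipeline_config` list. Referenced files are
#'   checked at construction time (fail-fast, before any compute).
#' @export
pipeline_config <- function(input,
                            smq_file = system.file(
                              "extdata", "smq_ild_20000042.csv",
                              package = "faerspv"),
                            synonym_file = system.file(
                              "extdata", "alk_tki_synonyms.csv",
                              package = "faerspv"),
                            thresholds = signal_thresholds(),
                            out_dir = NULL,
                            seed = NULL) {
  if (!file.exists(smq_file)) {
    stop("SMQ file not found: ", smq_file, call. = FALSE)
  }
  if (!file.exists(synonym_file)) {
    stop("synonym file not found: ", synonym_file, call. = FALSE)
  }
  synthetic <- inherits(input, "synth_config")
  if (synthetic) {
    if (!is.null(seed)) input$seed <- as.integer(seed)
  } else {
    missing_files <- unlist(input)[!file.exists(unlist(input))]
    if (length(missing_files) > 0) {
      stop("input file(s) not found: ",
           paste(missing_files, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(input = input, synthetic = synthetic,
                 smq_file = smq_file, synonym_file = synonym_file,
                 thresholds = thresholds, out_dir = out_dir,
                 seed = seed),
            class = "pipeline_config")
}

.stage <- function(report, name, expr, verbose) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Run the full study pipeline
#'
#' Stages run in order: ingest, impute, dedup, exclude, flag, signal,
#' onset, risk. A stage failure stops the run with an error naming the
#' stage. With the same config and seed the report is identical across
#' runs.
#'
#' @param config a [pipeline_config()].
#' @param verbose log per-stage timing messages?
#' @return a `study_report` list: `cleaning` (cleaning report),
#'   `demographics` (per-drug counts and percentages), `signals` (SMQ and
#'   per-PT signal table), `onset` (per-drug and pooled onset/dose
#'   summaries), `risk` (univariate ORs, multivariate fit, nomogram).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  smq <- load_smq(config$smq_file)
  synonyms <- load_drug_synonyms(config$synonym_file)

  raw <- .stage(NULL, "ingest", {
    if (config$synthetic) simulate_faers(config$input)
    else read_quarter(config$input)
  }, verbose)
  cleaned <- .stage(NULL, "clean", clean_bundle(raw), verbose)
  bundle <- cleaned$bundle
  flags <- .stage(NULL, "flag", flag_cases(bundle, smq), verbose)
  study <- select_study_reports(bundle, synonyms)
  demographics <- .stage(NULL, "demographics",
                         summarize_demographics(bundle, flags, study),
                         verbose)
  signals <- .stage(NULL, "signal",
                    detect_signals(bundle, smq, synonyms,
                                   config$thresholds), verbose)
  onset <- .stage(NULL, "onset", {
    recs <- onset_records(bundle, study[flags, on = "primaryid",
                                        nomatch = NULL][is_case == TRUE])
    rbind(onset_summary(recs, by = NULL),
          onset_summary(recs)[, .(group = drug, n_tto, median_days,
                                  q1_days, q3_days, pct_within_4wk,
                                  pct_within_8wk, n_dose,
                                  median_dose_mg_kg)])
  }, verbose)
  risk <- .stage(NULL, "risk", {
    cm <- build_case_control(bundle, smq, synonyms)
    if (nrow(cm) == 0 || sum(cm$ild) < 5) {
      list(matrix = cm, fit = NULL, nomogram = NULL)
    } else {
      # small databases cannot estimate every indicator; drop separated
      # covariates iteratively
      fit <- fit_risk_model(cm)
      if (is.null(fit)) list(matrix = cm, fit = NULL, nomogram = NULL)
      else list(matrix = cm, fit = fit, nomogram = build_nomogram(fit))
    }
  }, verbose)

  report <- structure(list(cleaning = cleaned$report,
                           demographics = demographics,
                           signals = signals, onset = onset, risk = risk),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' Demographic summary of SMQ cases by study drug
#'
#' For the SMQ cases among study reports: per-drug totals with the share
#' of all cases; age-group, sex and report-source counts with per-drug
#' percentages (denominator: the drug's cases); and outcome counts with
#' percentages over the drug's outcome records (a case can carry several
#' outcome records, so the outcome denominator is records, not cases).
#' Every percentage's numerator and denominator are emitted alongside it.
#'
#' @param bundle a cleaned `faers_bundle`.
#' @param flags output of [flag_cases()].
#' @param study output of [select_study_reports()].
#' @return `data.table(drug, section, level, n, denom, pct)`.
#' @export
summarize_demographics <- function(bundle, flags, study) {
  cases <- study[flags, on = "primaryid", nomatch = NULL][is_case == TRUE]
  cases <- cases[!duplicated(primaryid)]
  n_cases <- nrow(cases)
  demo <- bundle$demo[cases, on = "primaryid"]
  demo[, `:=`(
    age_group = data.table::fcase(
      is.na(age_yr), "unknown",
      age_yr < 65, "18-64",
      age_yr < 85, "65-84",
      default = ">=85"),
    sex_group = data.table::fcase(
      is.na(sex), "unknown", sex == "M", "male", sex == "F", "female",
      default = "unknown"),
    source_group = data.table::fcase(
      is.na(occp_cod), "unknown",
      occp_cod == "MD", "physician", occp_cod == "PH", "pharmacist",
      occp_cod == "CN", "consumer", occp_cod == "OT", "other",
      default = "unknown"))]

  rows <- list()
  tot <- demo[, .(n = .N), by = drug]
  rows[[1]] <- tot[, .(drug, section = "total", level = "total", n,
                       denom = n_cases, pct = 100 * n / n_cases)]
  cat_section <- function(col, section) {
    cnt <- demo[, .(n = .N), by = .(drug, level = get(col))]
    cnt[tot, on = "drug", denom := i.n]
    cnt[, .(drug, section = section, level, n, denom,
            pct = 100 * n / denom)]
  }
  rows[[2]] <- cat_section("age_group", "age")
  rows[[3]] <- cat_section("sex_group", "sex")
  rows[[4]] <- cat_section("source_group", "source")

  outc_names <- c(HO = "hospitalization", DS = "disability",
                  LT = "life-threatening", DE = "death", OT = "other")
  outc <- bundle$outc[cases, on = "primaryid", nomatch = NULL]
  if (nrow(outc) > 0) {
    outc[, level := unname(outc_names[outc_cod])]
    ocnt <- outc[, .(n = .N), by = .(drug, level)]
    oden <- outc[, .(denom = .N), by = drug]
    ocnt[oden, on = "drug", denom := i.denom]
    rows[[5]] <- ocnt[, .(drug, section = "outcome", level, n, denom,
                          pct = 100 * n / denom)]
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, section, drug, level)
  out[]
}

#' Write a study report as CSV + JSON files
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    cleaning = file.path(dir, "cleaning_report.json"),
    demographics = file.path(dir, "demographics.csv"),
    signals = file.path(dir, "signal_table.csv"),
    onset = file.path(dir, "onset_summary.csv"))
  jsonlite::write_json(unclass(report$cleaning), paths["cleaning"],
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(report$demographics, paths["demographics"])
  data.table::fwrite(report$signals, paths["signals"])
  data.table::fwrite(report$onset, paths["onset"])
  if (!is.null(report$risk$fit)) {
    paths["risk"] <- file.path(dir, "risk_model.csv")
    data.table::fwrite(report$risk$fit$table, paths["risk"])
    paths["nomogram"] <- file.path(dir, "nomogram.json")
    jsonlite::write_json(
      list(table = report$risk$nomogram$table,
           scale = report$risk$nomogram$scale,
           base_lp = report$risk$nomogram$base_lp,
           intercept = report$risk$nomogram$intercept),
      paths["nomogram"], auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  invisible(paths)
}

#' Reference report counts of the 2011Q1-2023Q2 FAERS ALK TKI ILD study
#'
#' Bundled headline counts of the full-database study dataset (total
#' FAERS reports, duplicate and under-18 exclusions, per-drug report and
#' ILD case counts) plus the demographic count table of the 640 ILD
#' cases. These are inputs for arithmetic cross-checks; the full corpus
#' itself is far beyond desk scale.
#'
#' @return list with `counts` (named numeric vector) and `demographics`
#'   (`data.table` of per-drug counts by section/level).
#' @export
load_reference_counts <- function() {
  counts <- data.table::fread(
    system.file("extdata", "faers_alk_ild_reference_counts.csv",
                package = "faerspv"), showProgress = FALSE)
  demo <- data.table::fread(
    system.file("extdata", "faers_alk_ild_reference_demographics.csv",
                package = "faerspv"), showProgress = FALSE)
  list(counts = stats::setNames(counts$value, counts$name),
       demographics = demo)
}
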