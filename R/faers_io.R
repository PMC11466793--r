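# FAERS quarterly ASCII I/O: "$"-delimited tables with a header row, one
# file per table (DEMOyyQq, DRUGyyQq, ...). All raw fields are kept as
# character columns exactly as read; derived numeric/date columns
# (age_yr, wt_kg) are recomputed from the raw fields so that
# write -> read round-trips are lossless.

.faers_tables <- c("demo", "drug", "reac", "ther", "indi", "outc")

.faers_schema <- list(
  demo = c("primaryid", "caseid", "caseversion", "i_f_code", "event_dt",
           "age", "age_cod", "sex", "wt", "wt_cod", "reporter_country",
           "occp_cod"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "dose_amt",
           "dose_unit"),
  reac = c("primaryid", "pt_code", "pt_name"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt_code", "indi_pt_name"),
  outc = c("primaryid", "outc_cod")
)

#' Construct a FAERS quarter bundle
#'
#' A bundle holds the six linked FAERS tables (DEMO, DRUG, REAC, THER,
#' INDI, OUTC) for one or more quarters as `data.table`s keyed by
#' `primaryid` (the report ID). `caseid` groups versions of the same case.
#'
#' @param demo,drug,reac,ther,indi,outc `data.frame`s with at least the
#'   columns of the corresponding FAERS table (see Details). Missing
#'   optional tables default to empty.
#' @param validate check referential integrity (every child row's
#'   `primaryid` must exist in DEMO)?
#' @return an object of class `faers_bundle`.
#' @details Required columns: DEMO `primaryid, caseid, caseversion,
#'   i_f_code, event_dt, age, age_cod, sex, wt, wt_cod, reporter_country,
#'   occp_cod`; DRUG `primaryid, drug_seq, role_cod, drugname, dose_amt,
#'   dose_unit`; REAC `primaryid, pt_code, pt_name`; THER `primaryid,
#'   dsg_drug_seq, start_dt, end_dt`; INDI `primaryid, indi_drug_seq,
#'   indi_pt_code, indi_pt_name`; OUTC `primaryid, outc_cod`.
#'   Role codes follow FAERS: PS (primary suspect), SS (secondary
#'   suspect), C (concomitant), I (interacting).
#' @export
faers_bundle <- function(demo, drug = NULL, reac = NULL, ther = NULL,
                         indi = NULL, outc = NULL, validate = TRUE) {
  tabs <- list(demo = demo, drug = drug, reac = reac, ther = ther,
               indi = indi, outc = outc)
  for (nm in .faers_tables) {
    tab <- tabs[[nm]]
    cols <- .faers_schema[[nm]]
    if (is.null(tab)) {
      tab <- data.table::as.data.table(
        stats::setNames(rep(list(character()), length(cols)), cols))
    } else {
      tab <- data.table::as.data.table(tab)
      miss <- setdiff(cols, names(tab))
      if (length(miss) > 0) {
        stop(sprintf("table '%s' is missing column(s): %s",
                     nm, paste(miss, collapse = ", ")), call. = FALSE)
      }
      raw <- tab[, cols, with = FALSE]
      for (cc in cols) data.table::set(raw, j = cc,
                                       value = as.character(raw[[cc]]))
      tab <- raw
    }
    tabs[[nm]] <- tab
  }
  tabs$demo[, age_yr := age_to_years(age, age_cod)]
  tabs$demo[, wt_kg := weight_to_kg(wt, wt_cod)]
  out <- structure(tabs, class = "faers_bundle")
  if (validate) validate_bundle(out)
  out
}

#' Check referential integrity of a bundle
#'
#' Every DRUG/REAC/THER/INDI/OUTC row must reference a report present in
#' DEMO.
#'
#' @param bundle a `faers_bundle`.
#' @return the bundle, invisibly; errors on violation.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  ids <- bundle$demo$primaryid
  if (anyDuplicated(ids)) {
    stop("duplicate primaryid in DEMO", call. = FALSE)
  }
  for (nm in setdiff(.faers_tables, "demo")) {
    orphan <- setdiff(bundle[[nm]]$primaryid, ids)
    if (length(orphan) > 0) {
      stop(sprintf("table '%s' references %d report id(s) absent from DEMO",
                   nm, length(orphan)), call. = FALSE)
    }
  }
  invisible(bundle)
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle>\n")
  for (nm in .faers_tables) {
    cat(sprintf("  %-5s %8d rows\n", toupper(nm), nrow(x[[nm]])))
  }
  cat(sprintf("  cases: %d unique case ids\n",
              data.table::uniqueN(x$demo$caseid)))
  invisible(x)
}

#' Number of reports in a bundle
#' @param bundle a `faers_bundle`.
#' @return integer count of DEMO rows (report versions).
#' @export
n_reports <- function(bundle) nrow(bundle$demo)

#' Restrict a bundle to a set of report ids
#'
#' Drops DEMO rows outside `ids` and all child rows referencing them.
#'
#' @param bundle a `faers_bundle`.
#' @param ids character vector of `primaryid`s to keep.
#' @return a filtered `faers_bundle`.
#' @export
subset_bundle <- function(bundle, ids) {
  out <- bundle
  for (nm in .faers_tables) {
    out[[nm]] <- out[[nm]][primaryid %chin% ids]
  }
  structure(out, class = "faers_bundle")
}

#' Read one FAERS quarter from disk
#'
#' Reads the "$"-delimited ASCII layout. Malformed rows (wrong field
#' count) are dropped by the parser and counted in the `n_malformed`
#' attribute rather than raising an error; a missing mandatory column in
#' the header is a format error naming the column. Age and weight are
#' normalized to years and kg at read time (`age_yr`, `wt_kg`), with the
#' original fields preserved.
#'
#' @param paths named character vector or list mapping table names
#'   (`demo`, `drug`, `reac`, `ther`, `indi`, `outc`; case-insensitive)
#'   to file paths. Tables may be omitted (empty table substituted).
#' @return a `faers_bundle`.
#' @export
read_quarter <- function(paths) {
  names(paths) <- tolower(names(paths))
  unknown <- setdiff(names(paths), .faers_tables)
  if (length(unknown) > 0) {
    stop("unknown table name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tabs <- list()
  n_malformed <- 0L
  for (nm in .faers_tables) {
    if (is.null(paths[[nm]])) next
    path <- paths[[nm]]
    if (!file.exists(path)) {
      stop(sprintf("file for table '%s' not found: %s", nm, path),
           call. = FALSE)
    }
    tab <- data.table::fread(path, sep = "$", header = TRUE,
                             colClasses = "character", na.strings = "",
                             fill = TRUE, quote = "", encoding = "UTF-8",
                             showProgress = FALSE)
    miss <- setdiff(.faers_schema[[nm]], names(tab))
    if (length(miss) > 0) {
      stop(sprintf("table '%s' (%s): missing mandatory column(s): %s",
                   nm, path, paste(miss, collapse = ", ")), call. = FALSE)
    }
    # rows lacking a primaryid are malformed (truncated lines)
    bad <- is.na(tab$primaryid) | tab$primaryid == ""
    n_malformed <- n_malformed + sum(bad)
    tabs[[nm]] <- tab[!bad]
  }
  out <- do.call(faers_bundle, c(tabs, list(validate = FALSE)))
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Write a bundle as FAERS quarterly ASCII files
#'
#' Emits the "$"-delimited layout with a header row, one file per table,
#' named `<TABLE><quarter>.txt` (e.g. `DEMO23Q1.txt`). Only the raw FAERS
#' fields are written; derived columns (`age_yr`, `wt_kg`) are dropped so
#' output mirrors input bit-exactly for the modeled fields.
#'
#' @param bundle a `faers_bundle`.
#' @param dir output directory (created if absent).
#' @param quarter quarter tag used in file names, e.g. `"23Q1"`.
#' @return named character vector of the six file paths, invisibly.
#' @export
write_quarter <- function(bundle, dir, quarter = "23Q1") {
  stopifnot(inherits(bundle, "faers_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  paths <- character()
  for (nm in .faers_tables) {
    path <- file.path(dir, sprintf("%s%s.txt", toupper(nm), quarter))
    out <- bundle[[nm]][, .faers_schema[[nm]], with = FALSE]
    data.table::fwrite(out, path, sep = "$", quote = FALSE, na = "",
                       eol = "\n")
    paths[nm] <- path
  }
  invisible(paths)
}
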