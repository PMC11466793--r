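# Standardised MedDRA Query (SMQ) case finding at the preferred-term
# level. The bundled definition covers the interstitial lung disease SMQ
# (20000042) with its core narrow PTs plus configurable broad extras; a
# full licensed MedDRA hierarchy is out of scope.

#' Load an SMQ definition
#'
#' @param path CSV with columns `smq_code, smq_name, pt_code, pt_name,
#'   scope` (scope in `narrow`/`broad`). Defaults to the bundled
#'   interstitial lung disease SMQ 20000042.
#' @param scope restrict to `"narrow"` PTs, or keep both (`"all"`,
#'   default; the analysis does not restrict scope).
#' @return an `smq_definition` list with `smq_code`, `smq_name` and a
#'   `data.table` of PTs.
#' @export
load_smq <- function(path = system.file("extdata", "smq_ild_20000042.csv",
                                        package = "faerspv"),
                     scope = c("all", "narrow")) {
  scope <- match.arg(scope)
  if (!file.exists(path)) stop("SMQ file not found: ", path, call. = FALSE)
  tab <- data.table::fread(path, colClasses = "character",
                           showProgress = FALSE)
  need <- c("smq_code", "smq_name", "pt_code", "pt_name", "scope")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("SMQ file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (scope == "narrow") tab <- tab[tab$scope == "narrow"]
  if (nrow(tab) == 0) stop("SMQ definition has an empty PT list",
                           call. = FALSE)
  if (anyDuplicated(tab$pt_code)) {
    stop("SMQ definition has duplicated PT codes", call. = FALSE)
  }
  if (any(!grepl("^[0-9]{8}$", tab$pt_code))) {
    stop("PT codes must be 8-digit MedDRA identifiers", call. = FALSE)
  }
  structure(list(smq_code = tab$smq_code[1], smq_name = tab$smq_name[1],
                 pts = tab[, .(pt_code, pt_name, scope)]),
            class = "smq_definition")
}

#' @export
print.smq_definition <- function(x, ...) {
  cat(sprintf("<smq_definition> %s (%s): %d PTs\n",
              x$smq_name, x$smq_code, nrow(x$pts)))
  invisible(x)
}

#' Flag SMQ cases at the report level
#'
#' A report is a case iff at least one of its reaction PTs belongs to the
#' SMQ; a report with several matching PTs is still counted once, so each
#' cleaned report contributes at most 1 to a contingency cell.
#'
#' @param bundle a cleaned `faers_bundle`.
#' @param smq an [load_smq()] definition.
#' @return `data.table(primaryid, is_case)` covering every DEMO report.
#' @export
flag_cases <- function(bundle, smq) {
  stopifnot(inherits(bundle, "faers_bundle"),
            inherits(smq, "smq_definition"))
  case_ids <- unique(bundle$reac[pt_code %chin% smq$pts$pt_code, primaryid])
  data.table::data.table(
    primaryid = bundle$demo$primaryid,
    is_case = bundle$demo$primaryid %chin% case_ids)
}
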