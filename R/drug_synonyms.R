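# Drug-name matching. FAERS drug names are free text; mapping to the
# five ALK TKIs uses a bundled synonym table (generic + brand names,
# case-insensitive, trimmed) in place of a full vocabulary
# standardization.

#' Load a drug synonym table
#'
#' @param path CSV with columns `drug` (canonical name) and `synonym`;
#'   defaults to the bundled ALK TKI table (generic and brand names).
#' @return named list: canonical drug -> character vector of synonyms.
#' @export
load_drug_synonyms <- function(path = system.file(
  "extdata", "alk_tki_synonyms.csv", package = "faerspv")) {
  tab <- data.table::fread(path, colClasses = "character",
                           showProgress = FALSE)
  if (!all(c("drug", "synonym") %in% names(tab))) {
    stop("synonym file needs columns 'drug' and 'synonym'", call. = FALSE)
  }
  split(tab$synonym, tab$drug)
}

#' Match free-text drug names against a synonym table
#'
#' Matching is exact after lower-casing and trimming whitespace.
#'
#' @param x character vector of drug-name strings.
#' @param synonyms named list as returned by [load_drug_synonyms()].
#' @return character vector of canonical drug names (`NA` where no
#'   synonym matches).
#' @export
match_drug <- function(x, synonyms = load_drug_synonyms()) {
  lut <- stats::setNames(
    rep(names(synonyms), lengths(synonyms)),
    tolower(trimws(unlist(synonyms, use.names = FALSE))))
  unname(lut[tolower(trimws(x))])
}
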