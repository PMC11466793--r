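#' Parse possibly-partial FAERS dates
#'
#' FAERS date fields are `YYYYMMDD` strings, but partial dates (`YYYYMM`,
#' `YYYY`) are common. For interval arithmetic a partial date is imputed to
#' its midpoint: the 15th of the month for `YYYYMM`, July 1st for `YYYY`.
#' The midpoint minimizes the expected absolute error of the imputation and
#' keeps onset intervals well-defined.
#'
#' @param x character vector of date strings (`""` and `NA` give `NA`).
#' @return a `Date` vector.
#' @seealso [faers_date_precision()] for the completeness flag.
#' @export
#' @examples
#' parse_faers_date(c("20200103", "202006", "2020", ""))
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]{4}([0-9]{2})?([0-9]{2})?$", x) | is.na(x)] <- NA_character_
  n <- nchar(x)
  full <- x
  full[!is.na(n) & n == 6L] <- paste0(x[!is.na(n) & n == 6L], "15")
  full[!is.na(n) & n == 4L] <- paste0(x[!is.na(n) & n == 4L], "0701")
  out <- as.Date(full, format = "%Y%m%d")
  out
}

#' Precision of a FAERS date string
#'
#' @param x character vector of date strings.
#' @return character vector in `{"day","month","year",NA}`.
#' @export
faers_date_precision <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]{4}([0-9]{2})?([0-9]{2})?$", x)] <- NA_character_
  out <- rep(NA_character_, length(x))
  out[nchar(x) == 8L] <- "day"
  out[nchar(x) == 6L] <- "month"
  out[nchar(x) == 4L] <- "year"
  out
}

# FAERS age unit codes -> years. DEC = decades, MON = months, WK = weeks,
# DY = days; unknown codes are treated as years (the FAERS default).
.age_unit_factor <- c(
  YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18, DY = 1 / 365.25, HR = 1 / 8766
)

#' Convert FAERS age values to years
#'
#' @param age numeric or character vector of age values.
#' @param unit character vector of FAERS age unit codes
#'   (`YR`, `DEC`, `MON`, `WK`, `DY`; missing treated as years).
#' @return numeric vector of ages in years (`NA` where age is missing).
#' @export
#' @examples
#' age_to_years(700, "MON") # 58.33
age_to_years <- function(age, unit) {
  age <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(as.character(unit)))
  f <- .age_unit_factor[unit]
  f[is.na(f)] <- 1
  out <- age * as.numeric(f)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Convert FAERS weight values to kilograms
#'
#' Weights outside (0, 500) kg after conversion are implausible for adult
#' humans and set to `NA`.
#'
#' @param wt numeric or character weight values.
#' @param unit character unit codes (`KG` or `LBS`; missing treated as kg).
#' @return numeric vector of weights in kg.
#' @export
weight_to_kg <- function(wt, unit) {
  wt <- suppressWarnings(as.numeric(wt))
  unit <- toupper(trimws(as.character(unit)))
  f <- ifelse(unit %in% "LBS", 0.4536, 1)
  out <- wt * f
  out[!is.na(out) & (out <= 0 | out >= 500)] <- NA_real_
  out
}
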