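# Disproportionality statistics over drug-event 2x2 contingency tables.
#
# For one drug-event pair against the rest of the database:
#             event     no event
#   drug        a           b
#   no drug     c           d
#
# ROR  = ad/bc with a log-scale Wald 95% CI (van Puijenbroek).
# PRR  = [a/(a+b)] / [c/(c+d)] with a Pearson chi-square (Evans).
# IC   = log2[(a+0.5)/(E+0.5)], E = (a+b)(a+c)/N, with the BCPNN-style
#        lower credibility bound IC025 (Noren).
# EBGM = posterior geometric mean of the observed/expected ratio under a
#        two-component gamma mixture prior (DuMouchel's MGPS; see mgps.R).

#' Build a 2x2 contingency table for one drug-event pair
#'
#' Cells partition the cleaned report universe at the report level: each
#' report contributes to exactly one cell.
#'
#' @param case_ids report ids with the event.
#' @param drug_ids report ids with the drug (primary suspect).
#' @param all_ids the full cleaned report universe.
#' @return a `contingency_table` list with integer `a`, `b`, `c`, `d`.
#' @export
build_table <- function(case_ids, drug_ids, all_ids) {
  if (length(all_ids) == 0) stop("empty report universe", call. = FALSE)
  if (anyDuplicated(all_ids)) stop("duplicated report ids in universe",
                                   call. = FALSE)
  in_drug <- all_ids %chin% drug_ids
  in_case <- all_ids %chin% case_ids
  structure(list(a = sum(in_drug & in_case),
                 b = sum(in_drug & !in_case),
                 c = sum(!in_drug & in_case),
                 d = sum(!in_drug & !in_case)),
            class = "contingency_table")
}

.tab_cells <- function(table) {
  if (inherits(table, "contingency_table") || is.list(table)) {
    unlist(table[c("a", "b", "c", "d")])
  } else {
    stats::setNames(as.numeric(table)[1:4], c("a", "b", "c", "d"))
  }
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad/bc`; `CI = exp(log ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' With a zero cell the estimate is undefined; if `correction` is enabled
#' (default) 0.5 is added to every cell of such tables, otherwise `NA` is
#' returned (an undefined-result marker, not an error).
#'
#' @param table a `contingency_table` (or vector `c(a,b,c,d)`).
#' @param correction apply the 0.5 continuity correction to zero-cell
#'   tables?
#' @return list with `ror`, `lo`, `hi`.
#' @export
ror <- function(table, correction = TRUE) {
  x <- .tab_cells(table)
  if (any(x == 0)) {
    if (!correction) return(list(ror = NA_real_, lo = NA_real_,
                                 hi = NA_real_))
    x <- x + 0.5
  }
  est <- (x["a"] * x["d"]) / (x["b"] * x["c"])
  se <- sqrt(sum(1 / x))
  ci <- exp(log(est) + c(-1, 1) * 1.96 * se)
  list(ror = unname(est), lo = ci[1], hi = ci[2])
}

#' Proportional reporting ratio with Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-square is the Pearson statistic
#' `N (ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`, without continuity correction
#' by default (`yates = TRUE` subtracts N/2 from |ad-bc| for sensitivity
#' analyses). A zero margin (or c = 0) yields `NA` markers.
#'
#' @param table a `contingency_table` (or vector `c(a,b,c,d)`).
#' @param yates apply the Yates continuity correction to the chi-square?
#' @return list with `prr`, `chisq`.
#' @export
prr <- function(table, yates = FALSE) {
  x <- .tab_cells(table)
  n <- sum(x)
  ab <- x["a"] + x["b"]; cd <- x["c"] + x["d"]
  ac <- x["a"] + x["c"]; bd <- x["b"] + x["d"]
  if (ab == 0 || cd == 0 || x["c"] == 0) {
    return(list(prr = NA_real_, chisq = NA_real_))
  }
  est <- (x["a"] / ab) / (x["c"] / cd)
  dev <- abs(x["a"] * x["d"] - x["b"] * x["c"])
  if (yates) dev <- max(0, dev - n / 2)
  chisq <- if (ac == 0 || bd == 0) NA_real_ else
    n * dev^2 / (ab * cd * ac * bd)
  list(prr = unname(est), chisq = unname(chisq))
}

#' Information component with lower credibility bound
#'
#' Shrunk log2 observed-over-expected ratio:
#' `IC = log2[(a+0.5)/(E+0.5)]` with `E = (a+b)(a+c)/N`, and
#' `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)`. The +0.5
#' shrinkage makes the statistic defined for every table with N > 0.
#'
#' @param table a `contingency_table` (or vector `c(a,b,c,d)`).
#' @return list with `ic`, `ic025`, and the expected count `E`.
#' @export
information_component <- function(table) {
  x <- .tab_cells(table)
  n <- sum(x)
  if (n == 0) stop("empty table", call. = FALSE)
  e <- (x["a"] + x["b"]) * (x["a"] + x["c"]) / n
  ic <- log2((x["a"] + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (x["a"] + 0.5)^(-0.5) - 2 * (x["a"] + 0.5)^(-1.5)
  list(ic = unname(ic), ic025 = unname(ic025), E = unname(e))
}

#' Default signal-declaration thresholds
#'
#' Standard pharmacovigilance criteria: minimum observed count `a >= 3`;
#' ROR lower 95% bound > 1; PRR >= 2 with chi-square >= 4; IC025 > 0;
#' EB05 > 2. The joint criterion requires all of them.
#'
#' @param min_a,ror_lo,prr_min,chisq_min,ic025_min,eb05_min numeric
#'   thresholds.
#' @return named list of thresholds.
#' @export
signal_thresholds <- function(min_a = 3, ror_lo = 1, prr_min = 2,
                              chisq_min = 4, ic025_min = 0, eb05_min = 2) {
  list(min_a = min_a, ror_lo = ror_lo, prr_min = prr_min,
       chisq_min = chisq_min, ic025_min = ic025_min, eb05_min = eb05_min)
}

# all four statistics + flags for a vector of (a, b, c, d) cells;
# internal vectorized workhorse behind detect_signals()
.signal_stats <- function(tab, prior, thresholds) {
  res <- tab
  n <- res$a + res$b + res$c + res$d
  res[, E := (a + b) * (a + c) / n]
  rors <- lapply(seq_len(nrow(res)), function(i)
    ror(c(res$a[i], res$b[i], res$c[i], res$d[i])))
  prrs <- lapply(seq_len(nrow(res)), function(i)
    prr(c(res$a[i], res$b[i], res$c[i], res$d[i])))
  ics <- lapply(seq_len(nrow(res)), function(i)
    information_component(c(res$a[i], res$b[i], res$c[i], res$d[i])))
  res[, `:=`(ror = vapply(rors, `[[`, 0, "ror"),
             ror_lo = vapply(rors, `[[`, 0, "lo"),
             ror_hi = vapply(rors, `[[`, 0, "hi"),
             prr = vapply(prrs, `[[`, 0, "prr"),
             chisq = vapply(prrs, `[[`, 0, "chisq"),
             ic = vapply(ics, `[[`, 0, "ic"),
             ic025 = vapply(ics, `[[`, 0, "ic025"))]
  eb <- ebgm(res$a, res$E, prior)
  res[, `:=`(ebgm = eb$ebgm, eb05 = eb$eb05, eb95 = eb$eb95)]
  th <- thresholds
  res[, `:=`(
    flag_ror = !is.na(ror_lo) & ror_lo > th$ror_lo,
    flag_prr = !is.na(prr) & prr >= th$prr_min & !is.na(chisq) &
      chisq >= th$chisq_min,
    flag_ic = ic025 > th$ic025_min,
    flag_ebgm = eb05 > th$eb05_min)]
  res[, flag_joint := a >= th$min_a & flag_ror & flag_prr & flag_ic &
        flag_ebgm]
  res
}

#' Detect disproportionality signals for study drugs
#'
#' Builds report-level 2x2 tables against the cleaned report universe and
#' computes all four algorithms (ROR, PRR + chi-square, IC + IC025,
#' EBGM + EB05/EB95) with per-algorithm and joint signal flags, at the
#' SMQ level per drug (plus the pooled drug group) and per (drug, PT)
#' pair. The MGPS prior is fitted once on all (primary-suspect drug, PT)
#' pairs of the database.
#'
#' @param bundle a cleaned `faers_bundle`.
#' @param smq an [load_smq()] definition for the SMQ-level analysis.
#' @param synonyms named synonym list defining the study drugs
#'   (default: the five ALK TKIs). The pooled row is named
#'   `"ALK TKIs"` when the default synonyms are used, else `"pooled"`.
#' @param thresholds [signal_thresholds()].
#' @param level `"smq"`, `"pt"`, or `"both"`.
#' @param prior optionally a pre-fitted [fit_mgps()] prior; fitted from
#'   the bundle when `NULL`.
#' @return a `data.table`, one row per drug-event pair, with cells,
#'   estimates, interval bounds and flags.
#' @export
detect_signals <- function(bundle, smq = load_smq(),
                           synonyms = load_drug_synonyms(),
                           thresholds = signal_thresholds(),
                           level = c("both", "smq", "pt"),
                           prior = NULL) {
  level <- match.arg(level)
  all_ids <- bundle$demo$primaryid
  universe_n <- length(all_ids)
  if (universe_n == 0) stop("empty report universe", call. = FALSE)

  ps <- unique(bundle$drug[role_cod == "PS", .(primaryid, drugname)])
  study <- select_study_reports(bundle, synonyms)
  pooled_name <- if (identical(sort(names(synonyms)), sort(alk_drugs())))
    "ALK TKIs" else "pooled"

  if (is.null(prior)) prior <- fit_mgps(pair_counts(bundle))

  # report counts per drug group: named list drug -> ids
  drug_ids <- split(study$primaryid, study$drug)
  drug_ids[[pooled_name]] <- unique(study$primaryid)

  rows <- list()
  if (level %in% c("both", "smq")) {
    flags <- flag_cases(bundle, smq)
    case_ids <- flags[is_case == TRUE, primaryid]
    for (dg in names(drug_ids)) {
      tb <- build_table(case_ids, drug_ids[[dg]], all_ids)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        drug = dg, event = smq$smq_name, event_type = "smq",
        a = tb$a, b = tb$b, c = tb$c, d = tb$d)
    }
  }
  if (level %in% c("both", "pt")) {
    reac <- unique(bundle$reac[, .(primaryid, pt_code, pt_name)])
    pts <- unique(reac[, .(pt_code, pt_name)])
    n_drug_tab <- vapply(drug_ids, length, 0L)
    for (dg in names(drug_ids)) {
      ids_d <- drug_ids[[dg]]
      sub <- reac[primaryid %chin% ids_d, .(a = .N), by = .(pt_code)]
      all_pt <- reac[, .(n_event = .N), by = .(pt_code)]
      tabs <- all_pt[pts, on = "pt_code"]
      tabs[sub, on = "pt_code", a := i.a]
      tabs[is.na(a), a := 0L]
      tabs[, `:=`(drug = dg, event = pt_name, event_type = "pt",
                  b = n_drug_tab[[dg]] - a, c = n_event - a,
                  d = universe_n - n_drug_tab[[dg]] - (n_event - a))]
      rows[[length(rows) + 1L]] <-
        tabs[, .(drug, event, event_type, a, b, c, d)]
    }
  }
  tab <- data.table::rbindlist(rows)
  .signal_stats(tab, prior, thresholds)
}

#' Observed and expected counts for every drug-event pair
#'
#' Report-level `(a, E)` pairs for all (primary-suspect drug, reaction
#' PT) combinations observed in the bundle, with expected counts from the
#' report-level margins `E = n_drug * n_event / N`. This is the input to
#' [fit_mgps()].
#'
#' @param bundle a cleaned `faers_bundle`.
#' @return `data.table(drug, pt_code, a, E, n_drug, n_event, N)`.
#' @export
pair_counts <- function(bundle) {
  n <- nrow(bundle$demo)
  ps <- unique(bundle$drug[role_cod == "PS", .(primaryid, drugname)])
  reac <- unique(bundle$reac[, .(primaryid, pt_code)])
  n_drug_tab <- ps[, .(n_drug = .N), by = drugname]
  n_event_tab <- reac[, .(n_event = .N), by = pt_code]
  pairs <- merge(ps, reac, by = "primaryid",
                 allow.cartesian = TRUE)[, .(a = .N),
                                         by = .(drugname, pt_code)]
  grid <- data.table::CJ(drugname = n_drug_tab$drugname,
                         pt_code = n_event_tab$pt_code)
  grid <- merge(grid, pairs, by = c("drugname", "pt_code"), all.x = TRUE)
  grid[is.na(a), a := 0L]
  grid <- merge(grid, n_drug_tab, by = "drugname")
  grid <- merge(grid, n_event_tab, by = "pt_code")
  grid[, `:=`(E = n_drug * n_event / n, N = n)]
  data.table::setnames(grid, "drugname", "drug")
  grid[, .(drug, pt_code, a, E, n_drug, n_event, N)]
}
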