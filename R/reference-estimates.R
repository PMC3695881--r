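#' Reference ERG model estimates for 20 hospital networks
#'
#' Parameter estimates, standard errors and the printed estimate/stderr
#' ratios of a high-order ERG model (2-star, 3-star, alternating k-star,
#' alternating k-triangle, alternating independent two-path) fitted to 20
#' physician collaboration networks stratified by outcome extremes -- the
#' 5 lowest- and highest-cost and the 5 lowest- and highest-readmission
#' hospitals -- transcribed from the published literature on physician
#' collaboration.  The underlying claims data are private, so these
#' published estimates serve as fixed inputs for the group-comparison
#' analyses, not as values this package re-derives.
#'
#' All numbers are printed at two decimal places.  In some rows the
#' printed ratio column is internally inconsistent with its own estimate
#' and standard error (a transcription defect of the source table), which
#' is why [resolve_tvalues()] exists.
#'
#' @return A tibble with columns `group` (`low_cost`, `high_cost`,
#'   `low_readmission`, `high_readmission`), `network` (1-5), `term`,
#'   `estimate`, `stderr`, `ratio_printed`.
#' @export
reference_ergm_estimates <- function() {
  path <- system.file("extdata", "reference_ergm_estimates.csv",
                      package = "pcnet", mustWork = TRUE)
  readr::read_csv(path, col_types = "cicddd", progress = FALSE)
}

#' Reconcile printed t-values with printed estimates
#'
#' Published regression-style tables print `estimate`, `stderr` and their
#' ratio, all rounded.  The printed ratio normally carries more precision
#' about the underlying t-value than re-dividing the rounded inputs, so
#' it is preferred -- but only when it is *consistent* with the rounded
#' estimate and standard error, i.e. lies inside the interval of ratios
#' attainable by any unrounded pair that rounds to the printed ones.
#' Inconsistent ratios (corrupted columns) are recomputed as
#' `estimate / stderr`; if that is impossible because the printed
#' standard error is zero, the t-value is flagged undefined (`NA`) rather
#' than divided.
#'
#' @param table Data frame with columns `estimate`, `stderr`,
#'   `ratio_printed` (e.g. from [reference_ergm_estimates()]).
#' @param precision Printing granularity of all three columns
#'   (default 0.01, i.e. two decimals).
#' @return The input with columns `t_value` and `t_source` (one of
#'   `"ratio"`, `"recomputed"`, `"undefined"`) appended.
#' @export
resolve_tvalues <- function(table, precision = 0.01) {
  h <- precision / 2
  resolve_one <- function(est, se, ratio) {
    a <- c(est - h, est + h)
    s <- c(max(se - h, 0), se + h)
    cand <- as.vector(outer(a, s, "/"))
    cand <- cand[!is.nan(cand)]
    if (!length(cand)) cand <- c(-Inf, Inf)
    consistent <- ratio >= min(cand) - h & ratio <= max(cand) + h
    if (consistent) {
      list(t = ratio, source = "ratio")
    } else if (se > 0) {
      list(t = est / se, source = "recomputed")
    } else {
      list(t = NA_real_, source = "undefined")
    }
  }
  res <- Map(resolve_one, table$estimate, table$stderr, table$ratio_printed)
  table$t_value <- vapply(res, `[[`, numeric(1), "t")
  table$t_source <- vapply(res, `[[`, character(1), "source")
  table
}
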