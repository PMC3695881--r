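#' Join network summaries with hospital outcomes
#'
#' @param summaries Tibble from [summarise_pcns()].
#' @param outcomes Tibble from [compute_all_outcomes()].
#' @return One row per hospital with both sets of columns; hospitals
#'   missing from either side are dropped with a warning.
#' @export
analysis_table <- function(summaries, outcomes) {
  out <- dplyr::inner_join(summaries, outcomes, by = "hospital_id")
  lost <- setdiff(union(summaries$hospital_id, outcomes$hospital_id),
                  out$hospital_id)
  if (length(lost)) {
    warning(length(lost), " hospital(s) missing from one side of the join",
            call. = FALSE)
  }
  out
}

#' Correlate a network index with an outcome
#'
#' Rank (Spearman) correlation by default, reported with a two-tailed
#' p-value; the product-moment (Pearson) coefficient is available as an
#' alternative.  Rank correlation is invariant under monotone transforms
#' of either variable, which suits indices and cost scales with skewed
#' distributions.
#'
#' @param table An [analysis_table()] (any data frame).
#' @param x,y Column names.
#' @param method `"rank"` or `"product_moment"`.
#' @return One-row tibble: `variable_x`, `variable_y`, `rho`, `p_value`,
#'   `n`, `method`.
#' @export
correlate <- function(table, x, y, method = c("rank", "product_moment")) {
  method <- match.arg(method)
  xv <- table[[x]]
  yv <- table[[y]]
  if (is.null(xv) || is.null(yv)) {
    stop("column not found: ", if (is.null(xv)) x else y, call. = FALSE)
  }
  if (length(xv) < 3) stop("need at least 3 observations", call. = FALSE)
  for (nm in c(x, y)) {
    if (stats::sd(table[[nm]]) == 0) {
      stop("correlation undefined: column '", nm, "' has zero variance",
           call. = FALSE)
    }
  }
  ct <- suppressWarnings(cor.test(
    xv, yv,
    method = if (method == "rank") "spearman" else "pearson",
    alternative = "two.sided", exact = FALSE
  ))
  tibble::tibble(
    variable_x = x, variable_y = y,
    rho = unname(ct$estimate), p_value = ct$p.value,
    n = length(xv), method = method
  )
}

#' Pairwise correlation table
#'
#' All pairwise correlations among the given columns, in long form.
#'
#' @inheritParams correlate
#' @param columns Character vector of column names.
#' @return Tibble of [correlate()] rows, one per unordered pair.
#' @export
correlate_pairs <- function(table, columns,
                            method = c("rank", "product_moment")) {
  method <- match.arg(method)
  pairs <- utils::combn(columns, 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(p) {
    correlate(table, p[1], p[2], method = method)
  }))
}

regression_result <- function(model, dependent, term_names) {
  cf <- summary(model)$coefficients
  terms <- tibble::tibble(
    term = term_names,
    beta = unname(cf[term_names, "Estimate"]),
    p_value = unname(cf[term_names, "Pr(>|t|)"])
  )
  structure(list(
    dependent = dependent,
    intercept = unname(cf["(Intercept)", "Estimate"]),
    r_squared = summary(model)$r.squared,
    terms = terms,
    model = model
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("OLS:", x$dependent, "~",
      paste(x$terms$term, collapse = " + "), "\n")
  cat(sprintf("  intercept %.4g, R-squared %.3f\n", x$intercept,
              x$r_squared))
  print(as.data.frame(x$terms))
  invisible(x)
}

#' Simple linear regression of an outcome on a network index
#'
#' Ordinary least squares with a single predictor; slope, intercept,
#' R-squared and the slope's p-value.
#'
#' @param table Data frame with one row per hospital.
#' @param dependent,independent Column names.
#' @return A `regression_result`.
#' @export
fit_simple <- function(table, dependent, independent) {
  if (nrow(table) <= 2) stop("need more than 2 observations", call. = FALSE)
  if (stats::sd(table[[independent]]) == 0) {
    stop("singular fit: '", independent, "' is constant", call. = FALSE)
  }
  f <- stats::reformulate(independent, response = dependent)
  regression_result(lm(f, data = table), dependent, independent)
}

#' Age-moderation regression
#'
#' Tests whether mean patient age moderates the association between a
#' network index and an outcome: OLS of the outcome on the index and the
#' index-by-moderator product.  A significant product term indicates
#' moderation.  The moderator's main effect is excluded by default,
#' mirroring the two-term moderation design this package reproduces; set
#' `include_moderator_main = TRUE` for the conventional three-term model.
#'
#' @param table Data frame with one row per hospital.
#' @param dependent,independent,moderator Column names.
#' @param include_moderator_main Also include the moderator's main effect.
#' @return A `regression_result`; the interaction term is named
#'   `"<independent>:<moderator>"`.
#' @export
fit_moderation <- function(table, dependent, independent, moderator,
                           include_moderator_main = FALSE) {
  if (nrow(table) <= 3) stop("need more than 3 observations", call. = FALSE)
  rhs <- c(independent, if (include_moderator_main) moderator,
           paste0(independent, ":", moderator))
  f <- stats::reformulate(rhs, response = dependent)
  m <- lm(f, data = table)
  regression_result(m, dependent, setdiff(rownames(summary(m)$coefficients),
                                          "(Intercept)"))
}

#' Extreme outcome groups
#'
#' Deterministically selects the `k` hospitals with the smallest and the
#' `k` with the largest value of an outcome column (ties broken by
#' `hospital_id` order), e.g. the 5 least and 5 most expensive networks.
#'
#' @param table Data frame with a `hospital_id` column.
#' @param outcome Column to order by.
#' @param k Group size; must not exceed half the rows.
#' @return A list with tibbles `low` and `high` (each `k` rows).
#' @export
select_extremes <- function(table, outcome, k) {
  n <- nrow(table)
  if (k > n / 2) stop("k must not exceed half the hospitals", call. = FALSE)
  v <- table[[outcome]]
  ord <- order(v, table$hospital_id)
  low <- table[ord[seq_len(k)], ]
  high <- table[rev(ord)[seq_len(k)], ]
  high <- high[order(high[[outcome]], high$hospital_id), ]
  boundary_low <- v[ord[k]]
  boundary_high <- v[ord[n - k + 1]]
  if (sum(v == boundary_low) > 1 && any(v[ord[-seq_len(k)]] == boundary_low)) {
    warning("ties at the low-group boundary broken by hospital_id",
            call. = FALSE)
  }
  if (sum(v == boundary_high) > 1 &&
      any(v[ord[seq_len(n - k)]] == boundary_high)) {
    warning("ties at the high-group boundary broken by hospital_id",
            call. = FALSE)
  }
  list(low = tibble::as_tibble(low), high = tibble::as_tibble(high))
}

#' Compare a parameter's t-values between outcome groups
#'
#' Pooled-variance two-sample t-test between the low and high outcome
#' groups of the t-values of one ERG model parameter.  The statistic is
#' oriented as high minus low; the one-tailed p-value refers to the
#' observed direction.  With equal group sizes the statistic reduces to
#' the mean difference divided by `sqrt(SE_low^2 + SE_high^2)`.
#'
#' Non-finite t-values (e.g. flagged-undefined ones from a zero standard
#' error) are excluded with a warning before testing.
#'
#' @param low,high Numeric vectors of per-network parameter t-values.
#' @param parameter Optional parameter name carried into the result.
#' @return One-row tibble: `parameter`, `mean_low`, `se_low`, `n_low`,
#'   `mean_high`, `se_high`, `n_high`, `t_statistic`, `df`, `p_one_tail`.
#' @export
tvalue_group_test <- function(low, high, parameter = NA_character_) {
  drop_bad <- function(v, label) {
    bad <- !is.finite(v)
    if (any(bad)) {
      warning(sum(bad), " non-finite t-value(s) excluded from the ",
              label, " group", call. = FALSE)
    }
    v[!bad]
  }
  low <- drop_bad(low, "low")
  high <- drop_bad(high, "high")
  n1 <- length(low); n2 <- length(high)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs at least 2 finite t-values", call. = FALSE)
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(low) + (n2 - 1) * var(high)) / df
  if (sp2 == 0) stop("degenerate test: zero pooled variance", call. = FALSE)
  t_stat <- (mean(high) - mean(low)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(
    parameter = parameter,
    mean_low = mean(low), se_low = sd(low) / sqrt(n1), n_low = n1,
    mean_high = mean(high), se_high = sd(high) / sqrt(n2), n_high = n2,
    t_statistic = t_stat, df = df,
    p_one_tail = pt(abs(t_stat), df, lower.tail = FALSE)
  )
}
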