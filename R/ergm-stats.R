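ERGM_TERMS <- c("edge", "two_star", "three_star", "triangle",
                "alt_k_star", "alt_k_triangle", "alt_k_two_path")
MARKOV_TERMS <- ERGM_TERMS[1:4]
ALTERNATING_TERMS <- ERGM_TERMS[5:7]

term_codes <- function(terms) match(terms, ERGM_TERMS)

#' Specify an exponential random graph model
#'
#' An ERG model assigns a graph `x` probability proportional to
#' `exp(sum_A eta_A g_A(x))`, where each `g_A` counts (or geometrically
#' aggregates) a local configuration.  Markov terms are raw counts:
#' `edge`, `two_star`, `three_star` (k-stars counted hierarchically as
#' `sum_i choose(d_i, k)`, so a triangle also contains three 2-stars) and
#' `triangle`.  The alternating terms down-weight higher-order
#' configurations geometrically with constant `lambda`, which curbs the
#' degeneracy of pure star/triangle models: `alt_k_star` (alternating
#' k-stars), `alt_k_triangle` (alternating k-triangles) and
#' `alt_k_two_path` (alternating independent two-paths).
#'
#' @param terms Character vector of distinct term names from
#'   `edge`, `two_star`, `three_star`, `triangle`, `alt_k_star`,
#'   `alt_k_triangle`, `alt_k_two_path`.
#' @param lambda Weighting constant of the alternating statistics
#'   (must exceed 1; default 2, the conventional choice).
#' @return An `ergm_spec` object.
#' @export
ergm_spec <- function(terms, lambda = 2) {
  terms <- as.character(terms)
  if (!length(terms)) stop("at least one term is required", call. = FALSE)
  bad <- setdiff(terms, ERGM_TERMS)
  if (length(bad)) {
    stop("unknown ERGM term(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(ERGM_TERMS, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(terms)) stop("duplicate terms", call. = FALSE)
  if (!is.numeric(lambda) || lambda <= 1) {
    stop("lambda must be > 1", call. = FALSE)
  }
  structure(list(terms = terms, lambda = as.numeric(lambda)),
            class = "ergm_spec")
}

#' @export
print.ergm_spec <- function(x, ...) {
  cat("ERGM specification:", paste(x$terms, collapse = " + "),
      sprintf("(lambda = %g)\n", x$lambda))
  invisible(x)
}

#' Count a Markov configuration
#'
#' @param graph A [binary_graph()].
#' @param term One of `edge`, `two_star`, `three_star`, `triangle`.
#' @return The configuration count (non-negative integer).
#' @export
count_statistic <- function(graph, term) {
  term <- match.arg(term, MARKOV_TERMS)
  adj <- graph$adjacency
  d <- rowSums(adj)
  switch(term,
    edge = sum(d) / 2,
    two_star = sum(choose(d, 2)),
    three_star = sum(choose(d, 3)),
    triangle = sum(diag(adj %*% adj %*% adj)) / 6
  )
}

#' Evaluate an alternating (geometrically weighted) statistic
#'
#' The alternating statistics replace an unbounded family of counts by a
#' single geometrically down-weighted alternating sum with constant
#' `lambda > 1`.  Writing `q = 1 - 1/lambda` and `d_i` for degrees,
#' `sp_uv` for the number of common neighbours of a pair:
#' \itemize{
#'   \item `alt_k_star` `= sum_{k>=2} (-1)^k S_k / lambda^{k-2}
#'     = lambda^2 sum_i (q^{d_i} - 1 + d_i / lambda)`
#'   \item `alt_k_triangle` `= lambda sum_{ties (u,v)} (1 - q^{sp_uv})`
#'   \item `alt_k_two_path` `= lambda sum_{pairs (u,v)} (1 - q^{sp_uv})`
#' }
#' With maximum degree 2 the alternating k-star sum truncates and equals
#' the plain 2-star count.
#'
#' @param graph A [binary_graph()].
#' @param term One of `alt_k_star`, `alt_k_triangle`, `alt_k_two_path`.
#' @param lambda Weighting constant, `> 1`.
#' @return A finite real number.
#' @export
alternating_statistic <- function(graph, term, lambda = 2) {
  term <- match.arg(term, ALTERNATING_TERMS)
  if (!is.numeric(lambda) || lambda <= 1) {
    stop("lambda must be > 1", call. = FALSE)
  }
  adj <- graph$adjacency
  q <- 1 - 1 / lambda
  if (term == "alt_k_star") {
    d <- rowSums(adj)
    return(lambda^2 * sum(q^d - 1 + d / lambda))
  }
  sp <- adj %*% adj  # shared-partner (two-path) counts per pair
  upper <- upper.tri(sp)
  if (term == "alt_k_triangle") {
    sum(lambda * (1 - q^sp[upper & adj == 1L]))
  } else {
    sum(lambda * (1 - q^sp[upper]))
  }
}

#' All sufficient statistics of a model
#'
#' @param graph A [binary_graph()].
#' @param spec An [ergm_spec()].
#' @return Named numeric vector of `g_A(x)`, one entry per term.
#' @export
ergm_statistics <- function(graph, spec) {
  vapply(spec$terms, function(term) {
    if (term %in% MARKOV_TERMS) count_statistic(graph, term)
    else alternating_statistic(graph, term, spec$lambda)
  }, numeric(1))
}

#' Change statistics of one dyad
#'
#' For each model term, the difference `g_A(x + ij) - g_A(x - ij)` between
#' the graph with and without the tie on dyad `(i, j)`, computed locally
#' from the dyad's neighbourhood rather than by a full recount.  Change
#' statistics are what the Metropolis sampler and the estimation routines
#' use, because ratios of the model probabilities do not involve the
#' normalising constant.
#'
#' @param graph A [binary_graph()]; the current state of the dyad does not
#'   affect the result.
#' @param dyad Length-2 vector of distinct node indices or names.
#' @param spec An [ergm_spec()].
#' @return Named numeric vector of per-term changes.
#' @export
change_statistics <- function(graph, dyad, spec) {
  nodes <- rownames(graph$adjacency)
  if (is.character(dyad)) dyad <- match(dyad, nodes)
  dyad <- as.integer(dyad)
  if (length(dyad) != 2 || anyNA(dyad)) {
    stop("dyad must name two nodes of the graph", call. = FALSE)
  }
  if (dyad[1] == dyad[2]) {
    stop("dyad must consist of two distinct nodes", call. = FALSE)
  }
  adj <- graph$adjacency
  adj[dyad[1], dyad[2]] <- 0L
  adj[dyad[2], dyad[1]] <- 0L
  delta <- cpp_change_stats(adj, dyad[1] - 1L, dyad[2] - 1L,
                            term_codes(spec$terms), spec$lambda)
  stats::setNames(delta, spec$terms)
}

#' Unnormalised log-probability of a graph
#'
#' Returns `sum_A eta_A g_A(x)`, the linear predictor of the ERG model;
#' the normalising constant over all graphs is deliberately excluded, as
#' every algorithm in the package only ever needs differences of this
#' quantity.
#'
#' @param stats Named statistic vector, as from [ergm_statistics()].
#' @param params Named parameter vector over the same terms.
#' @return A real number.
#' @export
ergm_log_weight <- function(stats, params) {
  if (!setequal(names(stats), names(params))) {
    stop("statistic and parameter term sets differ", call. = FALSE)
  }
  sum(params[names(stats)] * stats)
}
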