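#' Sampler and estimation settings
#'
#' Defaults follow the usual stochastic-approximation schedule for ERG
#' models: a calibration phase estimating the scale of each statistic, a
#' sequence of Robbins-Monro subphases with halving gain, and a long
#' final simulation from which standard errors and convergence t-ratios
#' are taken.
#'
#' @param burn_in Toggles discarded before sampling; default
#'   `max(10000, 20 * n_dyads)`.
#' @param thinning Toggles between retained samples; default `n_dyads`
#'   (one expected proposal per dyad).
#' @param phase1_n Calibration samples used to scale the updates.
#' @param phase2_subphases Number of Robbins-Monro subphases; the gain is
#'   halved and the subphase length doubled from one to the next.
#' @param phase2_n0 Updates in the first subphase.
#' @param gain0 Initial Robbins-Monro gain.
#' @param phase3_n Samples of the final simulation (standard errors,
#'   convergence t-ratios).
#' @param tol Convergence tolerance: largest absolute convergence t-ratio
#'   accepted as converged.
#' @param max_rounds Maximum number of update/check rounds: if the
#'   convergence t-ratios fail the tolerance, the update phase is
#'   repeated with the refreshed statistic covariance before giving up.
#' @return A list of settings (class `ergm_control`).
#' @export
ergm_control <- function(burn_in = NULL, thinning = NULL, phase1_n = 100,
                         phase2_subphases = 4, phase2_n0 = 50, gain0 = 0.1,
                         phase3_n = 500, tol = 0.1, max_rounds = 3) {
  structure(list(burn_in = burn_in, thinning = thinning,
                 phase1_n = phase1_n, phase2_subphases = phase2_subphases,
                 phase2_n0 = phase2_n0, gain0 = gain0,
                 phase3_n = phase3_n, tol = tol, max_rounds = max_rounds),
            class = "ergm_control")
}

check_params <- function(params, spec) {
  if (is.null(names(params)) || !setequal(names(params), spec$terms)) {
    stop("params must be named after the spec terms", call. = FALSE)
  }
  p <- as.numeric(params[spec$terms])
  if (any(!is.finite(p))) stop("params must be finite", call. = FALSE)
  stats::setNames(p, spec$terms)
}

#' Simulate graphs from an ERG model
#'
#' Metropolis chain over graphs: each step proposes toggling one uniformly
#' chosen dyad and accepts with probability
#' `min(1, exp(sum_A eta_A * delta_A))`, where `delta_A` are the change
#' statistics of the dyad, so the intractable normalising constant never
#' appears.  With an identical seed the output is identical.
#'
#' @param spec An [ergm_spec()].
#' @param params Named parameter vector over `spec$terms`.
#' @param n_nodes Number of nodes (`>= 2`).
#' @param n_samples Number of retained graphs.
#' @param burn_in,thinning Chain settings; `NULL` uses the
#'   [ergm_control()] defaults.
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param init Optional [binary_graph()] to start from (defaults to the
#'   empty graph).
#' @param output `"graphs"` for a list of [binary_graph()]s,
#'   `"statistics"` for the matrix of sampled sufficient statistics
#'   (rows = samples).
#' @return A list of graphs, or a numeric matrix of statistics.
#' @export
ergm_simulate <- function(spec, params, n_nodes, n_samples,
                          burn_in = NULL, thinning = NULL, seed = NULL,
                          init = NULL, output = c("graphs", "statistics")) {
  output <- match.arg(output)
  stopifnot(n_nodes >= 2, n_samples >= 1)
  theta <- check_params(params, spec)
  if (!is.null(seed)) set.seed(seed)
  dyads <- n_nodes * (n_nodes - 1) / 2
  if (is.null(burn_in)) burn_in <- max(10000, 20 * dyads)
  if (is.null(thinning)) thinning <- dyads
  adj <- if (is.null(init)) {
    matrix(0L, n_nodes, n_nodes)
  } else {
    init$adjacency
  }
  codes <- term_codes(spec$terms)
  adj <- cpp_mh_run(adj, theta, codes, spec$lambda, as.integer(burn_in))
  out_graphs <- vector("list", n_samples)
  out_stats <- matrix(NA_real_, n_samples, length(theta),
                      dimnames = list(NULL, spec$terms))
  for (s in seq_len(n_samples)) {
    adj <- cpp_mh_run(adj, theta, codes, spec$lambda, as.integer(thinning))
    g <- binary_graph(adj)
    if (output == "graphs") out_graphs[[s]] <- g
    else out_stats[s, ] <- ergm_statistics(g, spec)
  }
  if (output == "graphs") out_graphs else out_stats
}

#' Fit an ERG model by MCMC maximum likelihood
#'
#' Stochastic-approximation (Robbins-Monro) estimation: the parameters are
#' updated toward equating the simulated mean sufficient statistics with
#' the observed ones, which characterises the maximum-likelihood estimate
#' of an exponential-family model.  The edge parameter is initialised at
#' the logit of the observed density and the others at zero.  After the
#' update phases, a long simulation at the final parameters provides (i)
#' the estimated covariance of the statistics, whose inverse gives the
#' standard errors, and (ii) the convergence t-ratios
#' `(simulated mean - observed) / simulated SD`, all of which must fall
#' within `control$tol` in magnitude for the fit to count as converged.
#'
#' Degenerate situations are flagged rather than looped on: an observed
#' graph at the boundary (empty or complete with an edge term in the
#' model) returns immediately with `converged = FALSE` and flag
#' `"boundary"`, and a final chain stuck near the empty or complete graph
#' is flagged `"degenerate"`.
#'
#' @param graph A [binary_graph()] with at least 3 nodes.
#' @param spec An [ergm_spec()].
#' @param control An [ergm_control()].
#' @param seed Optional integer seed.
#' @return An `ergm_fit` object: `params`, `stderr`, `t_value`
#'   (estimate / stderr), `convergence_t_ratios`, `converged`, `flags`,
#'   `n_iterations`, `seed`, `observed`, `sample_mean`, `spec`.
#' @export
ergm_fit <- function(graph, spec, control = ergm_control(), seed = NULL) {
  n <- n_nodes(graph)
  if (n < 3) stop("ERGM fitting needs at least 3 nodes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dyads <- n * (n - 1) / 2
  burn_in <- control$burn_in %||% max(10000, 20 * dyads)
  thinning <- control$thinning %||% dyads
  codes <- term_codes(spec$terms)
  g_obs <- ergm_statistics(graph, spec)
  dens <- n_ties(graph) / dyads
  terms <- spec$terms
  na_vec <- stats::setNames(rep(NA_real_, length(terms)), terms)

  make_fit <- function(params, stderr, tratios, converged, flags, iters,
                       sample_mean = na_vec) {
    t_value <- ifelse(!is.na(stderr) & stderr > 1e-8, params / stderr,
                      NA_real_)
    structure(list(
      params = params, stderr = stderr,
      t_value = stats::setNames(t_value, terms),
      convergence_t_ratios = tratios, converged = converged,
      flags = flags, n_iterations = iters, seed = seed,
      observed = g_obs, sample_mean = sample_mean, spec = spec
    ), class = "ergm_fit")
  }

  if (dens %in% c(0, 1)) {
    init <- na_vec
    return(make_fit(init, na_vec, na_vec, FALSE, "boundary", 0L))
  }

  theta <- stats::setNames(rep(0, length(terms)), terms)
  if ("edge" %in% terms) theta["edge"] <- stats::qlogis(dens)

  run <- function(adj, steps) cpp_mh_run(adj, theta, codes, spec$lambda,
                                         as.integer(steps))
  stats_of <- function(adj) ergm_statistics(binary_graph(adj), spec)

  # Phase 1: estimate the statistic covariance, whose (ridged) inverse
  # scales the updates -- a Newton-type step that copes with the strong
  # correlation between, say, edge and star counts
  adj <- run(graph$adjacency, burn_in)
  p1 <- matrix(NA_real_, control$phase1_n, length(terms))
  for (k in seq_len(control$phase1_n)) {
    adj <- run(adj, thinning)
    p1[k, ] <- stats_of(adj)
  }
  ridged_inverse <- function(S) {
    ridge <- 1e-4 + 0.05 * mean(diag(S))
    solve(S + diag(ridge, length(terms)))
  }
  d_inv <- ridged_inverse(stats::cov(p1))

  iters <- 0L
  for (round in seq_len(max(1, control$max_rounds))) {
    # Phase 2: Robbins-Monro subphases with halving gain and doubling
    # length; the estimate is the average over the final subphase
    for (s in seq_len(control$phase2_subphases)) {
      gain <- control$gain0 / 2^(s - 1)
      n_s <- control$phase2_n0 * 2^(s - 1)
      theta_trace <- matrix(NA_real_, n_s, length(terms))
      for (k in seq_len(n_s)) {
        adj <- run(adj, thinning)
        g_sim <- stats_of(adj)
        theta <- theta - gain * as.vector(d_inv %*% (g_sim - g_obs))
        theta <- pmin(pmax(theta, -100), 100)
        theta_trace[k, ] <- theta
        iters <- iters + 1L
      }
    }
    theta <- stats::setNames(colMeans(theta_trace), terms)

    # Phase 3: long run at the final parameters
    adj <- run(adj, burn_in)
    p3 <- matrix(NA_real_, control$phase3_n, length(terms))
    edge_frac <- numeric(control$phase3_n)
    for (k in seq_len(control$phase3_n)) {
      adj <- run(adj, thinning)
      p3[k, ] <- stats_of(adj)
      edge_frac[k] <- sum(adj) / 2 / dyads
    }
    m <- colMeans(p3)
    S <- stats::cov(p3)
    sdv <- sqrt(pmax(diag(S), 0))
    tratios <- stats::setNames(
      ifelse(sdv > 0, (m - g_obs) / sdv, Inf), terms)
    if (all(abs(tratios) <= control$tol)) break
    # not yet matched: refresh the covariance scaling and update again
    d_inv <- ridged_inverse(S)
  }

  flags <- character(0)
  if (mean(edge_frac <= 1 / dyads | edge_frac >= 1 - 1 / dyads) > 0.9) {
    flags <- c(flags, "degenerate")
  }
  stderr <- na_vec
  info_inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(info_inv)) {
    flags <- c(flags, "singular")
  } else {
    stderr <- stats::setNames(sqrt(pmax(diag(info_inv), 0)), terms)
  }
  converged <- !length(flags) && all(abs(tratios) <= control$tol)
  make_fit(theta, stderr, tratios, converged, flags, iters,
           sample_mean = stats::setNames(m, terms))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ergm_fit <- function(x, ...) {
  cat("ERG model fit (MCMC maximum likelihood)\n")
  tab <- data.frame(
    estimate = round(x$params, 4),
    stderr = round(x$stderr, 4),
    t_value = round(x$t_value, 2),
    conv_t_ratio = round(x$convergence_t_ratios, 3)
  )
  print(tab)
  cat("converged:", x$converged)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Parameter t-values of a fit
#'
#' The t-value of a parameter is its estimate divided by its standard
#' error -- how many standard errors the estimate lies from zero;
#' magnitudes above 2 are conventionally read as meaningful effects.
#' Parameters whose standard error is missing or below a numerical floor
#' are returned as `NA` rather than divided, so that near-zero standard
#' errors never manufacture infinite t-values.
#'
#' @param fit An `ergm_fit`.
#' @param floor Smallest standard error accepted for division.
#' @return Named numeric vector (with `NA` for flagged terms).
#' @export
tvalues <- function(fit, floor = 1e-8) {
  stopifnot(inherits(fit, "ergm_fit"))
  ok <- !is.na(fit$stderr) & fit$stderr > floor
  out <- ifelse(ok, fit$params / fit$stderr, NA_real_)
  stats::setNames(out, names(fit$params))
}
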