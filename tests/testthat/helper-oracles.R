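# independent oracles, deliberately brute-force ------------------------

# normalised betweenness by counting walks at exact shortest distances:
# walks of length d(j, k) are necessarily simple shortest paths, so the
# matrix powers of the adjacency give path counts without any shortest-
# path algorithm.
oracle_betweenness <- function(graph) {
  adj <- graph$adjacency
  n <- nrow(adj)
  pow <- vector("list", n)
  pow[[1]] <- adj
  for (l in seq_len(n - 1)[-1]) pow[[l]] <- pow[[l - 1]] %*% adj
  dist <- matrix(Inf, n, n)
  npaths <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    for (l in seq_len(n - 1)) {
      if (pow[[l]][j, k] > 0) {
        dist[j, k] <- l
        npaths[j, k] <- pow[[l]][j, k]
        break
      }
    }
  }
  b <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j >= k || j == i || k == i) next
      if (!is.finite(dist[j, k])) next
      through <- 0
      if (is.finite(dist[j, i]) && is.finite(dist[i, k]) &&
          dist[j, i] + dist[i, k] == dist[j, k]) {
        through <- npaths[j, i] * npaths[i, k]
      }
      tot <- tot + through / npaths[j, k]
    }
    b[i] <- tot / ((n - 1) * (n - 2) / 2)
  }
  b
}

# shared-partner counts per unordered pair
oracle_shared_partners <- function(adj) {
  n <- nrow(adj)
  sp <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) sp[i, j] <- sum(adj[i, ] & adj[j, ])
  }
  sp
}

# alternating statistics evaluated from their defining alternating sums
# over enumerated k-star / shared-partner counts (not the closed forms)
oracle_alternating <- function(graph, term, lambda) {
  adj <- graph$adjacency
  n <- nrow(adj)
  d <- rowSums(adj)
  sp <- oracle_shared_partners(adj)
  if (term == "alt_k_star") {
    if (n < 2) return(0)
    s_k <- vapply(2:max(2, n - 1), function(k) sum(choose(d, k)), numeric(1))
    ks <- seq_along(s_k) + 1
    return(sum((-1)^ks * s_k / lambda^(ks - 2)))
  }
  counts <- if (term == "alt_k_triangle") {
    sp[upper.tri(sp) & adj == 1L]
  } else {
    sp[upper.tri(sp)]
  }
  if (!length(counts) || max(counts) == 0) return(0)
  t_k <- vapply(seq_len(max(counts)), function(k) sum(choose(counts, k)),
                numeric(1))
  ks <- seq_along(t_k)
  sum((-1)^(ks + 1) * t_k / lambda^(ks - 1))
}

# every labelled graph on n nodes (as binary_graph objects)
enumerate_graphs <- function(n) {
  n_dyads <- n * (n - 1) / 2
  lapply(seq_len(2^n_dyads) - 1, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n_dyads)]
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- bits
    binary_graph(adj + t(adj))
  })
}

# exact moments of the ERG distribution by exhaustive enumeration
exact_ergm_moments <- function(spec, params, n) {
  graphs <- enumerate_graphs(n)
  stats <- t(vapply(graphs, ergm_statistics, numeric(length(spec$terms)),
                    spec = spec))
  w <- exp(as.vector(stats %*% params[spec$terms]))
  w <- w / sum(w)
  list(mean = colSums(stats * w),
       var = colSums(stats^2 * w) - colSums(stats * w)^2)
}
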