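#' Binary (tie/no-tie) graph
#'
#' The network-level indices and the ERG models operate on tie presence,
#' not on weights.  A `binary_graph` wraps a symmetric 0/1 adjacency
#' matrix with a zero diagonal and named nodes.
#'
#' @param adjacency Square symmetric 0/1 (or logical) matrix; the diagonal
#'   is ignored.
#' @param nodes Optional node names (defaults to the matrix dimnames or
#'   `n1...nN`).
#' @return A `binary_graph` object.
#' @export
binary_graph <- function(adjacency, nodes = NULL) {
  adjacency <- as.matrix(adjacency)
  mode(adjacency) <- "integer"
  adjacency[adjacency != 0L] <- 1L
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be square", call. = FALSE)
  }
  diag(adjacency) <- 0L
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- rownames(adjacency)
    if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(adjacency)))
  }
  dimnames(adjacency) <- list(nodes, nodes)
  structure(list(adjacency = adjacency), class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("binary graph:", n_nodes(x), "nodes,", n_ties(x), "ties\n")
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$adjacency)
n_ties <- function(graph) sum(graph$adjacency) %/% 2L

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
}

#' Dichotomise a weighted collaboration network
#'
#' A tie is present between two physicians when their shared-patient
#' count reaches `threshold`.  The default threshold of 1 treats any
#' shared patient as a collaboration tie; the node set (including
#' isolates) is preserved.
#'
#' @param pcn A `pcn` graph (or any weighted undirected igraph).
#' @param threshold Minimum weight that forms a tie (positive integer).
#' @return A [binary_graph()].
#' @export
binarise <- function(pcn, threshold = 1) {
  stopifnot(threshold >= 1)
  adj <- as.matrix(igraph::as_adjacency_matrix(pcn, attr = "weight",
                                               sparse = FALSE))
  binary_graph(adj >= threshold, nodes = igraph::V(pcn)$name)
}

#' Node-level centrality (normalised)
#'
#' Degree centrality of a node is its degree as a proportion of the
#' `N - 1` other nodes, so an isolate scores 0 and a node tied to everyone
#' scores 1.  Betweenness centrality is the sum over node pairs of the
#' share of shortest paths passing through the node, normalised by the
#' number of pairs `(N - 1)(N - 2) / 2`; pairs with no connecting path
#' contribute 0.  The hub of a star scores 1 on both.
#'
#' @param graph A [binary_graph()].
#' @param kind `"degree"` or `"betweenness"`.
#' @return Named numeric vector in \[0, 1\], one value per node.
#' @export
centrality <- function(graph, kind = c("degree", "betweenness")) {
  kind <- match.arg(kind)
  n <- n_nodes(graph)
  if (kind == "degree") {
    if (n < 2) stop("degree centrality needs at least 2 nodes", call. = FALSE)
    return(rowSums(graph$adjacency) / (n - 1))
  }
  if (n < 3) {
    stop("betweenness centrality needs at least 3 nodes", call. = FALSE)
  }
  b <- igraph::betweenness(as_igraph(graph), directed = FALSE, weights = NA)
  stats::setNames(as.numeric(b) / ((n - 1) * (n - 2) / 2),
                  rownames(graph$adjacency))
}

#' Network centralisation
#'
#' Freeman's network-level index: the sum of differences between the
#' largest observed centrality and each node's centrality, divided by the
#' maximum that sum can attain, so that a star scores 1 and a perfectly
#' egalitarian (e.g. circle) graph scores 0.  Degree centralisation is
#' computed on raw degrees with denominator `(N - 1)(N - 2)`; betweenness
#' centralisation on normalised betweenness with denominator `N - 1`.
#'
#' @param graph A [binary_graph()] with at least 3 nodes.
#' @param kind `"degree"` or `"betweenness"`.
#' @return A number in \[0, 1\].
#' @export
centralisation <- function(graph, kind = c("degree", "betweenness")) {
  kind <- match.arg(kind)
  n <- n_nodes(graph)
  if (n < 3) stop("centralisation needs at least 3 nodes", call. = FALSE)
  if (kind == "degree") {
    d <- rowSums(graph$adjacency)
    sum(max(d) - d) / ((n - 1) * (n - 2))
  } else {
    b <- centrality(graph, "betweenness")
    sum(max(b) - b) / (n - 1)
  }
}

#' Network density
#'
#' The proportion of realised ties among the `N(N - 1) / 2` possible
#' unordered pairs: 1 for a complete graph, 0 for an edgeless one.
#'
#' @param graph A [binary_graph()] with at least 2 nodes.
#' @return A number in \[0, 1\].
#' @export
network_density <- function(graph) {
  n <- n_nodes(graph)
  if (n < 2) stop("density needs at least 2 nodes", call. = FALSE)
  2 * n_ties(graph) / (n * (n - 1))
}

#' Network-level summary of a collaboration network
#'
#' Dichotomises the weighted network at `threshold` and returns the three
#' network-level indices together with size metadata.
#'
#' @param pcn A `pcn` graph.
#' @param threshold Tie threshold passed to [binarise()].
#' @return A one-row tibble: `hospital_id`, `n_nodes`, `n_edges`,
#'   `density`, `degree_centralisation`, `betweenness_centralisation`.
#' @export
summarise_pcn <- function(pcn, threshold = 1) {
  g <- binarise(pcn, threshold)
  tibble::tibble(
    hospital_id = igraph::graph_attr(pcn, "hospital_id"),
    n_nodes = n_nodes(g),
    n_edges = n_ties(g),
    density = network_density(g),
    degree_centralisation = centralisation(g, "degree"),
    betweenness_centralisation = centralisation(g, "betweenness")
  )
}

#' Summaries for a list of collaboration networks
#'
#' @param pcns A list of `pcn` graphs, as from [build_pcns()].
#' @param threshold Tie threshold passed to [binarise()].
#' @return A tibble with one [summarise_pcn()] row per network.
#' @export
summarise_pcns <- function(pcns, threshold = 1) {
  dplyr::bind_rows(lapply(pcns, summarise_pcn, threshold = threshold))
}
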