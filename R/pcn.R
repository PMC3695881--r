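#' Build the physician collaboration network of one hospital
#'
#' Projects the two-mode patient-physician visit relation of a hospital
#' onto physicians: nodes are all physicians with at least one medical
#' claim in the hospital, and an edge joins two physicians with weight
#' equal to the number of distinct patients both visited.  Physicians who
#' share no patient remain isolate nodes (they still enter the node count
#' of the network-level indices).  Only medical-category claims define
#' visits; ancillary and hospital claims carry cost but no physician
#' collaboration information.
#'
#' @param visits A `visit_table`.
#' @param hospital_id Hospital whose network to build.
#'
#' @return An [igraph][igraph::igraph-package] graph (class `pcn`),
#'   undirected and weighted, with graph attributes `hospital_id` and
#'   `patient_count` (distinct patients among the hospital's records).
#' @examples
#' visits <- validate_claims(tibble::tibble(
#'   hospital_id = "H1",
#'   patient_id = rep(c("Pa1", "Pa2", "Pa3"), c(3, 3, 2)),
#'   physician_id = c("Ph1", "Ph2", "Ph4", "Ph2", "Ph3", "Ph4", "Ph3", "Ph4"),
#'   admission_id = rep(c("A1", "A2", "A3"), c(3, 3, 2)),
#'   service_date = as.Date("2020-01-01"),
#'   claim_category = "medical",
#'   benefit_amount = 100,
#'   patient_age = 70,
#'   procedure_code = "THR"
#' ))
#' pcn <- build_pcn(visits, "H1")
#' igraph::E(pcn)$weight  # shared-patient counts
#' @export
build_pcn <- function(visits, hospital_id) {
  rows <- visits[visits$hospital_id == hospital_id, ]
  if (!nrow(rows)) {
    stop("unknown hospital_id: ", hospital_id, call. = FALSE)
  }
  patient_count <- length(unique(rows$patient_id))
  med <- rows[rows$claim_category == "medical", ]
  pairs <- unique(med[, c("patient_id", "physician_id")])
  physicians <- sort(unique(pairs$physician_id))

  # incidence (patients x physicians); projection weights are the inner
  # products: weight(i, j) = number of patients visited by both
  if (nrow(pairs)) {
    inc <- table(pairs$patient_id, pairs$physician_id)
    w <- crossprod(inc)
    diag(w) <- 0
    g <- igraph::graph_from_adjacency_matrix(
      w[physicians, physicians, drop = FALSE],
      mode = "undirected", weighted = TRUE
    )
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  }
  g <- igraph::set_graph_attr(g, "hospital_id", hospital_id)
  g <- igraph::set_graph_attr(g, "patient_count", patient_count)
  class(g) <- unique(c("pcn", class(g)))
  g
}

#' Build the collaboration network of every hospital
#'
#' @param visits A `visit_table`.
#' @return A named list of `pcn` graphs, one per hospital.
#' @export
build_pcns <- function(visits) {
  ids <- sort(unique(visits$hospital_id))
  stats::setNames(lapply(ids, function(h) build_pcn(visits, h)), ids)
}

#' @export
print.pcn <- function(x, ...) {
  cat("Physician collaboration network --",
      igraph::graph_attr(x, "hospital_id"), "\n")
  cat("  physicians:", igraph::vcount(x),
      " collaborations:", igraph::ecount(x),
      " patients:", igraph::graph_attr(x, "patient_count"), "\n")
  invisible(x)
}

#' Write a collaboration network to disk
#'
#' Two plain-text formats are supported: GraphML (self-contained,
#' attribute-preserving) and a 3-column tab-separated edge list
#' (`node_i`, `node_j`, `weight`) with a companion `<path>.nodes` file
#' listing every node -- including isolates -- plus the hospital metadata
#' as `#`-comment lines.  Both round-trip exactly through [read_pcn()].
#'
#' @param pcn A `pcn` graph.
#' @param path Output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_pcn <- function(pcn, path, format = c("graphml", "tsv")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop("unsupported format '", format[1],
         "'; supported formats: graphml, tsv", call. = FALSE)
  })
  if (format == "graphml") {
    igraph::write_graph(pcn, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(pcn, what = "edges")
    edges <- tibble::tibble(node_i = ed$from, node_j = ed$to,
                            weight = as.integer(ed$weight))
    readr::write_tsv(edges, path, progress = FALSE)
    node_path <- paste0(path, ".nodes")
    meta <- c(
      paste0("# hospital_id=", igraph::graph_attr(pcn, "hospital_id")),
      paste0("# patient_count=", igraph::graph_attr(pcn, "patient_count")),
      "node"
    )
    writeLines(c(meta, igraph::V(pcn)$name), node_path)
  }
  invisible(path)
}

#' Read a collaboration network written by [write_pcn()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"tsv"`.
#' @return A `pcn` graph.
#' @export
read_pcn <- function(path, format = c("graphml", "tsv")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop("unsupported format '", format[1],
         "'; supported formats: graphml, tsv", call. = FALSE)
  })
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::vcount(g) && is.null(igraph::V(g)$name)) {
      g <- igraph::set_vertex_attr(g, "name", value = igraph::V(g)$id)
    }
  } else {
    node_path <- paste0(path, ".nodes")
    lines <- readLines(node_path)
    meta <- lines[startsWith(lines, "#")]
    nodes <- setdiff(lines[!startsWith(lines, "#")], "node")
    edges <- readr::read_tsv(path, col_types = "cci", progress = FALSE)
    g <- igraph::graph_from_data_frame(
      edges[, c("node_i", "node_j")], directed = FALSE,
      vertices = data.frame(name = nodes)
    )
    g <- igraph::set_edge_attr(g, "weight", value = edges$weight)
    get_meta <- function(key) {
      hit <- sub(paste0("^# ", key, "="), "",
                 meta[startsWith(meta, paste0("# ", key, "="))])
      if (length(hit)) hit[[1]] else NA_character_
    }
    g <- igraph::set_graph_attr(g, "hospital_id", get_meta("hospital_id"))
    g <- igraph::set_graph_attr(g, "patient_count",
                                as.integer(get_meta("patient_count")))
  }
  class(g) <- unique(c("pcn", class(g)))
  g
}
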