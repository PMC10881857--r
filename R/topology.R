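#' Convert an MI network (or edge table) to an igraph graph
#'
#' @param x An [mi_network()] or a data.frame with columns `a`, `b`.
#' @param nodes Optional node id vector (keeps isolated nodes).
#' @return Undirected simple igraph graph.
#' @export
as_igraph_network <- function(x, nodes = NULL) {
  if (inherits(x, "mi_network")) {
    edges <- x$edges[, c("a", "b"), drop = FALSE]
    nodes <- x$nodes$id
  } else {
    edges <- as.data.frame(x)[, c("a", "b"), drop = FALSE]
    if (is.null(nodes)) nodes <- unique(c(edges$a, edges$b))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Per-node topology metrics (NetworkAnalyzer conventions)
#'
#' For a simple undirected unweighted graph computes, per node: average
#' shortest path length to reachable nodes (`aspl`, NA for isolated nodes),
#' betweenness centrality normalized by (N-1)(N-2)/2 (`betweenness`),
#' Cytoscape closeness = reachable count / sum of distances (`closeness`, 0
#' for isolated nodes), neighborhood connectivity = mean neighbor degree
#' (`nc`, 0 for isolated nodes), and the topological coefficient (`tc`): for
#' nodes of degree >= 2, the mean over nodes sharing at least one neighbor of
#' (shared-neighbor count, plus 1 if adjacent) divided by the degree, else 0.
#'
#' @param graph An undirected, unweighted igraph graph.
#' @return data.frame: node, degree, aspl, betweenness, closeness, nc, tc.
#' @export
node_metrics <- function(graph) {
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  if ("weight" %in% igraph::edge_attr_names(graph)) {
    stop("graph must be unweighted (drop the 'weight' edge attribute)")
  }
  n <- igraph::vcount(graph)
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  deg <- igraph::degree(graph)
  D <- igraph::distances(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = FALSE))

  aspl <- closeness <- nc <- tc <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    reach <- is.finite(d) & d > 0
    aspl[i] <- if (any(reach)) mean(d[reach]) else NA_real_
    closeness[i] <- if (any(reach)) sum(reach) / sum(d[reach]) else 0
    nc[i] <- if (deg[i] > 0) mean(deg[A[i, ] > 0]) else 0
  }
  btw <- if (n >= 3) igraph::betweenness(graph, normalized = TRUE)
         else rep(0, n)
  S <- A %*% A
  for (i in seq_len(n)) {
    if (deg[i] < 2) { tc[i] <- 0; next }
    share <- which(S[i, ] > 0 & seq_len(n) != i)
    tc[i] <- if (length(share)) {
      mean(S[i, share] + (A[i, share] > 0)) / deg[i]
    } else 0
  }
  data.frame(node = ids, degree = as.integer(deg), aspl = aspl,
             betweenness = as.numeric(btw), closeness = closeness, nc = nc,
             tc = tc, row.names = NULL, stringsAsFactors = FALSE)
}

#' Network-level topology summary
#'
#' Arithmetic means of the per-node metrics; nodes with undefined ASPL
#' (isolated) are excluded from the ASPL mean only.
#'
#' @param graph An undirected, unweighted igraph graph (non-empty).
#' @param id Optional network id carried into the result.
#' @return One-row data.frame: network, aspl, bc, cc, nc, tc.
#' @export
summarize_network <- function(graph, id = "network") {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  m <- node_metrics(graph)
  data.frame(network = id, aspl = mean(m$aspl, na.rm = TRUE),
             bc = mean(m$betweenness), cc = mean(m$closeness),
             nc = mean(m$nc), tc = mean(m$tc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Average per-network summaries across a group of networks
#'
#' Unweighted mean of each metric across networks (each network counts once,
#' regardless of size).
#'
#' @param summaries data.frame of [summarize_network()] rows, or a list of
#'   them.
#' @param id Group label.
#' @return One-row data.frame: network (= `id`), aspl, bc, cc, nc, tc.
#' @export
summarize_group <- function(summaries, id = "group") {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, summaries)
  }
  stopifnot(nrow(summaries) >= 1)
  data.frame(network = id, aspl = mean(summaries$aspl),
             bc = mean(summaries$bc), cc = mean(summaries$cc),
             nc = mean(summaries$nc), tc = mean(summaries$tc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Round half away from zero (table reporting convention)
#'
#' @param x Numeric vector (non-negative metrics).
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 3) {
  floor(x * 10^digits + 0.5 + sqrt(.Machine$double.eps)) / 10^digits
}

#' Read a metric-by-network TSV table into per-network summary rows
#'
#' Inverse of [write_topology_table()]; also reads published comparison
#' tables in the same layout (rows ASPL, BC, CC, NC, TC).
#'
#' @param path TSV path.
#' @return data.frame: network, aspl, bc, cc, nc, tc.
#' @export
read_topology_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot(identical(toupper(df[[1]]), c("ASPL", "BC", "CC", "NC", "TC")))
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- c("aspl", "bc", "cc", "nc", "tc")
  data.frame(network = rownames(m), m, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write per-network summaries as a metric-by-network TSV table
#'
#' Rows ASPL, BC, CC, NC, TC; one column per network; values rounded half-up.
#'
#' @param summaries data.frame of [summarize_network()] rows.
#' @param path Output path.
#' @param digits Decimal places (default 3).
#' @export
write_topology_table <- function(summaries, path, digits = 3) {
  m <- t(as.matrix(summaries[, c("aspl", "bc", "cc", "nc", "tc")]))
  m <- round_half_up(m, digits)
  rownames(m) <- c("ASPL", "BC", "CC", "NC", "TC")
  colnames(m) <- summaries$network
  df <- data.frame(metric = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
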