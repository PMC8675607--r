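#' Node centralities on the thresholded co-expression graph
#'
#' Degree (DG) counts neighbors.  Betweenness (BW) is the summed fraction of
#' shortest paths through a node, normalized by the number of node pairs
#' excluding it, `(N - 1)(N - 2) / 2`, with N the size of the node's
#' connected component, so BW lies in \[0, 1\].  Closeness (CN) is the
#' inverse of the mean shortest-path length to every reachable node
#' (0 for isolated nodes).  The clustering coefficient (CC) is
#' `2 e_v / (k_v (k_v - 1))`, the density of edges among a node's
#' neighbors (0 when the degree is below 2).  All measures treat the graph
#' as simple and unweighted.
#'
#' @param graph an igraph undirected graph.
#' @return A named numeric (integer for `node_degree`) vector over nodes.
#' @name centralities
NULL

#' @rdname centralities
#' @export
node_degree <- function(graph) {
  igraph::degree(graph)
}

#' @rdname centralities
#' @export
node_betweenness <- function(graph) {
  raw <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  comps <- igraph::components(graph)
  nc <- comps$csize[comps$membership]
  denom <- (nc - 1) * (nc - 2) / 2
  bw <- ifelse(denom > 0, raw / denom, 0)
  setNames(as.numeric(bw), names(raw))
}

#' @rdname centralities
#' @export
node_closeness <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(setNames(numeric(0), character(0)))
  d <- igraph::distances(graph, weights = NA)
  cn <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0L) 0 else 1 / mean(dv)
  }, numeric(1))
  setNames(cn, igraph::V(graph)$name)
}

#' @rdname centralities
#' @export
clustering_coefficient <- function(graph) {
  cc <- igraph::transitivity(graph, type = "localundirected",
                             isolates = "zero")
  setNames(cc, igraph::V(graph)$name)
}

# ascending percentile rank in (0, 1]: high values -> high percentile;
# ties get the average rank
percentile_rank <- function(x) {
  rank(x, ties.method = "average") / length(x)
}

#' Per-gene centrality table for one state network
#'
#' All four measures plus descending percentile ranks (a percentile of 1
#' marks the top-ranked gene; ties receive the average rank).
#'
#' @param net a [build_network()] result (its thresholded graph is used).
#' @return A data frame (class `centrality_table`) with columns `gene`,
#'   `state`, `DG`, `BW`, `CN`, `CC` and `*_pct` percentile columns.
#' @export
centrality_table <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- net$graph
  dg <- node_degree(g)
  bw <- node_betweenness(g)
  cn <- node_closeness(g)
  cc <- clustering_coefficient(g)
  res <- data.frame(
    gene = names(dg), state = net$state_label,
    DG = as.integer(dg), BW = as.numeric(bw), CN = as.numeric(cn),
    CC = as.numeric(cc),
    DG_pct = percentile_rank(dg), BW_pct = percentile_rank(bw),
    CN_pct = percentile_rank(cn), CC_pct = percentile_rank(cc),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(res) <- c("centrality_table", "data.frame")
  res
}
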