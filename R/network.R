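#' Pairwise Pearson correlation of gene expression profiles
#'
#' @param log_expr gene x sample matrix of log expression.
#' @return An object of class `correlation_matrix`: list with `genes` and
#'   the symmetric correlation matrix `r` (unit diagonal; zero-variance
#'   genes get r = 0 off-diagonal by convention and are listed in
#'   `zero_variance`).
#' @export
correlation_matrix <- function(log_expr) {
  log_expr <- as.matrix(log_expr)
  if (ncol(log_expr) < 3L) {
    stop("at least 3 samples are required for correlations", call. = FALSE)
  }
  sds <- apply(log_expr, 1, sd)
  zv <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(t(log_expr)))
  if (any(zv)) {
    r[zv, ] <- 0
    r[, zv] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r <- (r + t(r)) / 2
  structure(list(genes = rownames(log_expr), r = r,
                 zero_variance = rownames(log_expr)[zv]),
            class = "correlation_matrix")
}

# log-log regression of degree frequency on degree: slope and R^2 of the
# scale-free topology fit.  Degrees are binned into n_bins equal-width bins.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < 2L || diff(range(k)) == 0) {
    return(list(r2 = NA_real_, slope = NA_real_))
  }
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(ok) < 3L) return(list(r2 = NA_real_, slope = NA_real_))
  xf <- log10(mean_k[ok])
  yf <- log10(freq[ok] / sum(freq[ok]))
  fit <- lm(yf ~ xf)
  list(r2 = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
}

#' Scan soft-threshold powers for scale-free topology fit
#'
#' For each candidate power, the weighted connectivity
#' `k_i = sum_j |r_ij|^beta` is computed, the connectivity distribution is
#' binned, and log10(frequency) is regressed on log10(mean connectivity per
#' bin).  The chosen power is the smallest one whose fit R^2 reaches
#' `fit_threshold` (NA sentinel if none does).
#'
#' @param cor a [correlation_matrix()].
#' @param powers candidate integer powers.
#' @param fit_threshold minimum scale-free fit R^2 (default 0.90).
#' @param n_bins number of connectivity histogram bins.
#' @return An object of class `soft_threshold_scan`: data frame `scan`
#'   (power, r2, slope, mean_connectivity), `chosen_beta`, `fit_threshold`.
#' @export
soft_threshold_scan <- function(cor, powers = 1:20, fit_threshold = 0.90,
                                n_bins = 10) {
  stopifnot(inherits(cor, "correlation_matrix"))
  if (length(cor$genes) < 2L) stop("at least 2 genes required", call. = FALSE)
  a0 <- abs(cor$r)
  diag(a0) <- 0
  rows <- lapply(powers, function(beta) {
    a <- a0^beta
    k <- rowSums(a)
    fit <- scale_free_fit(k, n_bins = n_bins)
    data.frame(power = beta, r2 = fit$r2, slope = fit$slope,
               mean_connectivity = mean(k))
  })
  scan <- do.call(rbind, rows)
  # a scale-free fit requires a decreasing log-log line: positive-slope fits
  # are rejected regardless of R^2 (the signed-R^2 convention)
  hit <- which(!is.na(scan$r2) & scan$r2 >= fit_threshold & scan$slope < 0)
  chosen <- if (length(hit)) scan$power[hit[1L]] else NA_integer_
  structure(list(scan = scan, chosen_beta = chosen,
                 fit_threshold = fit_threshold),
            class = "soft_threshold_scan")
}

#' Pick a power from a soft-threshold scan, with a fallback
#'
#' Returns `chosen_beta` when the scan reached the fit threshold.  When no
#' power qualifies (common for small or strongly modular networks, whose
#' degree distributions are not scale-free), falls back on the standard
#' sample-size rule of thumb for unsigned networks when `n_samples` is
#' given (< 20 samples: 9; 20-30: 8; 30-40: 7; > 40: 6), otherwise on the
#' smallest power whose negative-slope fit R^2 reaches 90% of the best
#' observed.
#'
#' @param scan a [soft_threshold_scan()] result.
#' @param n_samples number of samples the correlations were computed from
#'   (enables the rule-of-thumb fallback).
#' @return An integer power.
#' @export
pick_power <- function(scan, n_samples = NULL) {
  stopifnot(inherits(scan, "soft_threshold_scan"))
  if (!is.na(scan$chosen_beta)) return(scan$chosen_beta)
  if (!is.null(n_samples)) {
    return(if (n_samples < 20) 9L else if (n_samples < 30) 8L
           else if (n_samples <= 40) 7L else 6L)
  }
  r2 <- scan$scan$r2
  ok <- !is.na(r2) & scan$scan$slope < 0
  if (!any(ok)) stop("scale-free fit undefined at every power", call. = FALSE)
  best <- max(r2[ok])
  scan$scan$power[which(ok & r2 >= 0.9 * best)[1L]]
}

#' Build a weighted co-expression network
#'
#' Unsigned power adjacency `a_ij = |r_ij|^beta`; an undirected edge is kept
#' for every unordered pair with `a_ij >= edge_min` (inclusive, "0.1 or
#' heavier").  Genes isolated after thresholding are dropped from the graph
#' but retained in the adjacency matrix.
#'
#' @param cor a [correlation_matrix()].
#' @param beta soft-threshold power (>= 1).
#' @param edge_min minimum edge weight kept in the graph, in (0, 1).
#' @param state_label one of "global", "normal", "salinity" (free-form).
#' @param drop_isolated drop nodes with no retained edge from the graph.
#' @return An object of class `coexpression_network`: `genes`, `adjacency`,
#'   `beta`, `edge_min`, `graph` (igraph, weighted), `state_label`.
#' @export
build_network <- function(cor, beta, edge_min = 0.1, state_label = "global",
                          drop_isolated = TRUE) {
  stopifnot(inherits(cor, "correlation_matrix"))
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  if (edge_min <= 0 || edge_min >= 1) {
    stop("edge_min must lie in (0, 1)", call. = FALSE)
  }
  a <- abs(cor$r)^beta
  diag(a) <- 0
  ut <- upper.tri(a)
  keep <- which(ut & a >= edge_min, arr.ind = TRUE)
  edges <- data.frame(from = cor$genes[keep[, 1]],
                      to = cor$genes[keep[, 2]],
                      weight = a[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = cor$genes))
  if (drop_isolated) {
    iso <- igraph::V(g)[igraph::degree(g) == 0]
    g <- igraph::delete_vertices(g, iso)
  }
  structure(list(genes = cor$genes, adjacency = a, beta = beta,
                 edge_min = edge_min, graph = g, state_label = state_label),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network [%s]: %d genes, graph %d nodes / %d edges (beta=%g, edge_min=%g)\n",
              x$state_label, length(x$genes), igraph::vcount(x$graph),
              igraph::ecount(x$graph), x$beta, x$edge_min))
  invisible(x)
}

#' Average degree and connections per node from node/edge counts
#'
#' Arithmetic helpers for the standard network summary panel:
#' average degree = 2E/N, connections per node = E/N.
#'
#' @param n_nodes,n_edges node and edge counts.
#' @return A number.
#' @export
average_degree <- function(n_nodes, n_edges) 2 * n_edges / n_nodes

#' @rdname average_degree
#' @export
connections_per_node <- function(n_nodes, n_edges) n_edges / n_nodes

#' Structural property panel of a co-expression network
#'
#' Node and edge counts, average degree (2E/N), diameter of the largest
#' connected component, average local clustering coefficient, connections
#' per node (E/N), and the slope and R^2 of the power-law (scale-free)
#' degree-distribution fit.
#'
#' @param net a [build_network()] result.
#' @param n_bins bins for the degree-distribution fit.
#' @return A list of class `network_properties`.
#' @export
network_properties <- function(net, n_bins = 10) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0L) {
    warning("empty graph: all properties zero")
    return(structure(list(n_nodes = 0, n_edges = 0, average_degree = 0,
                          diameter = 0, average_clustering_coefficient = 0,
                          connections_per_node = 0,
                          power_law_slope = NA_real_,
                          power_law_r2 = NA_real_,
                          state_label = net$state_label),
                     class = "network_properties"))
  }
  comps <- igraph::components(g)
  big <- which.max(comps$csize)
  sub <- igraph::induced_subgraph(g, which(comps$membership == big))
  diam <- igraph::diameter(sub, weights = NA)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  degs <- igraph::degree(g)
  fit <- scale_free_fit(degs, n_bins = n_bins)
  structure(list(
    n_nodes = n, n_edges = e,
    average_degree = average_degree(n, e),
    diameter = diam,
    average_clustering_coefficient = mean(cc),
    connections_per_node = connections_per_node(n, e),
    power_law_slope = fit$slope, power_law_r2 = fit$r2,
    state_label = net$state_label
  ), class = "network_properties")
}

#' @export
print.network_properties <- function(x, ...) {
  cat(sprintf("network_properties [%s]\n", x$state_label))
  for (f in c("n_nodes", "n_edges", "average_degree", "diameter",
              "average_clustering_coefficient", "connections_per_node",
              "power_law_slope", "power_law_r2")) {
    cat(sprintf("  %-32s %s\n", f, format(x[[f]])))
  }
  invisible(x)
}
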