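test_that("Pearson correlation matrix matches the textbook formula", {
  set.seed(2)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  cm <- correlation_matrix(x)
  # brute force: cov / (sd sd)
  for (i in c(1, 7, 20)) for (j in c(2, 13)) {
    xi <- x[i, ]; xj <- x[j, ]
    r_bf <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(cm$r[i, j], r_bf, tolerance = 1e-12)
  }
  expect_equal(diag(cm$r), rep(1, 20), ignore_attr = TRUE)
  expect_lt(max(abs(cm$r - t(cm$r))), 1e-12)

  # affine invariance and anti-correlation
  y <- rbind(a = x[1, ], b = 3 * x[1, ] + 5, c = -x[1, ])
  cy <- correlation_matrix(y)$r
  expect_equal(cy["a", "b"], 1)
  expect_equal(cy["a", "c"], -1)

  expect_error(correlation_matrix(x[, 1:2]), "3 samples")

  z <- rbind(const = rep(2, 10), x[1:2, ])
  cz <- correlation_matrix(z)
  expect_equal(cz$r["const", 2:3], c(0, 0), ignore_attr = TRUE)
  expect_equal(cz$zero_variance, "const")
})

test_that("soft-threshold scan: identity power, monotone connectivity, chosen beta", {
  set.seed(4)
  x <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
  cm <- correlation_matrix(x)
  scan <- soft_threshold_scan(cm, powers = 1:10)
  a1 <- abs(cm$r); diag(a1) <- 0
  expect_equal(scan$scan$mean_connectivity[1], mean(rowSums(a1)))
  expect_true(all(diff(scan$scan$mean_connectivity) < 0))
  hit <- which(!is.na(scan$scan$r2) & scan$scan$r2 >= scan$fit_threshold &
                 scan$scan$slope < 0)
  if (length(hit)) expect_equal(scan$chosen_beta, scan$scan$power[hit[1]])
  else expect_true(is.na(scan$chosen_beta))
})

test_that("a power-law degree sequence fits with high R2 and negative slope", {
  # discrete power law k^-2 over k = 1..50, frequencies set analytically
  k <- 1:50
  freq <- round(1e5 * k^-2)
  ks <- rep(k, freq)
  fit <- saltnet:::scale_free_fit(ks, n_bins = 10)
  expect_gt(fit$r2, 0.95)
  expect_lt(fit$slope, 0)
})

test_that("power adjacency and inclusive edge threshold", {
  r <- diag(2); r[1, 2] <- r[2, 1] <- 0.9
  dimnames(r) <- list(c("a", "b"), c("a", "b"))
  cm <- structure(list(genes = c("a", "b"), r = r, zero_variance = character(0)),
                  class = "correlation_matrix")
  net <- build_network(cm, beta = 10, edge_min = 0.1)
  expect_equal(net$adjacency["a", "b"], 0.9^10)
  expect_equal(igraph::ecount(net$graph), 1)

  # weight exactly at the threshold is kept ("0.1 or heavier")
  r2 <- diag(2); r2[1, 2] <- r2[2, 1] <- 0.1
  dimnames(r2) <- dimnames(r)
  cm2 <- structure(list(genes = c("a", "b"), r = r2,
                        zero_variance = character(0)),
                   class = "correlation_matrix")
  net2 <- build_network(cm2, beta = 1, edge_min = 0.1)
  expect_equal(igraph::ecount(net2$graph), 1)
})

test_that("edge set equals brute-force thresholding; raising edge_min only removes", {
  set.seed(9)
  x <- matrix(rnorm(25 * 10), 25, 10,
              dimnames = list(paste0("g", 1:25), paste0("s", 1:10)))
  cm <- correlation_matrix(x)
  net <- build_network(cm, beta = 3, edge_min = 0.1)
  a <- abs(cm$r)^3; diag(a) <- 0
  bf_edges <- sum(a[upper.tri(a)] >= 0.1)
  expect_equal(igraph::ecount(net$graph), bf_edges)
  el <- igraph::as_data_frame(net$graph)
  for (i in seq_len(nrow(el))) {
    expect_gte(a[el$from[i], el$to[i]], 0.1)
  }
  net_hi <- build_network(cm, beta = 3, edge_min = 0.4)
  expect_lte(igraph::ecount(net_hi$graph), igraph::ecount(net$graph))
  el_hi <- igraph::as_data_frame(net_hi$graph)
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
  expect_true(all(key(el_hi) %in% key(el)))
})

test_that("network property panel: closed forms and the printed-table identities", {
  # triangle graph
  r <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cm <- structure(list(genes = letters[1:3], r = r,
                       zero_variance = character(0)),
                  class = "correlation_matrix")
  net <- build_network(cm, beta = 1, edge_min = 0.5)
  p <- network_properties(net)
  expect_equal(p$n_nodes, 3); expect_equal(p$n_edges, 3)
  expect_equal(p$average_degree, 2)
  expect_equal(p$diameter, 1)
  expect_equal(p$average_clustering_coefficient, 1)
  expect_equal(p$connections_per_node, 1)
  expect_equal(p$average_degree, 2 * p$connections_per_node)

  # published panel arithmetic: average degree = 2E/N, connections = E/N
  expect_equal(round(average_degree(1183, 94797), 3), 160.265)
  expect_equal(round(average_degree(1385, 181121), 3), 261.547)
  expect_equal(round(average_degree(1386, 186083), 3), 268.518)
  expect_equal(connections_per_node(1183, 94797), 80.132, tolerance = 1e-3)
})

test_that("network properties agree with brute force on a random graph", {
  set.seed(14)
  a <- random_graph_adj(30, 0.15)
  # route the same graph through build_network via a correlation stand-in
  r <- a * 0.9; diag(r) <- 1
  cm <- structure(list(genes = rownames(a), r = r,
                       zero_variance = character(0)),
                  class = "correlation_matrix")
  net <- build_network(cm, beta = 1, edge_min = 0.5)
  p <- network_properties(net)

  keep <- rowSums(a) > 0
  a2 <- a[keep, keep]
  expect_equal(p$n_nodes, nrow(a2))
  expect_equal(p$n_edges, sum(a2) / 2)
  expect_equal(p$average_degree, mean(rowSums(a2)) , tolerance = 1e-12)
  expect_equal(p$average_clustering_coefficient, mean(bf_clustering(a2)),
               tolerance = 1e-12)
  # diameter of the largest component by BFS
  d <- t(vapply(seq_len(nrow(a2)), function(s) bf_bfs_dist(a2, s),
                numeric(nrow(a2))))
  comp <- is.finite(d[1, ])
  sizes <- integer(0); seen <- rep(FALSE, nrow(a2)); diam_bf <- 0
  for (v in seq_len(nrow(a2))) {
    if (!seen[v]) {
      members <- which(is.finite(d[v, ]))
      seen[members] <- TRUE
      sizes <- c(sizes, length(members))
    }
  }
  big <- which.max(sizes)
  cnt <- 0
  for (v in seq_len(nrow(a2))) {
    members <- which(is.finite(d[v, ]))
    if (length(members) == max(sizes)) {
      diam_bf <- max(d[members, members][is.finite(d[members, members])])
      break
    }
  }
  expect_equal(p$diameter, diam_bf)
})

test_that("complete graphs have unit clustering and diameter one", {
  for (n in c(4, 7)) {
    r <- matrix(1, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
    cm <- structure(list(genes = rownames(r), r = r,
                         zero_variance = character(0)),
                    class = "correlation_matrix")
    p <- network_properties(build_network(cm, beta = 1, edge_min = 0.5))
    expect_equal(p$average_clustering_coefficient, 1)
    expect_equal(p$diameter, 1)
  }
})

test_that("synthetic networks are heavier-tailed than Erdos-Renyi matches", {
  run <- cached_default_run(1)
  p_syn <- network_properties(run$res$networks$global)
  wins <- vapply(1:10, function(s) {
    set.seed(100 + s)
    g <- igraph::sample_gnm(p_syn$n_nodes, p_syn$n_edges)
    fit <- saltnet:::scale_free_fit(igraph::degree(g), n_bins = 10)
    is.na(fit$r2) || p_syn$power_law_r2 > fit$r2
  }, logical(1))
  expect_gte(sum(wins), 8)
})
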