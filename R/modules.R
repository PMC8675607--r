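#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j, with `k_i = sum_u a_iu` and unit diagonal; the overlap is high
#' when two genes share many weighted neighbors.  Computed on the full
#' weighted adjacency (pre-thresholding).
#'
#' @param net a [build_network()] result, or a symmetric weighted adjacency
#'   matrix in \[0, 1\] with zero diagonal.
#' @return An object of class `tom_matrix`: `genes`, `tom`, `dissimilarity`
#'   (1 - TOM).
#' @export
topological_overlap <- function(net) {
  a <- if (inherits(net, "coexpression_network")) net$adjacency else as.matrix(net)
  genes <- rownames(a)
  if (is.null(genes)) genes <- if (inherits(net, "coexpression_network"))
    net$genes else as.character(seq_len(nrow(a)))
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- list(genes, genes)
  structure(list(genes = genes, tom = tom, dissimilarity = 1 - tom),
            class = "tom_matrix")
}

# WGCNA-style color palette for size-ordered module labels
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
}

#' Module eigengene (first principal component of a module)
#'
#' The eigengene is the first principal component of the per-gene z-scored
#' member expression across samples, sign-oriented so the mean correlation
#' with member genes is positive, and scaled to unit variance.
#'
#' @param log_expr gene x sample log-expression matrix.
#' @param member_genes character vector of member gene IDs (>= 2).
#' @return Named per-sample numeric vector.
#' @export
module_eigengene <- function(log_expr, member_genes) {
  x <- log_expr[intersect(member_genes, rownames(log_expr)), , drop = FALSE]
  if (nrow(x) < 2L) stop("at least 2 member genes required", call. = FALSE)
  sds <- apply(x, 1, sd)
  x <- x[sds > 0, , drop = FALSE]
  if (nrow(x) == 0L) stop("all member genes are constant", call. = FALSE)
  z <- t(scale(t(x)))
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (mean(cor(e, t(z))) < 0) e <- -e
  e <- as.numeric(scale(e))
  names(e) <- colnames(log_expr)
  e
}

#' Detect co-expression modules from TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on 1 - TOM; branches are obtained
#' by cutting the tree at a fixed dissimilarity (`cut_height`), clusters
#' smaller than `min_module_size` are sent to the reserved "grey" label
#' (genes outside all modules), and modules whose eigengenes correlate above
#' `1 - merge_cut` are merged iteratively, recomputing eigengenes after each
#' merge.  Surviving modules are labelled with color names in decreasing
#' size order.
#'
#' @param tom a [topological_overlap()] result.
#' @param log_expr gene x sample log-expression matrix (used for eigengene
#'   merging and the returned eigengenes); may be `NULL` to skip merging.
#' @param min_module_size smallest allowed module (default 30).
#' @param cut_height static tree-cut dissimilarity (default 0.85).
#' @param merge_cut modules with eigengene correlation > 1 - merge_cut are
#'   merged (default 0.25).
#' @param kme_rescue grey genes whose maximum absolute module membership
#'   (kME, correlation with a module eigengene) reaches this value are
#'   re-assigned to that module; 0 disables the rescue (default 0.50).
#' @return An object of class `module_result`: `assignment` (named gene ->
#'   label, "grey" = unassigned), `module_sizes`, `eigengenes` (module x
#'   sample), `merge_log`, `dendrogram` (the hclust object), `cut_height`.
#' @export
detect_modules <- function(tom, log_expr = NULL, min_module_size = 30,
                           cut_height = 0.85, merge_cut = 0.25,
                           kme_rescue = 0.50) {
  stopifnot(inherits(tom, "tom_matrix"))
  genes <- tom$genes
  if (length(genes) < min_module_size) {
    stop("fewer genes than min_module_size", call. = FALSE)
  }
  hc <- hclust(as.dist(tom$dissimilarity), method = "average")
  # tied dissimilarities can leave heights non-monotone within fp noise
  hc$height <- cummax(hc$height)
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  cl[cl %in% small] <- 0L  # grey
  merge_log <- character(0)

  if (!is.null(log_expr)) {
    repeat {
      labs <- setdiff(unique(cl), 0L)
      if (length(labs) < 2L) break
      eg <- sapply(labs, function(l) module_eigengene(log_expr, genes[cl == l]))
      cm <- cor(eg)
      diag(cm) <- -Inf
      top <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
      if (max(cm) <= 1 - merge_cut) break
      a <- labs[top[1L]]; b <- labs[top[2L]]
      cl[cl == b] <- a
      merge_log <- c(merge_log,
                     sprintf("merged cluster %d into %d (eigengene r = %.3f)",
                             b, a, max(cm)))
    }
  }

  labs <- setdiff(unique(cl), 0L)
  ord <- labs[order(-tabulate(match(cl, labs), nbins = length(labs)))]
  palette <- module_palette()
  if (length(ord) > length(palette)) {
    palette <- c(palette, sprintf("module%03d", seq_len(length(ord))))
  }
  new_lab <- setNames(palette[seq_along(ord)], ord)
  assignment <- setNames(rep("grey", length(genes)), genes)
  for (l in ord) assignment[cl == l] <- new_lab[as.character(l)]

  non_grey <- setdiff(unique(assignment), "grey")
  eigengenes <- NULL
  if (!is.null(log_expr) && length(non_grey)) {
    eigengenes <- t(sapply(non_grey, function(m)
      module_eigengene(log_expr, names(assignment)[assignment == m])))
    # kME rescue: grey genes strongly correlated with a module eigengene
    # are assigned to that module (unsigned module membership)
    grey_genes <- names(assignment)[assignment == "grey"]
    grey_genes <- intersect(grey_genes, rownames(log_expr))
    if (kme_rescue > 0 && length(grey_genes)) {
      kme <- abs(suppressWarnings(
        cor(t(log_expr[grey_genes, , drop = FALSE]), t(eigengenes))))
      kme[is.na(kme)] <- 0
      best <- apply(kme, 1, which.max)
      hit <- kme[cbind(seq_along(best), best)] >= kme_rescue
      assignment[grey_genes[hit]] <- rownames(eigengenes)[best[hit]]
      if (any(hit)) {
        eigengenes <- t(sapply(non_grey, function(m)
          module_eigengene(log_expr, names(assignment)[assignment == m])))
      }
    }
  }
  if (length(non_grey) == 0L) warning("no module passed min_module_size; all genes grey")
  structure(list(
    assignment = assignment,
    module_sizes = sort(table(assignment[assignment != "grey"]),
                        decreasing = TRUE),
    eigengenes = eigengenes,
    merge_log = merge_log,
    dendrogram = hc,
    cut_height = cut_height
  ), class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  cat(sprintf("module_result: %d modules, %d genes grey of %d\n",
              length(x$module_sizes), sum(x$assignment == "grey"),
              length(x$assignment)))
  print(x$module_sizes)
  invisible(x)
}

#' Salt time-point trait indicators
#'
#' One indicator per time point: 1 for stress-condition samples at that
#' time, 0 for every other sample (controls included as 0); optionally
#' restricted to stress samples only.
#'
#' @param design per-sample design data frame.
#' @param stress_label condition label of the stress state; defaults to the
#'   second condition level in order of appearance.
#' @param include_controls keep control samples (as 0) in the trait vectors.
#' @return trait x sample 0/1 matrix (rownames like `"salt_12h"`).
#' @export
time_point_traits <- function(design, stress_label = NULL,
                              include_controls = TRUE) {
  conds <- unique(design$condition)
  if (is.null(stress_label)) stress_label <- conds[length(conds)]
  keep <- if (include_controls) rep(TRUE, nrow(design))
          else design$condition == stress_label
  tps <- sort(unique(design$time_h))
  tr <- t(sapply(tps, function(t)
    as.numeric(design$condition == stress_label & design$time_h == t)[keep]))
  dimnames(tr) <- list(sprintf("%s_%gh", stress_label, tps),
                       design$sample[keep])
  tr
}

#' Module-trait relationships
#'
#' Pearson correlation of each module eigengene with each trait vector, with
#' a two-sided p-value from the t distribution with n - 2 degrees of
#' freedom.  A module-trait pair is significant when |r| > `r_cut` and
#' p < `p_cut`.
#'
#' @param eigengenes module x sample matrix (from [detect_modules()]).
#' @param traits trait x sample numeric matrix (e.g. [time_point_traits()]).
#' @param r_cut,p_cut significance thresholds (defaults 0.50 and 0.05).
#' @return A data frame (class `mtr_table`) with columns `module`, `trait`,
#'   `r`, `p`, `significant`; constant traits give NA rows.
#' @export
module_trait_relationships <- function(eigengenes, traits, r_cut = 0.50,
                                       p_cut = 0.05) {
  common <- intersect(colnames(eigengenes), colnames(traits))
  if (length(common) < 3L) stop("traits and eigengenes must share >= 3 samples",
                                call. = FALSE)
  eg <- eigengenes[, common, drop = FALSE]
  tr <- traits[, common, drop = FALSE]
  n <- length(common)
  rows <- list()
  for (m in rownames(eg)) for (t in rownames(tr)) {
    if (sd(tr[t, ]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = t, r = NA_real_, p = NA_real_, significant = NA)
      next
    }
    r <- cor(eg[m, ], tr[t, ])
    r2 <- min(r^2, 1 - 1e-15)
    tstat <- r * sqrt(n - 2) / sqrt(1 - r2)
    p <- 2 * pt(-abs(tstat), df = n - 2)
    rows[[length(rows) + 1L]] <- data.frame(
      module = m, trait = t, r = r, p = p,
      significant = abs(r) > r_cut & p < p_cut)
  }
  res <- do.call(rbind, rows)
  class(res) <- c("mtr_table", "data.frame")
  attr(res, "r_cut") <- r_cut
  attr(res, "p_cut") <- p_cut
  res
}

#' Modules significantly related to at least one trait
#'
#' @param mtr an [module_trait_relationships()] table.
#' @return Character vector of module labels.
#' @export
significant_modules <- function(mtr) {
  unique(mtr$module[!is.na(mtr$significant) & mtr$significant])
}
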