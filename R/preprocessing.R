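#' Remove genes with too many zero counts
#'
#' Drops genes whose fraction of zero-count samples strictly exceeds
#' `zero_fraction` (default 0.8: a gene observed in fewer than 20% of
#' libraries is considered unreliable).  Sample set and surviving gene order
#' are unchanged.
#'
#' @param data a [count_dataset()].
#' @param zero_fraction maximum tolerated fraction of zero-count samples,
#'   in (0, 1].
#' @return A filtered `count_dataset`.
#' @export
filter_low_expression <- function(data, zero_fraction = 0.8) {
  stopifnot(inherits(data, "count_dataset"))
  if (zero_fraction <= 0 || zero_fraction > 1) {
    stop("zero_fraction must lie in (0, 1]", call. = FALSE)
  }
  frac0 <- rowMeans(data$counts == 0)
  keep <- frac0 <= zero_fraction
  if (!any(keep)) warning("all genes removed by the zero-count filter")
  count_dataset(data$counts[keep, , drop = FALSE], data$design)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' `count / geometric mean of that gene across samples`.  Genes with any
#' zero count are excluded from the reference set.
#'
#' @param data a [count_dataset()] or a count matrix.
#' @return Named numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(data) {
  counts <- if (inherits(data, "count_dataset")) data$counts else as.matrix(data)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    stop("no gene with all-positive counts; filter low-expression genes ",
         "or add a pseudo-count before computing size factors",
         call. = FALSE)
  }
  refc <- counts[ref, , drop = FALSE]
  geomean <- exp(rowMeans(log(refc)))
  sf <- apply(refc / geomean, 2, median)
  names(sf) <- colnames(counts)
  sf
}

#' Normalize counts by size factors
#'
#' @param data a [count_dataset()].
#' @param factors positive per-sample size factors; computed by
#'   [size_factors()] when missing.
#' @return An object of class `normalized_dataset` with fields
#'   `size_factors`, `normalized` (count / factor), `log_expression`
#'   (log2(normalized + 1)), `counts` and `design`.
#' @export
normalize_counts <- function(data, factors = NULL) {
  stopifnot(inherits(data, "count_dataset"))
  if (is.null(factors)) factors <- size_factors(data)
  if (length(factors) != ncol(data$counts)) {
    stop("one size factor per sample is required", call. = FALSE)
  }
  if (any(factors <= 0)) stop("size factors must be positive", call. = FALSE)
  normalized <- sweep(data$counts, 2, factors, "/")
  structure(list(
    size_factors = setNames(as.numeric(factors), colnames(data$counts)),
    normalized = normalized,
    log_expression = log2(normalized + 1),
    counts = data$counts,
    design = data$design
  ), class = "normalized_dataset")
}

#' Negative-binomial Wald screen for differential expression
#'
#' Fits, per gene, an NB generalized linear model of the raw counts on the
#' condition label with log size factors as offsets.  The dispersion is a
#' per-gene method-of-moments estimate on normalized counts,
#' `max((var - mean) / mean^2, 1e-8)`.  The Wald statistic is the condition
#' coefficient divided by its standard error, with a two-sided p-value from
#' the standard normal.  Genes with all-zero counts get p = 1 by convention.
#'
#' @param norm a [normalize_counts()] result.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param dispersion_floor lower bound for the dispersion estimate.
#' @return A data frame (class `de_result`) with columns `gene`, `log2fc`
#'   (stress vs. control), `stat`, `pvalue`, `significant`.
#' @export
wald_de_screen <- function(norm, alpha = 0.05, dispersion_floor = 1e-8) {
  stopifnot(inherits(norm, "normalized_dataset"))
  cond <- factor(norm$design$condition)
  if (nlevels(cond) != 2L || any(table(cond) < 2L)) {
    stop("both condition labels must be present with at least 2 samples each",
         call. = FALSE)
  }
  off <- log(norm$size_factors)
  x <- as.numeric(cond) - 1  # 0 = reference (first level), 1 = stress
  genes <- rownames(norm$counts)
  n_g <- length(genes)
  lfc <- stat <- numeric(n_g)
  pval <- rep(1, n_g)
  for (g in seq_len(n_g)) {
    y <- norm$counts[g, ]
    if (all(y == 0)) next
    nrm <- norm$normalized[g, ]
    m <- mean(nrm); v <- var(nrm)
    disp <- max((v - m) / m^2, dispersion_floor)
    fit <- tryCatch(
      suppressWarnings(glm(y ~ x, offset = off,
                           family = MASS::negative.binomial(theta = 1 / disp))),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    # dispersion fixed at 1: the NB variance is carried by theta, so the
    # covariance must not be rescaled by the Pearson statistic
    sm <- suppressWarnings(summary(fit, dispersion = 1)$coefficients)
    if (!"x" %in% rownames(sm)) next
    b <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
    if (!is.finite(b) || !is.finite(se) || se <= 0) next
    lfc[g] <- b / log(2)
    stat[g] <- b / se
    pval[g] <- 2 * pnorm(-abs(stat[g]))
  }
  res <- data.frame(gene = genes, log2fc = lfc, stat = stat, pvalue = pval,
                    significant = pval < alpha, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  attr(res, "alpha") <- alpha
  res
}
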