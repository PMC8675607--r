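#' Annotation map for term enrichment
#'
#' @param term_genes named list: term -> character vector of genes.
#' @param universe background gene universe; annotated genes outside it are
#'   dropped with a warning.
#' @param namespace optional named character vector of term namespaces.
#' @return An object of class `annotation_map`.
#' @export
annotation_map <- function(term_genes, universe, namespace = NULL) {
  universe <- unique(as.character(universe))
  cleaned <- lapply(term_genes, function(g) intersect(unique(g), universe))
  if (any(vapply(term_genes,
                 function(g) length(setdiff(g, universe)) > 0, NA))) {
    warning("annotated genes outside the universe were dropped")
  }
  structure(list(term_genes = cleaned, universe = universe,
                 namespace = namespace),
            class = "annotation_map")
}

#' Read a two-column (gene, term) TSV or a GMT file as an annotation map
#'
#' @param path annotation file.
#' @param universe background gene universe.
#' @param format `"tsv"` (columns gene, term; header optional) or `"gmt"`
#'   (term, description, genes...).
#' @return An [annotation_map()].
#' @export
read_annotation <- function(path, universe, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t")
    term_genes <- setNames(lapply(parts, function(p) p[-(1:2)]),
                           vapply(parts, `[[`, "", 1L))
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(as.character(tab[1, 1])), "gene")) {
      tab <- tab[-1, , drop = FALSE]
    }
    term_genes <- split(as.character(tab[[1]]), as.character(tab[[2]]))
  }
  annotation_map(term_genes, universe)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} (m / j) p_(j)`, capped at 1, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Fisher-exact (hypergeometric) term over-representation test
#'
#' For each term, the one-sided over-representation p-value is the
#' hypergeometric upper tail `P(X >= k)` for k query genes among the K term
#' genes, drawing n from a universe of N.  Benjamini-Hochberg q-values are
#' computed across all tested terms; a term is significant at
#' `q < q_cut` (terms with K < 2 or k = 0 are reported but never flagged).
#'
#' @param query character vector of query genes; genes outside the universe
#'   are dropped with a warning.
#' @param annotation an [annotation_map()].
#' @param q_cut significance threshold on the BH q-value (default 0.05).
#' @return A data frame (class `enrichment_result`) sorted by q then p with
#'   columns `term`, `k`, `K`, `n`, `N`, `odds_ratio`, `p`, `q`,
#'   `significant`.
#' @export
fisher_enrichment <- function(query, annotation, q_cut = 0.05) {
  stopifnot(inherits(annotation, "annotation_map"))
  query <- unique(as.character(query))
  outside <- setdiff(query, annotation$universe)
  if (length(outside)) {
    warning(length(outside), " query genes outside the universe dropped")
    query <- setdiff(query, outside)
  }
  terms <- names(annotation$term_genes)
  if (length(query) == 0L || length(terms) == 0L) {
    res <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0))
    class(res) <- c("enrichment_result", "data.frame")
    return(res)
  }
  N <- length(annotation$universe)
  n <- length(query)
  K <- vapply(annotation$term_genes, length, 0L)
  k <- vapply(annotation$term_genes,
              function(g) length(intersect(g, query)), 0L)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  or <- (k * (N - K - n + k)) / pmax((K - k) * (n - k), .Machine$double.eps)
  q <- benjamini_hochberg(p)
  res <- data.frame(term = terms, k = k, K = K, n = n, N = N,
                    odds_ratio = or, p = p, q = q,
                    significant = q < q_cut & K >= 2 & k > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$q, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "q_cut") <- q_cut
  res
}
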