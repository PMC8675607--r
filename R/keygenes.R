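#' Identify key genes gaining network importance under stress
#'
#' Within each module and for each centrality measure (DG, BW, CN, CC),
#' percentile ranks are computed over the module's genes separately in the
#' normal-state and the stress-state network.  A gene is flagged for a
#' measure when it is of low importance in the normal state
#' (`normal percentile <= normal_max_percentile`) but of high importance in
#' the stress state
#' (`stress percentile >= 1 - salinity_top_fraction`).  Genes absent from a
#' state's graph are treated as percentile 0 in that state.
#'
#' @param normal,salinity [centrality_table()]s of the two state networks.
#' @param modules a [detect_modules()] result (or a named gene -> module
#'   vector).
#' @param keep_modules modules to examine; default all non-grey modules.
#' @param salinity_top_fraction top fraction in the stress network counted
#'   as high importance (default 0.10).
#' @param normal_max_percentile maximum normal-state percentile counted as
#'   low importance (default 0.50).
#' @return An object of class `key_gene_report`: `table` (flagged rows:
#'   gene, module, measure, per-state value and percentile), `summary`
#'   (per gene: detecting measures, `multi_measure` flag), `percentiles`
#'   (all examined rows), `thresholds`.
#' @export
identify_key_genes <- function(normal, salinity, modules,
                               keep_modules = NULL,
                               salinity_top_fraction = 0.10,
                               normal_max_percentile = 0.50) {
  assignment <- if (inherits(modules, "module_result")) modules$assignment
                else modules
  if (is.null(keep_modules)) {
    keep_modules <- setdiff(unique(assignment), "grey")
  }
  measures <- c("DG", "BW", "CN", "CC")
  all_rows <- list()
  for (mod in keep_modules) {
    mod_genes <- names(assignment)[assignment == mod]
    if (length(mod_genes) == 0L) next
    in_norm <- mod_genes %in% normal$gene
    in_sal <- mod_genes %in% salinity$gene
    if (!any(in_norm)) warning("module ", mod,
                               " absent from the normal-state network")
    if (!any(in_sal)) warning("module ", mod,
                              " absent from the salinity-state network")
    for (meas in measures) {
      nv <- setNames(rep(NA_real_, length(mod_genes)), mod_genes)
      sv <- nv
      nv[in_norm] <- normal[[meas]][match(mod_genes[in_norm], normal$gene)]
      sv[in_sal] <- salinity[[meas]][match(mod_genes[in_sal], salinity$gene)]
      np <- setNames(rep(0, length(mod_genes)), mod_genes)
      sp <- np
      if (any(in_norm)) np[in_norm] <- percentile_rank(nv[in_norm])
      if (any(in_sal)) sp[in_sal] <- percentile_rank(sv[in_sal])
      all_rows[[length(all_rows) + 1L]] <- data.frame(
        gene = mod_genes, module = mod, measure = meas,
        normal_value = as.numeric(nv), salinity_value = as.numeric(sv),
        normal_pct = as.numeric(np), salinity_pct = as.numeric(sp),
        flagged = sp >= 1 - salinity_top_fraction & np <= normal_max_percentile,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  percentiles <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(gene = character(0), module = character(0),
               measure = character(0), normal_value = numeric(0),
               salinity_value = numeric(0), normal_pct = numeric(0),
               salinity_pct = numeric(0), flagged = logical(0))
  tab <- percentiles[percentiles$flagged, , drop = FALSE]
  tab <- tab[order(tab$module, tab$gene, tab$measure), , drop = FALSE]
  rownames(tab) <- NULL

  summ <- if (nrow(tab)) {
    sp <- split(tab$measure, tab$gene)
    data.frame(
      gene = names(sp),
      module = assignment[names(sp)],
      measures = vapply(sp, function(m) paste(sort(unique(m)),
                                              collapse = ","), ""),
      n_measures = vapply(sp, function(m) length(unique(m)), 0L),
      multi_measure = vapply(sp, function(m) length(unique(m)) >= 2L, NA),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(gene = character(0), module = character(0),
               measures = character(0), n_measures = integer(0),
               multi_measure = logical(0))
  }
  structure(list(
    table = tab, summary = summ, percentiles = percentiles,
    thresholds = list(salinity_top_fraction = salinity_top_fraction,
                      normal_max_percentile = normal_max_percentile)
  ), class = "key_gene_report")
}

#' @export
print.key_gene_report <- function(x, ...) {
  cat(sprintf("key_gene_report: %d genes flagged (%d multi-measure) across %d modules\n",
              nrow(x$summary), sum(x$summary$multi_measure),
              length(unique(x$summary$module))))
  invisible(x)
}

#' Summarize a key-gene report
#'
#' @param report a [identify_key_genes()] result.
#' @return A list with `counts` (module x measure flag counts),
#'   `genes_per_module`, `multi_measure_genes`, `n_key_genes`.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "key_gene_report"))
  tab <- report$table
  measures <- c("DG", "BW", "CN", "CC")
  mods <- unique(tab$module)
  counts <- matrix(0L, length(mods), length(measures),
                   dimnames = list(mods, measures))
  for (i in seq_len(nrow(tab))) {
    counts[tab$module[i], tab$measure[i]] <-
      counts[tab$module[i], tab$measure[i]] + 1L
  }
  list(
    counts = counts,
    genes_per_module = vapply(split(report$summary$gene,
                                    report$summary$module), length, 0L),
    multi_measure_genes = report$summary$gene[report$summary$multi_measure],
    n_key_genes = nrow(report$summary)
  )
}
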