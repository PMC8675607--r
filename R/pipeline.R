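#' Analysis configuration with the study defaults
#'
#' Aggregates every stage parameter: zero-count filter at 0.8, DE screen at
#' raw p < 0.05, soft-threshold scan over powers 1..20 with fit threshold
#' 0.90, edge weight cut 0.1 (inclusive), minimum module size 30, MTR cuts
#' |r| > 0.50 and p < 0.05, key-gene percentile thresholds, enrichment
#' q < 0.05.
#'
#' @param zero_fraction,de_alpha,powers,fit_threshold,edge_min,n_bins
#'   stage parameters (see the stage functions).
#' @param min_module_size,cut_height,merge_cut module-detection parameters.
#' @param mtr_r_cut,mtr_p_cut,include_controls_in_traits MTR parameters.
#' @param salinity_top_fraction,normal_max_percentile key-gene thresholds.
#' @param enrichment_q_cut enrichment significance threshold.
#' @param seed integer seed (used only when the pipeline simulates input).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(zero_fraction = 0.8, de_alpha = 0.05,
                            powers = 1:20, fit_threshold = 0.90,
                            edge_min = 0.1, n_bins = 10,
                            min_module_size = 30, cut_height = 0.85,
                            merge_cut = 0.25, kme_rescue = 0.50,
                            mtr_r_cut = 0.50,
                            mtr_p_cut = 0.05,
                            include_controls_in_traits = TRUE,
                            salinity_top_fraction = 0.10,
                            normal_max_percentile = 0.50,
                            enrichment_q_cut = 0.05, seed = 1L) {
  structure(list(
    zero_fraction = zero_fraction, de_alpha = de_alpha,
    powers = as.integer(powers), fit_threshold = fit_threshold,
    edge_min = edge_min, n_bins = as.integer(n_bins),
    min_module_size = as.integer(min_module_size), cut_height = cut_height,
    merge_cut = merge_cut, kme_rescue = kme_rescue,
    mtr_r_cut = mtr_r_cut, mtr_p_cut = mtr_p_cut,
    include_controls_in_traits = include_controls_in_traits,
    salinity_top_fraction = salinity_top_fraction,
    normal_max_percentile = normal_max_percentile,
    enrichment_q_cut = enrichment_q_cut, seed = as.integer(seed)
  ), class = "analysis_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full two-state co-expression analysis
#'
#' Executes, in order: zero-count filtering, median-of-ratios normalization,
#' the NB Wald DE screen, the soft-threshold scan on the global correlation
#' matrix of DE genes, construction of the global / normal-state /
#' salinity-state networks (one power, chosen on the global network),
#' TOM-based module detection with eigengene merging, module-trait
#' relationships against time-point indicators, per-state centrality
#' tables, key-gene identification, optional term enrichment per module,
#' and -- when a ground truth is supplied -- recovery metrics (module
#' adjusted Rand index, key-gene precision/recall, DE screen
#' precision/recall).
#'
#' @param data a [count_dataset()].
#' @param config an [analysis_config()].
#' @param annotation optional [annotation_map()] for per-module enrichment.
#' @param truth optional `synthetic_truth` for recovery metrics.
#' @param output_dir optional directory; when given, all stage outputs are
#'   written as TSV/JSON, each carrying the config hash.
#' @param key_gene_modules modules passed to [identify_key_genes()];
#'   `"significant"` (MTR-selected, the study rule) or `"all"` (every
#'   non-grey module).
#' @return A list of class `pipeline_result` with all stage objects and a
#'   `report` (the run summary: per-stage counts, three network property
#'   panels, chosen power, recovery metrics, config hash and seed).
#' @export
run_pipeline <- function(data, config = analysis_config(),
                         annotation = NULL, truth = NULL,
                         output_dir = NULL,
                         key_gene_modules = c("significant", "all")) {
  stopifnot(inherits(data, "count_dataset"))
  key_gene_modules <- match.arg(key_gene_modules)
  stage <- "filter"
  result <- tryCatch({
    filtered <- filter_low_expression(data, config$zero_fraction)
    stage <- "normalize"
    norm <- normalize_counts(filtered)
    stage <- "de_screen"
    de <- wald_de_screen(norm, alpha = config$de_alpha)
    de_genes <- de$gene[de$significant]
    if (length(de_genes) < config$min_module_size) {
      stop("fewer DE genes than min_module_size; nothing to network")
    }
    conds <- unique(norm$design$condition)
    stress <- conds[length(conds)]
    le <- norm$log_expression[de_genes, , drop = FALSE]
    ctrl_s <- norm$design$sample[norm$design$condition != stress]
    strs_s <- norm$design$sample[norm$design$condition == stress]

    stage <- "soft_threshold"
    cor_global <- correlation_matrix(le)
    scan <- soft_threshold_scan(cor_global, powers = config$powers,
                                fit_threshold = config$fit_threshold,
                                n_bins = config$n_bins)
    beta <- pick_power(scan, n_samples = ncol(le))

    stage <- "networks"
    net_global <- build_network(cor_global, beta, config$edge_min, "global")
    net_normal <- build_network(correlation_matrix(le[, ctrl_s, drop = FALSE]),
                                beta, config$edge_min, "normal")
    net_salinity <- build_network(correlation_matrix(le[, strs_s, drop = FALSE]),
                                  beta, config$edge_min, "salinity")
    props <- lapply(list(global = net_global, normal = net_normal,
                         salinity = net_salinity),
                    network_properties, n_bins = config$n_bins)

    stage <- "modules"
    tom <- topological_overlap(net_global)
    modules <- detect_modules(tom, le,
                              min_module_size = config$min_module_size,
                              cut_height = config$cut_height,
                              merge_cut = config$merge_cut,
                              kme_rescue = config$kme_rescue)
    mtr <- NULL
    sig_mods <- character(0)
    if (!is.null(modules$eigengenes)) {
      traits <- time_point_traits(norm$design, stress_label = stress,
                                  include_controls =
                                    config$include_controls_in_traits)
      mtr <- module_trait_relationships(modules$eigengenes, traits,
                                        r_cut = config$mtr_r_cut,
                                        p_cut = config$mtr_p_cut)
      sig_mods <- significant_modules(mtr)
    }

    stage <- "centrality"
    cent_normal <- centrality_table(net_normal)
    cent_salinity <- centrality_table(net_salinity)

    stage <- "key_genes"
    keep <- if (key_gene_modules == "significant") sig_mods else NULL
    keygenes <- identify_key_genes(
      cent_normal, cent_salinity, modules, keep_modules = keep,
      salinity_top_fraction = config$salinity_top_fraction,
      normal_max_percentile = config$normal_max_percentile)

    stage <- "enrichment"
    enrich <- NULL
    if (!is.null(annotation)) {
      mods <- setdiff(unique(modules$assignment), "grey")
      enrich <- lapply(setNames(mods, mods), function(m)
        fisher_enrichment(names(modules$assignment)[modules$assignment == m],
                          annotation, q_cut = config$enrichment_q_cut))
    }

    stage <- "recovery"
    recovery <- NULL
    if (!is.null(truth)) {
      recovery <- recovery_metrics(modules, keygenes, de, truth)
    }

    list(filtered = filtered, normalized = norm, de = de,
         scan = scan, beta = beta,
         networks = list(global = net_global, normal = net_normal,
                         salinity = net_salinity),
         properties = props, tom = tom, modules = modules, mtr = mtr,
         significant_modules = sig_mods,
         centrality = list(normal = cent_normal, salinity = cent_salinity),
         key_genes = keygenes, enrichment = enrich, recovery = recovery)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  report <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_samples = ncol(data$counts),
    genes_in = nrow(data$counts),
    genes_after_filter = nrow(result$filtered$counts),
    n_de_genes = length(result$de$gene[result$de$significant]),
    chosen_beta = result$beta,
    networks = lapply(result$properties, function(p)
      list(n_nodes = p$n_nodes, n_edges = p$n_edges,
           average_degree = p$average_degree, diameter = p$diameter,
           average_clustering_coefficient = p$average_clustering_coefficient,
           connections_per_node = p$connections_per_node,
           power_law_slope = p$power_law_slope,
           power_law_r2 = p$power_law_r2)),
    n_modules = length(result$modules$module_sizes),
    module_sizes = as.list(result$modules$module_sizes),
    significant_modules = result$significant_modules,
    n_key_genes = nrow(result$key_genes$summary),
    recovery = result$recovery
  )
  result$report <- report
  result$config <- config
  class(result) <- "pipeline_result"
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

#' Recovery metrics against a synthetic ground truth
#'
#' @param modules a [detect_modules()] result.
#' @param keygenes an [identify_key_genes()] result.
#' @param de a [wald_de_screen()] result.
#' @param truth a `synthetic_truth`.
#' @return A list with `module_ari`, `keygene_precision`, `keygene_recall`,
#'   `de_precision`, `de_recall`.
#' @export
recovery_metrics <- function(modules, keygenes, de, truth) {
  assignment <- modules$assignment
  true_lab <- truth$module_membership[names(assignment)]
  ari <- mclust::adjustedRandIndex(assignment, true_lab)
  flagged <- unique(keygenes$summary$gene)
  truthkey <- truth$key_genes
  prec <- if (length(flagged)) length(intersect(flagged, truthkey)) /
    length(flagged) else NA_real_
  rec <- if (length(truthkey)) length(intersect(flagged, truthkey)) /
    length(truthkey) else NA_real_
  de_called <- de$gene[de$significant]
  de_prec <- if (length(de_called)) length(intersect(de_called, truth$de_genes)) /
    length(de_called) else NA_real_
  de_rec <- if (length(truth$de_genes)) length(intersect(de_called, truth$de_genes)) /
    length(truth$de_genes) else NA_real_
  list(module_ari = ari, keygene_precision = prec, keygene_recall = rec,
       de_precision = de_prec, de_recall = de_rec)
}

#' Write all stage outputs of a pipeline run
#'
#' @param result a [run_pipeline()] result.
#' @param output_dir destination directory (created if missing).
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, output_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- result$report$config_hash
  w <- function(df, name) {
    path <- file.path(output_dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# config_hash: %s", hash), con)
    close(con)
    suppressWarnings(
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  append = TRUE))
    path
  }
  w(result$de, "de_table.tsv")
  w(result$scan$scan, "soft_threshold_scan.tsv")
  for (nm in names(result$networks)) {
    net <- result$networks[[nm]]
    el <- igraph::as_data_frame(net$graph, what = "edges")
    names(el) <- c("gene_a", "gene_b", "weight")
    w(el, sprintf("edges_%s.tsv", nm))
    w(data.frame(gene = igraph::V(net$graph)$name),
      sprintf("nodes_%s.tsv", nm))
  }
  w(data.frame(gene = names(result$modules$assignment),
               module = unname(result$modules$assignment)),
    "module_assignment.tsv")
  if (!is.null(result$modules$eigengenes)) {
    w(data.frame(module = rownames(result$modules$eigengenes),
                 result$modules$eigengenes, check.names = FALSE),
      "eigengenes.tsv")
  }
  if (!is.null(result$mtr)) w(result$mtr, "mtr_table.tsv")
  for (nm in names(result$centrality)) {
    w(result$centrality[[nm]], sprintf("centrality_%s.tsv", nm))
  }
  w(result$key_genes$table, "key_genes.tsv")
  if (!is.null(result$enrichment)) {
    for (m in names(result$enrichment)) {
      w(result$enrichment[[m]], sprintf("enrichment_%s.tsv", m))
    }
  }
  jsonlite::write_json(
    c(result$report, list(config = unclass(result$config))),
    file.path(output_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("pipeline_result: %d samples, %d -> %d genes, %d DE, beta=%d\n",
              r$n_samples, r$genes_in, r$genes_after_filter, r$n_de_genes,
              r$chosen_beta))
  cat(sprintf("  modules: %d (%s significant), key genes: %d\n",
              r$n_modules, length(r$significant_modules), r$n_key_genes))
  invisible(x)
}
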