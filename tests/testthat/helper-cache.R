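# Full pipeline runs on the default synthetic dataset are expensive;
# several test files share them through this per-session cache.
.run_cache <- new.env(parent = emptyenv())

cached_default_run <- function(seed) {
  key <- paste0("run", seed)
  if (is.null(.run_cache[[key]])) {
    sim <- generate_dataset(sim_config(seed = seed))
    res <- run_pipeline(sim$dataset, analysis_config(seed = seed),
                        truth = sim$truth, key_gene_modules = "all")
    .run_cache[[key]] <- list(sim = sim, res = res)
  }
  .run_cache[[key]]
}
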