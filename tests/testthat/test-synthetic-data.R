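test_that("default design yields 36 libraries and an internally consistent truth", {
  sim <- generate_dataset(sim_config(seed = 11))
  d <- sim$dataset; tr <- sim$truth
  expect_equal(ncol(d$counts), 36L)
  expect_equal(nrow(d$design), 36L)
  expect_setequal(unique(d$design$condition), c("control", "salt"))
  expect_true(all(d$counts >= 0), info = "counts non-negative")
  expect_true(all(d$counts == round(d$counts)))
  # gene budget and truth invariants
  planted <- names(tr$module_membership)[tr$module_membership != "none"]
  expect_equal(length(tr$module_membership), 1000L)
  expect_equal(length(planted) + 700L, 1000L)
  expect_true(all(tr$key_genes %in% planted))
  expect_true(all(tr$size_factors > 0))
  expect_setequal(tr$de_genes, planted)
})

test_that("sample count follows the design for arbitrary configs", {
  for (cfg in list(
    sim_config(n_genes = 80, module_sizes = c(20, 20), n_key_genes_per_module = 3,
               timepoints_h = c(0, 24), n_replicates = 2, seed = 1),
    sim_config(n_genes = 60, module_sizes = 30, n_key_genes_per_module = 4,
               timepoints_h = c(0, 6, 12), n_replicates = 4, seed = 2)
  )) {
    sim <- generate_dataset(cfg)
    expect_equal(ncol(sim$dataset$counts),
                 2L * length(cfg$timepoints_h) * cfg$n_replicates)
  }
  expect_error(sim_config(n_genes = 100, module_sizes = c(60, 60)),
               "gene budget")
})

test_that("the same seed reproduces the dataset exactly", {
  a <- generate_dataset(sim_config(seed = 42))
  b <- generate_dataset(sim_config(seed = 42))
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$truth$key_genes, b$truth$key_genes)
  c <- generate_dataset(sim_config(seed = 43))
  expect_false(identical(a$dataset$counts, c$dataset$counts))
})

test_that("module genes out-correlate null genes in stress samples", {
  cfg <- sim_config(seed = 5, within_module_loading = 0.9,
                    nb_dispersion = 0.05)
  sim <- generate_dataset(cfg)
  norm <- normalize_counts(sim$dataset)
  salt <- norm$design$sample[norm$design$condition == "salt"]
  mm <- sim$truth$module_membership
  mod1 <- names(mm)[mm == "module_1"]
  null <- names(mm)[mm == "none"][1:50]
  le <- norm$log_expression
  within_r <- cor(t(le[mod1, salt]))
  cross_r <- cor(t(le[mod1, salt]), t(le[null, salt]))
  expect_gt(mean(within_r[upper.tri(within_r)]), mean(cross_r))
})

test_that("with zero loading, within-module correlations look null", {
  # loading and condition effects both off: isolates the co-expression
  # mechanism (the condition main effect would correlate module genes
  # regardless of loading)
  rejections <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 120, module_sizes = c(30, 30),
                      n_key_genes_per_module = 0, within_module_loading = 1e-6,
                      de_effect_log2fc = 0, key_de_log2fc = 0, seed = s)
    sim <- generate_dataset(cfg)
    le <- normalize_counts(sim$dataset)$log_expression
    mm <- sim$truth$module_membership
    mod <- names(mm)[mm == "module_1"]
    null <- names(mm)[mm == "none"]
    rw <- abs(cor(t(le[mod, ]))[upper.tri(diag(length(mod)))])
    rn <- abs(cor(t(le[null, ]))[upper.tri(diag(length(null)))])
    suppressWarnings(stats::ks.test(rw, rn)$p.value) < 0.01
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)
})

test_that("key genes couple to their module only under stress", {
  sim <- generate_dataset(sim_config(seed = 9))
  norm <- normalize_counts(sim$dataset)
  le <- norm$log_expression
  salt <- norm$design$sample[norm$design$condition == "salt"]
  ctrl <- norm$design$sample[norm$design$condition == "control"]
  mm <- sim$truth$module_membership
  deltas <- vapply(sim$truth$key_genes, function(k) {
    ord <- setdiff(names(mm)[mm == mm[k]], sim$truth$key_genes)
    proxy_s <- colMeans(le[ord, salt])   # module factor proxy
    proxy_c <- colMeans(le[ord, ctrl])
    abs(cor(le[k, salt], proxy_s)) - abs(cor(le[k, ctrl], proxy_c))
  }, numeric(1))
  expect_gt(mean(deltas > 0), 0.95)
  expect_gt(mean(deltas), 0.3)
})

test_that("sample totals track the planted size factors", {
  # with expression effects silenced, per-sample totals are driven by the
  # library-size factors alone; under the full defaults the planted module
  # factors add genuine biological variation to the totals
  cfg0 <- sim_config(seed = 4, de_effect_log2fc = 0, key_de_log2fc = 0,
                     activity_amplitude = 0, within_module_loading = 0.05)
  sim0 <- generate_dataset(cfg0)
  expect_gt(cor(colSums(sim0$dataset$counts), sim0$truth$size_factors,
                method = "spearman"), 0.9)
})

test_that("truth round-trips losslessly through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  sim <- generate_dataset(sim_config(seed = 2))
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$module_membership, sim$truth$module_membership)
  expect_equal(back$key_genes, sim$truth$key_genes)
  expect_equal(back$de_genes, sim$truth$de_genes)
  expect_equal(back$size_factors, sim$truth$size_factors)
  expect_equal(unclass(back$config_echo), unclass(sim$truth$config_echo))
})

test_that("an empty key-gene set round-trips as an empty set", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- sim_config(n_genes = 80, module_sizes = c(30, 30),
                    n_key_genes_per_module = 0, seed = 1)
  sim <- generate_dataset(cfg)
  expect_length(sim$truth$key_genes, 0)
  write_truth(sim$truth, path)
  expect_identical(read_truth(path)$key_genes, character(0))
})

test_that("randomized truths round-trip across 20 seeds", {
  path <- withr::local_tempfile(fileext = ".json")
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 50, module_sizes = c(15, 15),
                      n_key_genes_per_module = s %% 4,
                      timepoints_h = c(0, 12), n_replicates = 1, seed = s)
    tr <- generate_dataset(cfg)$truth
    write_truth(tr, path)
    back <- read_truth(path)
    expect_equal(back$module_membership, tr$module_membership)
    expect_equal(back$key_genes, tr$key_genes)
    expect_equal(back$size_factors, tr$size_factors)
  }
})
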