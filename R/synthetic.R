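#' Simulation configuration for synthetic stress time-course counts
#'
#' Describes a two-condition (control vs. stress) time-course RNA-seq design
#' with planted co-expression modules, stress-rewired "key" genes and a null
#' background.  The defaults emulate the 36-library design of a salt-stress
#' experiment: 2 conditions x 6 time points (0, 3, 6, 12, 24, 48 h) x 3
#' replicates.
#'
#' Each planted module has its own latent factor and activity profile (flat
#' in control, a single-time-point bump under stress); ordinary module genes
#' load on their module's factor in both conditions.  Modules come in pairs
#' whose factor *noise* components correlate at `factor_cor` -- too weakly
#' to connect ordinary genes across the pair, but enough for the key genes,
#' which load on *both* factors of their pair (more strongly on their home
#' module), to correlate highly with both.  Key genes load in stress
#' samples only: under normal conditions they are decoupled from the
#' module, under stress they bridge the paired modules and become the most
#' connected nodes of both (hub genes recruiting many partners under
#' stress).  The control-state factor noise is inflated so the total factor
#' variance and covariance match the stress state; ordinary co-expression
#' strength is therefore condition-independent, and only the key genes
#' rewire.
#'
#' @param n_genes total number of genes (planted + null).
#' @param module_sizes integer vector, genes per planted module.
#' @param n_key_genes_per_module number of rewired key genes inside each
#'   module (counted within `module_sizes`).
#' @param n_null_genes number of independent background genes; must satisfy
#'   `sum(module_sizes) + n_null_genes == n_genes`.
#' @param conditions two condition labels; the second is the stress state.
#' @param timepoints_h sampling times in hours.
#' @param n_replicates biological replicates per condition x time point.
#' @param activity_amplitude absolute bump height of the module activity
#'   profile, in natural-log expression units.
#' @param activity_times time point (h) of each module's stress bump;
#'   recycled over modules.  Defaults to the non-zero time points cycled,
#'   so paired modules peak at different times.
#' @param module_signs +1/-1 per module: direction of both the activity bump
#'   and the condition main effect (up- or down-regulated module).  Defaults
#'   alternate, so paired modules move in opposite directions.
#' @param within_module_loading reference loading on the module factors, in
#'   (0, 1]; key genes load at `within_module_loading / sqrt(2)` on the two
#'   factors of their module pair (stress only), slightly stronger on the
#'   home module.
#' @param ordinary_loading_range range of uniform multipliers applied to
#'   `within_module_loading` for ordinary (non-key) module genes.
#' @param factor_cor correlation between the factor noise components of
#'   paired modules.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseline_log_mean_range range of per-gene baseline natural-log
#'   means, sampled uniformly.
#' @param size_factor_log_sd standard deviation of per-sample log size
#'   factors.
#' @param de_effect_log2fc condition main effect (log2 fold change, stress
#'   vs. control) applied to every ordinary planted module gene with the
#'   module sign.
#' @param key_de_log2fc condition main effect applied to key genes (module
#'   sign); larger than `de_effect_log2fc` because the stress-only factor
#'   loading adds within-stress variance that a differential-expression
#'   screen must overcome.
#' @param seed integer seed driving a single generator stream.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1000L,
                       module_sizes = rep(50L, 6L),
                       n_key_genes_per_module = 6L,
                       n_null_genes = n_genes - sum(module_sizes),
                       conditions = c("control", "salt"),
                       timepoints_h = c(0, 3, 6, 12, 24, 48),
                       n_replicates = 3L,
                       activity_amplitude = 2.5,
                       activity_times = NULL,
                       module_signs = NULL,
                       within_module_loading = 0.9,
                       ordinary_loading_range = c(0.7, 0.95),
                       factor_cor = 0.6,
                       nb_dispersion = 0.05,
                       baseline_log_mean_range = log(c(100, 3000)),
                       size_factor_log_sd = 0.25,
                       de_effect_log2fc = 1.5,
                       key_de_log2fc = 3.5,
                       seed = 1L) {
  n_modules <- length(module_sizes)
  if (n_null_genes < 0 || sum(module_sizes) + n_null_genes != n_genes) {
    stop("inconsistent gene budget: sum(module_sizes) + n_null_genes must ",
         "equal n_genes", call. = FALSE)
  }
  if (any(module_sizes < n_key_genes_per_module)) {
    stop("n_key_genes_per_module exceeds a module size", call. = FALSE)
  }
  if (length(conditions) != 2L) {
    stop("exactly two condition labels are required", call. = FALSE)
  }
  if (within_module_loading <= 0 || within_module_loading > 1) {
    stop("within_module_loading must lie in (0, 1]", call. = FALSE)
  }
  if (abs(factor_cor) >= 1) {
    stop("factor_cor must lie in (-1, 1)", call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive", call. = FALSE)
  if (is.null(activity_times)) {
    pool <- setdiff(timepoints_h, 0)
    if (length(pool) == 0L) pool <- timepoints_h
    activity_times <- rep_len(pool, n_modules)
  } else {
    activity_times <- rep_len(activity_times, n_modules)
  }
  if (is.null(module_signs)) {
    module_signs <- rep_len(c(1, -1), n_modules)
  } else {
    module_signs <- rep_len(module_signs, n_modules)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    n_key_genes_per_module = as.integer(n_key_genes_per_module),
    n_null_genes = as.integer(n_null_genes),
    conditions = as.character(conditions),
    timepoints_h = as.numeric(timepoints_h),
    n_replicates = as.integer(n_replicates),
    activity_amplitude = as.numeric(activity_amplitude),
    activity_times = as.numeric(activity_times),
    module_signs = as.numeric(module_signs),
    within_module_loading = as.numeric(within_module_loading),
    ordinary_loading_range = as.numeric(ordinary_loading_range),
    factor_cor = as.numeric(factor_cor),
    nb_dispersion = as.numeric(nb_dispersion),
    baseline_log_mean_range = as.numeric(baseline_log_mean_range),
    size_factor_log_sd = as.numeric(size_factor_log_sd),
    de_effect_log2fc = as.numeric(de_effect_log2fc),
    key_de_log2fc = as.numeric(key_de_log2fc),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic count dataset with ground truth
#'
#' Draws negative-binomial counts with mean
#' `size_factor * exp(baseline + loading * module_activity + condition effect)`.
#' Ordinary module genes load on their module factor in both conditions; key
#' genes load only in stress samples; null genes are independent noise.  All
#' stochastic draws consume one stream seeded by `config$seed`, in a fixed
#' order (size factors, baselines, loading multipliers, factor noise, counts).
#'
#' @param config a [sim_config()] object.
#' @return A list with components `dataset` (a [count_dataset()]) and
#'   `truth` (a `synthetic_truth` object: `module_membership`, `key_genes`,
#'   `de_genes`, `size_factors`, `config_echo`).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  stress <- config$conditions[2L]
  design <- expand.grid(
    replicate = seq_len(config$n_replicates),
    time_h = config$timepoints_h,
    condition = config$conditions,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("condition", "time_h", "replicate")]
  design$sample <- sprintf("%s_%02gh_r%d", design$condition, design$time_h,
                           design$replicate)
  design <- design[, c("sample", "condition", "time_h", "replicate")]
  n_samp <- nrow(design)

  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  module_of <- rep(NA_character_, config$n_genes)
  idx <- 1L
  module_labels <- sprintf("module_%d", seq_len(config$n_modules))
  key_genes <- character(0)
  for (m in seq_len(config$n_modules)) {
    sz <- config$module_sizes[m]
    members <- idx:(idx + sz - 1L)
    module_of[members] <- module_labels[m]
    key_genes <- c(key_genes,
                   genes[members[seq_len(config$n_key_genes_per_module)]])
    idx <- idx + sz
  }
  planted <- !is.na(module_of)

  # draw order is fixed and documented
  size_factors <- exp(rnorm(n_samp, 0, config$size_factor_log_sd))
  names(size_factors) <- design$sample
  baseline <- runif(config$n_genes, config$baseline_log_mean_range[1L],
                    config$baseline_log_mean_range[2L])

  loading <- numeric(config$n_genes)
  mult <- runif(config$n_genes, config$ordinary_loading_range[1L],
                config$ordinary_loading_range[2L])
  loading[planted] <- config$within_module_loading * mult[planted]
  is_key <- genes %in% key_genes
  key_load <- config$within_module_loading / sqrt(2)
  # partner module within each pair (an unpaired trailing module partners
  # with itself: its keys then load sqrt(2) * key_load on the own factor)
  partner <- ifelse(seq_len(config$n_modules) %% 2L == 1L,
                    pmin(seq_len(config$n_modules) + 1L, config$n_modules),
                    seq_len(config$n_modules) - 1L)

  # latent per-module factors.  Paired modules have their own activity
  # profiles but share factor *noise* at correlation factor_cor; the
  # control noise is inflated (and its correlation deflated) so per-state
  # factor variance and covariance both match the stress state: ordinary
  # co-expression strength is condition-independent by construction
  is_stress <- design$condition == stress
  activity <- matrix(0, config$n_modules, n_samp)
  for (m in seq_len(config$n_modules)) {
    bump <- is_stress & design$time_h == config$activity_times[m]
    activity[m, bump] <- config$module_signs[m] * config$activity_amplitude
  }
  rho <- config$factor_cor
  n_str <- sum(is_stress)
  f_fac <- matrix(0, config$n_modules, n_samp)
  for (p in seq_len(ceiling(config$n_modules / 2))) {
    a <- 2L * p - 1L
    b <- if (2L * p <= config$n_modules) 2L * p else NA_integer_
    av_a <- if (n_str > 1)
      var(activity[a, is_stress]) * (n_str - 1) / n_str else 0
    e_f <- rnorm(n_samp)
    e_g <- rnorm(n_samp)
    f_fac[a, ] <- ifelse(is_stress, activity[a, ] + e_f,
                         sqrt(1 + av_a) * e_f)
    if (!is.na(b)) {
      av_b <- if (n_str > 1)
        var(activity[b, is_stress]) * (n_str - 1) / n_str else 0
      e_b <- rho * e_f + sqrt(1 - rho^2) * e_g
      # control: var 1 + av_b, covariance with f_a still rho
      rho_ctl <- rho / sqrt((1 + av_a) * (1 + av_b))
      e_b_ctl <- rho_ctl * e_f + sqrt(1 - rho_ctl^2) * e_g
      f_fac[b, ] <- ifelse(is_stress, activity[b, ] + e_b,
                           sqrt(1 + av_b) * e_b_ctl)
    }
  }

  # keys bridge their module pair, loading more strongly on the home module
  key_load_own <- key_load * 1.15
  key_load_partner <- key_load * 0.85

  de_ln <- log(2) * config$de_effect_log2fc
  key_de_ln <- log(2) * config$key_de_log2fc
  counts <- matrix(0L, config$n_genes, n_samp,
                   dimnames = list(genes, design$sample))
  for (g in seq_len(config$n_genes)) {
    eta <- rep(baseline[g], n_samp)
    if (planted[g]) {
      m <- match(module_of[g], module_labels)
      on <- as.numeric(is_stress)
      if (is_key[g]) {
        eta <- eta + on * (key_load_own * f_fac[m, ] +
                             key_load_partner * f_fac[partner[m], ]) +
          config$module_signs[m] * key_de_ln * on
      } else {
        eta <- eta + loading[g] * f_fac[m, ] +
          config$module_signs[m] * de_ln * on
      }
    }
    mu <- size_factors * exp(eta)
    counts[g, ] <- rnbinom(n_samp, mu = mu, size = 1 / config$nb_dispersion)
  }

  dataset <- count_dataset(counts, design)
  truth <- structure(list(
    module_membership = setNames(ifelse(is.na(module_of), "none", module_of),
                                 genes),
    key_genes = key_genes,
    de_genes = genes[planted],
    size_factors = size_factors,
    config_echo = config
  ), class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Write / read the synthetic ground truth as JSON
#'
#' The JSON round-trips losslessly through [read_truth()].
#'
#' @param truth a `synthetic_truth` object from [generate_dataset()].
#' @param path output file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   the reconstructed `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  payload <- list(
    module_membership = as.list(truth$module_membership),
    key_genes = truth$key_genes,
    de_genes = truth$de_genes,
    size_factors = as.list(truth$size_factors),
    config_echo = unclass(truth$config_echo)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config_echo
  cfg_obj <- sim_config(
    n_genes = cfg$n_genes, module_sizes = cfg$module_sizes,
    n_key_genes_per_module = cfg$n_key_genes_per_module,
    n_null_genes = cfg$n_null_genes, conditions = cfg$conditions,
    timepoints_h = cfg$timepoints_h, n_replicates = cfg$n_replicates,
    activity_amplitude = cfg$activity_amplitude,
    activity_times = cfg$activity_times, module_signs = cfg$module_signs,
    within_module_loading = cfg$within_module_loading,
    ordinary_loading_range = cfg$ordinary_loading_range,
    factor_cor = cfg$factor_cor,
    nb_dispersion = cfg$nb_dispersion,
    baseline_log_mean_range = cfg$baseline_log_mean_range,
    size_factor_log_sd = cfg$size_factor_log_sd,
    de_effect_log2fc = cfg$de_effect_log2fc,
    key_de_log2fc = cfg$key_de_log2fc, seed = cfg$seed
  )
  membership <- unlist(x$module_membership)
  if (is.null(membership)) membership <- setNames(character(0), character(0))
  sf <- unlist(x$size_factors)
  structure(list(
    module_membership = membership,
    key_genes = as.character(x$key_genes %||% character(0)),
    de_genes = as.character(x$de_genes %||% character(0)),
    size_factors = sf,
    config_echo = cfg_obj
  ), class = "synthetic_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
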