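#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline in one validated
#' object. A single integer `seed` governs all stochastic stages; each
#' stage derives its own reproducible stream from `(seed, stage name)`
#' via [stage_seed()], so stages can be re-run independently and two runs
#' with identical configuration are bitwise identical.
#'
#' @param seed integer master seed.
#' @param k_biclusters number of biclusters searched for.
#' @param correlation_threshold Pearson threshold above which a test
#'   tumour is assigned to a bicluster.
#' @param early_cutoff_years,late_cutoff_years relapse dichotomization
#'   boundaries (years): relapse at or before the early cutoff is "early",
#'   disease-free survival at or past the late cutoff is "late".
#' @param n_cv_splits number of random train/test splits.
#' @param test_fraction fraction of labeled samples held out per split.
#' @param split_alpha significance level used when comparing predictors
#'   across splits.
#' @param t_initial,cooling,iters_per_bicluster geometric annealing
#'   schedule: temperature `t_initial * cooling^i` over
#'   `iters_per_bicluster * k_biclusters` toggles (the default gives
#'   each bicluster roughly ten sweeps over its candidate toggles at
#'   the default design scale).
#' @param min_samples,max_samples,min_genes,max_genes hard size bounds a
#'   bicluster must respect.
#' @param target_samples,target_genes soft size targets for the size
#'   penalty (20 tumours matches the average bicluster size the search is
#'   calibrated for).
#' @param lambda_size,lambda_overlap penalty weights: `lambda_size`
#'   scales the quality-coupled volume term (growth of a bicluster is
#'   rewarded while its coherence stays below `coherence_null`);
#'   `lambda_overlap` scales the duplicate-repelling overlap term (sum
#'   over biclusters of their maximum pairwise sample-Jaccard).
#' @param coherence_null coherence level of a structureless noise block;
#'   biclusters more coherent than this are rewarded for growing,
#'   less coherent ones for shrinking.
#' @param seed_neighbours,seed_genes bicluster seeding: a random tumour
#'   plus its most-correlated neighbours, and the genes with lowest
#'   variance across that seed.
#' @param noise_threshold log2 intensity below which a value counts as
#'   noise; `NULL` means the data-driven default (20th percentile).
#' @param min_expressed_fraction minimum fraction of samples in which a
#'   gene must exceed the noise threshold to be retained.
#' @param cox_p_cutoff univariate Cox p-value cutoff for
#'   survival-associated gene selection.
#' @param de_p_cutoff,de_fc_cutoff volcano selection cutoffs (raw p and
#'   fold change).
#' @param n_randomizations number of size-matched randomizations pooled
#'   into the separation-test null.
#' @param tree_alpha,tree_min_leaf,tree_n_perm,tree_trim conditional
#'   inference tree controls: split significance level, minimum leaf
#'   size, Monte-Carlo permutations per test, and the display-trim level
#'   (nodes with adjusted p below `tree_trim` but above `tree_alpha` are
#'   reported greyed, never used to split).
#' @param auc_horizon_years horizon for the time-dependent AUC.
#'
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(seed = 1L,
                       k_biclusters = 44L,
                       correlation_threshold = 0.9,
                       early_cutoff_years = 2,
                       late_cutoff_years = 8,
                       n_cv_splits = 50L,
                       test_fraction = 0.2,
                       split_alpha = 0.05,
                       t_initial = 1.0,
                       cooling = 0.995,
                       iters_per_bicluster = 15000L,
                       min_samples = 15L,
                       max_samples = 60L,
                       min_genes = 15L,
                       max_genes = 120L,
                       target_samples = 20L,
                       target_genes = 60L,
                       lambda_size = 2.0,
                       coherence_null = 0.9,
                       lambda_overlap = 0.05,
                       seed_neighbours = 5L,
                       seed_genes = 30L,
                       noise_threshold = NULL,
                       min_expressed_fraction = 0.10,
                       cox_p_cutoff = 0.01,
                       de_p_cutoff = 0.05,
                       de_fc_cutoff = 2,
                       n_randomizations = 20L,
                       tree_alpha = 0.05,
                       tree_min_leaf = 7L,
                       tree_n_perm = 9999L,
                       tree_trim = 0.5,
                       auc_horizon_years = 2) {
  cfg <- list(
    seed = as.integer(seed),
    k_biclusters = as.integer(k_biclusters),
    correlation_threshold = correlation_threshold,
    early_cutoff_years = early_cutoff_years,
    late_cutoff_years = late_cutoff_years,
    n_cv_splits = as.integer(n_cv_splits),
    test_fraction = test_fraction,
    split_alpha = split_alpha,
    t_initial = t_initial,
    cooling = cooling,
    iters_per_bicluster = as.integer(iters_per_bicluster),
    min_samples = as.integer(min_samples),
    max_samples = as.integer(max_samples),
    min_genes = as.integer(min_genes),
    max_genes = as.integer(max_genes),
    target_samples = as.integer(target_samples),
    target_genes = as.integer(target_genes),
    lambda_size = lambda_size,
    coherence_null = coherence_null,
    lambda_overlap = lambda_overlap,
    seed_neighbours = as.integer(seed_neighbours),
    seed_genes = as.integer(seed_genes),
    noise_threshold = noise_threshold,
    min_expressed_fraction = min_expressed_fraction,
    cox_p_cutoff = cox_p_cutoff,
    de_p_cutoff = de_p_cutoff,
    de_fc_cutoff = de_fc_cutoff,
    n_randomizations = as.integer(n_randomizations),
    tree_alpha = tree_alpha,
    tree_min_leaf = as.integer(tree_min_leaf),
    tree_n_perm = as.integer(tree_n_perm),
    tree_trim = tree_trim,
    auc_horizon_years = auc_horizon_years
  )
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$k_biclusters < 1L) stop("k_biclusters must be >= 1")
  if (!(cfg$test_fraction > 0 && cfg$test_fraction < 1)) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  if (!(cfg$early_cutoff_years < cfg$late_cutoff_years)) {
    stop("early_cutoff_years must be smaller than late_cutoff_years")
  }
  if (cfg$t_initial <= 0 || cfg$cooling <= 0 || cfg$cooling >= 1) {
    stop("annealing schedule requires t_initial > 0 and cooling in (0,1)")
  }
  if (cfg$min_samples < 2L || cfg$min_genes < 2L) {
    stop("minimum bicluster sizes must be at least 2")
  }
  if (cfg$min_samples > cfg$max_samples || cfg$min_genes > cfg$max_genes) {
    stop("size bounds must satisfy min <= max")
  }
  if (!(cfg$min_expressed_fraction > 0 && cfg$min_expressed_fraction <= 1)) {
    stop("min_expressed_fraction must lie in (0, 1]")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Any field of [run_config()] may appear in the file; unnamed fields take
#' their defaults. `overrides` (e.g. parsed command-line flags) win over
#' the file on conflict.
#'
#' @param path YAML file, or `NULL` for pure defaults/overrides.
#' @param overrides named list of fields overriding the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("config file must contain a YAML mapping")
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Derive a stage-specific RNG seed from the master seed
#'
#' Deterministic hash of `(seed, stage)` into `[1, 2^31 - 2]`, so every
#' stochastic pipeline stage gets its own reproducible stream and stages
#' can be re-run independently of one another.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return A positive integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.character(stage), length(stage) == 1)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (c in utf8ToInt(stage)) {
    h <- (h * 31 + c) %% m
  }
  # final scramble keeps nearby seeds apart
  h <- (h * 48271) %% m
  as.integer(h + 1)
}

# Evaluate `expr` under a given seed without disturbing the caller's
# RNG state.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
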