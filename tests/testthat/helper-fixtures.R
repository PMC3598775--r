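# Shared fixtures, all generated in code.

# small deterministic expression matrix
tiny_expression <- function(n_genes = 6, n_samples = 4, seed = 42,
                            symbols = NULL) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  expression_matrix(vals,
                    gene_ids = sprintf("g%02d", seq_len(n_genes)),
                    sample_ids = sprintf("s%02d", seq_len(n_samples)),
                    gene_symbols = symbols)
}

# minimal valid clinical table
tiny_clinical <- function(n = 8, seed = 7) {
  set.seed(seed)
  clinical_table(data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    cohort = rep(c("c1", "c2"), length.out = n),
    ln_status = rep(c("LN-", "LN+"), length.out = n),
    er_status = rep(c("ER+", "ER-"), length.out = n),
    pgr_status = rep(c("PgR+", "PgR-"), length.out = n),
    grade = rep(c("G1", "G2", "G3"), length.out = n),
    subtype = rep(c("LumA", "Basal"), length.out = n),
    size_mm = round(runif(n, 5, 50), 1),
    age_years = round(runif(n, 35, 80)),
    dfs_time_years = round(rexp(n, 0.2), 3),
    dfs_event = rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  ))
}

# a scaled-down simulation design for fast end-to-end checks
small_design <- function(seed = 1, n_genes = 300, n_samples = 120,
                         n_planted = 4) {
  default_design(seed = seed, n_genes = n_genes, n_samples = n_samples,
                 n_planted = n_planted)
}

# a fast run_config for small problems
small_config <- function(seed = 1, k = 4, ...) {
  run_config(seed = seed, k_biclusters = k, iters_per_bicluster = 3000,
             tree_n_perm = 999, ...)
}

# exponential two-group survival data
two_group_surv <- function(n_per = 50, hr = 1, rate = 0.2, censor = 0) {
  g <- rep(0:1, each = n_per)
  tt <- rexp(2 * n_per, rate * ifelse(g == 1, hr, 1))
  if (censor > 0) {
    cc <- rexp(2 * n_per, censor)
    list(times = pmin(tt, cc), events = as.integer(tt <= cc), group = g)
  } else {
    list(times = tt, events = rep(1L, 2 * n_per), group = g)
  }
}
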