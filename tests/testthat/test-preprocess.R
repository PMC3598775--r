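test_that("noise filter keeps genes expressed in at least the required fraction", {
  vals <- matrix(0, 3, 10)
  vals[1, 1] <- 5      # above threshold in exactly 1 of 10 samples
  vals[2, 1:3] <- 5
  # gene 3 never above threshold
  x <- expression_matrix(vals, gene_ids = c("a", "b", "c"),
                         sample_ids = sprintf("s%02d", 1:10))
  out <- filter_low_expression(x, filter_spec(noise_threshold = 1,
                                              min_expressed_fraction = 0.10))
  expect_equal(out$gene_ids, c("a", "b")) # boundary inclusive: >= 10%
  expect_equal(attr(out, "removed_genes"), "c")

  ident <- filter_low_expression(x, filter_spec(noise_threshold = -Inf))
  expect_equal(ident$gene_ids, x$gene_ids)
  expect_error(filter_low_expression(x, filter_spec(noise_threshold = 10)),
               "empty result")
})

test_that("probe collapse keeps the probe closest to the symbol median", {
  # symbol X: probe p1 tracks the median pattern, p2 is anti-correlated
  vals <- rbind(c(1, 2, 3),
                c(3, 2, 1),
                c(1.1, 2.2, 2.9),
                c(5, 5, 5))
  x <- expression_matrix(vals, gene_ids = c("p1", "p2", "p3", "q1"),
                         sample_ids = c("s1", "s2", "s3"),
                         gene_symbols = c("X", "X", "X", "Y"))
  out <- collapse_probes(x)
  expect_equal(out$gene_ids, c("p1", "q1"))

  # all symbols unique: identity
  x2 <- tiny_expression(symbols = c("A", "B", "C", "D", "E", "F"))
  expect_equal(collapse_probes(x2)$gene_ids, x2$gene_ids)

  # identical duplicate probes: lexicographically first gene id retained
  vals3 <- rbind(c(1, 2, 3), c(1, 2, 3))
  x3 <- expression_matrix(vals3, gene_ids = c("pB", "pA"),
                          sample_ids = c("s1", "s2", "s3"),
                          gene_symbols = c("Z", "Z"))
  expect_equal(collapse_probes(x3)$gene_ids, "pA")

  expect_error(collapse_probes(tiny_expression()), "gene_symbols")
})

test_that("filter-then-collapse commutes with sample permutation", {
  set.seed(8)
  x <- tiny_expression(n_genes = 12, n_samples = 10,
                       symbols = rep(c("A", "B", "C", "D", "E", "F"), 2))
  run <- function(z) {
    collapse_probes(filter_low_expression(z, filter_spec(noise_threshold = -1)))
  }
  perm <- sample(10)
  xp <- expression_matrix(x$values[, perm],
                                       gene_ids = x$gene_ids,
                                       sample_ids = x$sample_ids[perm],
                                       gene_symbols = x$gene_symbols)
  a <- run(x)
  b <- run(xp)
  expect_equal(a$gene_ids, b$gene_ids)
  expect_equal(a$values[, a$sample_ids], b$values[, a$sample_ids])
})

test_that("batch adjustment equalizes cohort location and scale", {
  set.seed(9)
  vals <- matrix(rnorm(50 * 20), 50, 20)
  vals[, 11:20] <- vals[, 11:20] + 5 # pure +5 shift on cohort 2
  x <- expression_matrix(vals, gene_ids = sprintf("g%02d", 1:50),
                         sample_ids = sprintf("s%02d", 1:20))
  cohort <- rep(c("a", "b"), each = 10)
  adj <- adjust_batch(x, cohort)
  m_a <- rowMeans(adj$values[, 1:10])
  m_b <- rowMeans(adj$values[, 11:20])
  expect_lt(max(abs(m_a - m_b)), 1e-8)
  v_a <- apply(adj$values[, 1:10], 1, var)
  v_b <- apply(adj$values[, 11:20], 1, var)
  expect_lt(max(abs(v_a / v_b - 1)), 1e-6)
  # within-cohort gene-gene correlations untouched by the affine map
  expect_equal(cor(t(vals[1:5, 1:10])), cor(t(adj$values[1:5, 1:10])),
               tolerance = 1e-9, ignore_attr = TRUE)

  # idempotent
  adj2 <- adjust_batch(adj, cohort)
  expect_lt(max(abs(adj2$values - adj$values)), 1e-8)

  expect_error(adjust_batch(x, rep(c("a", "b", "solo"), c(10, 9, 1))),
               "single sample")
})

test_that("batch adjustment shrinks between-cohort F statistics on synthetic data", {
  sim <- simulate_dataset(small_design(seed = 6))
  cohort <- sim$clinical$cohort
  fstat <- function(v) {
    fit <- stats::aov(v ~ factor(cohort))
    summary(fit)[[1]][["F value"]][1]
  }
  idx <- seq_len(150) # a subset of genes keeps this quick
  f_pre <- apply(sim$expression$values[idx, ], 1, fstat)
  adj <- adjust_batch(sim$expression, cohort)
  f_post <- apply(adj$values[idx, ], 1, fstat)
  expect_gte(mean(f_post <= f_pre), 0.99)
})

test_that("planted block contrast survives batch adjustment", {
  pb <- planted_bicluster(1:24, 1:30, expression_shift = 3)
  d <- simulation_design(n_genes = 120, n_samples = 96, n_cohorts = 3,
                         planted = list(pb), seed = 12)
  sim <- simulate_dataset(d)
  adj <- adjust_batch(sim$expression, sim$clinical$cohort)
  contrast <- function(v) mean(v[1:30, 1:24]) - mean(v[1:30, 25:96])
  expect_equal(contrast(adj$values), contrast(sim$expression$values),
               tolerance = 0.05 * 3)
})
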