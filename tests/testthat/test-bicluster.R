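test_that("coherence score is zero for constant and additive blocks", {
  set.seed(1)
  m <- matrix(rnorm(400), 20, 20)
  m[1:6, 1:5] <- 4
  expect_equal(coherence_score(m, samples = 1:5, genes = 1:6), 0)

  # additive block: a_t + b_g has no interaction residue
  a <- rnorm(5); b <- rnorm(6)
  m[1:6, 1:5] <- outer(b, a, "+")
  expect_equal(coherence_score(m, samples = 1:5, genes = 1:6), 0)

  expect_error(coherence_score(m, samples = 1, genes = 1:6), "at least 2")
})

test_that("an i.i.d. noise block scores near (1-1/n)(1-1/m)", {
  set.seed(2)
  scores <- vapply(1:200, function(r) {
    m <- matrix(rnorm(400), 20, 20)
    coherence_score(m, samples = 1:20, genes = 1:20)
  }, numeric(1))
  expect_equal(mean(scores), (1 - 1 / 20)^2, tolerance = 0.02)
})

test_that("a rank-one module scores far below a noise block", {
  set.seed(3)
  m <- matrix(rnorm(3000), 50, 60)
  m[1:30, 1:20] <- m[1:30, 1:20] +
    3 * (rnorm(30, 1, 0.5) %o% rnorm(20, 1, 0.3))
  expect_lt(coherence_score(m, samples = 1:20, genes = 1:30), 0.5)
  expect_gt(coherence_score(m, samples = 21:40, genes = 31:50), 0.8)
})

test_that("compiled residue agrees exactly with the reference implementation", {
  set.seed(4)
  m <- matrix(rnorm(1200), 30, 40)
  for (r in 1:20) {
    gi <- sample(30, sample(2:15, 1))
    si <- sample(40, sample(2:15, 1))
    expect_equal(bistrat:::.coh_resid_cpp(m, gi, si),
                 bistrat:::coh_resid(m, gi, si), tolerance = 1e-12)
  }
})

test_that("greedy refinement grows a seeded searcher onto its planted module", {
  pb <- planted_bicluster(1:20, 1:30, expression_shift = 3)
  d <- simulation_design(n_genes = 200, n_samples = 100, n_cohorts = 1,
                         cohort_shift_sd = 0, cohort_scale_sd = 0,
                         planted = list(pb), seed = 50)
  sim <- simulate_dataset(d)
  cfg <- run_config(seed = 1, k_biclusters = 1, t_initial = 1e-9,
                    cooling = 0.5) # T -> 0: pure greedy toggling
  set.seed(8)
  state <- new_search_state(sim$expression, cfg)
  state$Smem[, 1] <- seq_len(100) %in% 1:6
  state$Gmem[, 1] <- rep(FALSE, 200)
  state$Gmem[1:15, 1] <- TRUE
  state$coh[1] <- bistrat:::coh_resid(state$vals, 1:15, 1:6)
  state$pen[1] <- bistrat:::size_penalty(state$coh[1], 6, 15, state$cfg)
  for (i in 1:3000) state <- propose_move(state)
  found <- which(state$Smem[, 1])
  jac <- length(intersect(found, 1:20)) / length(union(found, 1:20))
  expect_gte(jac, 0.75)
  # most of the planted module's genes are recruited
  expect_gte(mean(1:30 %in% which(state$Gmem[, 1])), 0.6)
})

test_that("annealing acceptance follows the Metropolis rule in the limits", {
  # downhill moves always accepted, uphill moves frozen out at T -> 0:
  # a greedy chain's total score never increases
  set.seed(7)
  sim <- simulate_dataset(small_design(seed = 7))
  cfg <- small_config(seed = 2, t_initial = 1e-8)
  state <- new_search_state(sim$expression, cfg)
  s0 <- bistrat:::state_total_score(state)
  for (i in 1:150) {
    state <- propose_move(state)
    s1 <- bistrat:::state_total_score(state)
    expect_lte(s1, s0 + 1e-9)
    s0 <- s1
  }
})

test_that("run_biclustering is deterministic and respects its contracts", {
  sim <- simulate_dataset(small_design(seed = 8))
  x <- adjust_batch(sim$expression, sim$clinical$cohort)
  cfg <- small_config(seed = 5)
  b1 <- run_biclustering(x, cfg)
  b2 <- run_biclustering(x, cfg)
  expect_identical(lapply(b1$biclusters, `[[`, "sample_ids"),
                   lapply(b2$biclusters, `[[`, "sample_ids"))
  expect_identical(lapply(b1$biclusters, `[[`, "gene_ids"),
                   lapply(b2$biclusters, `[[`, "gene_ids"))
  expect_equal(length(b1), cfg$k_biclusters)
  for (b in b1$biclusters) {
    expect_gte(length(b$sample_ids), cfg$min_samples)
    expect_lte(length(b$sample_ids), cfg$max_samples)
    expect_gte(length(b$gene_ids), cfg$min_genes)
    expect_lte(length(b$gene_ids), cfg$max_genes)
    expect_true(is.finite(b$score))
  }
  expect_lte(attr(b1, "final_score"), attr(b1, "initial_score"))

  expect_error(run_biclustering(x, run_config(k_biclusters = 1000)),
               "exceeds the number of samples")
})

test_that("a single searcher recovers a lone planted module", {
  pb <- planted_bicluster(1:18, 1:40, expression_shift = 3)
  d <- simulation_design(n_genes = 200, n_samples = 60, n_cohorts = 1,
                         cohort_shift_sd = 0, cohort_scale_sd = 0,
                         planted = list(pb), seed = 31)
  sim <- simulate_dataset(d)
  cfg <- run_config(seed = 3, k_biclusters = 1, iters_per_bicluster = 4000)
  bcs <- run_biclustering(sim$expression, cfg)
  found <- bcs$biclusters[[1]]$sample_ids
  block <- sim$truth$biclusters[[1]]$sample_ids
  expect_gte(length(intersect(found, block)) / length(block), 0.9)
})

test_that("recovery jaccard matches direct counting", {
  t1 <- bicluster_set(list(bicluster(1, paste0("s", 1:4), "g1")))
  f_same <- bicluster_set(list(bicluster(1, paste0("s", 1:4), "g9")))
  expect_equal(recovery_jaccard(f_same, t1), 1.0)
  f_disj <- bicluster_set(list(bicluster(1, paste0("s", 5:8), "g9")))
  expect_equal(recovery_jaccard(f_disj, t1), 0.0)
  f_part <- bicluster_set(list(bicluster(1, paste0("s", 3:6), "g9")))
  expect_equal(recovery_jaccard(f_part, t1), 2 / 6)
  expect_error(recovery_jaccard(f_part, bicluster_set(list())), "empty")
})
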