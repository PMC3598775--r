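test_that("relapse dichotomization follows the cutoff rules and partitions", {
  cl <- tiny_clinical(n = 6)
  cl$dfs_time_years <- c(1.5, 9.0, 1.5, 2.0, 8.0, 5.0)
  cl$dfs_event <- c(1L, 0L, 0L, 1L, 0L, 1L)
  lab <- dichotomize(cl)
  expect_equal(as.character(lab),
               c("early", "late", "intermediate", "early", "late",
                 "intermediate"))
  expect_equal(sum(table(lab)), nrow(cl))
})

test_that("covariate encoding uses the prescribed size and age classes", {
  cl <- tiny_clinical(n = 5)
  cl$size_mm <- c(5, 10, 20, 39.9, 40)
  cl$age_years <- c(39, 40, 50, 59, 60)
  enc <- encode_covariates(cl)
  expect_equal(as.character(enc$size_class),
               c("<10", "[10,20)", "[20,40)", "[20,40)", ">=40"))
  expect_equal(as.character(enc$age_class),
               c("<40", "[40,50)", "[50,60)", "[50,60)", ">=60"))

  memb <- matrix(0L, 5, 3, dimnames = list(cl$sample_id, paste0("bc", 1:3)))
  memb["s01", c(1, 3)] <- 1L
  enc2 <- encode_covariates(cl, memb)
  expect_equal(as.character(enc2$bc1), c("1", "0", "0", "0", "0"))
  expect_equal(as.character(enc2$bc3), c("1", "0", "0", "0", "0"))

  cl$size_mm[2] <- NA
  enc3 <- encode_covariates(cl)
  expect_equal(as.character(enc3$size_class)[2], "NA")
  cl$size_mm[2] <- -1
  expect_error(encode_covariates(cl), "negative")
})

test_that("PC1 profile recovers a rank-one gene pattern up to sign", {
  set.seed(41)
  p <- rnorm(20, 1, 0.5)
  a <- abs(rnorm(12, 1, 0.3))
  vals <- 3 * (p %o% a) + matrix(rnorm(240, sd = 0.05), 20, 12)
  x <- expression_matrix(vals, gene_ids = sprintf("g%02d", 1:20),
                         sample_ids = sprintf("s%02d", 1:12))
  b <- bicluster(1, x$sample_ids, x$gene_ids)
  prof <- bicluster_pc1_profile(x, b)
  expect_gte(abs(cor(prof, p)), 0.99)
  # sign rule: non-negative correlation with the mean gene profile
  expect_gte(cor(prof, rowMeans(vals)), 0)

  # zero-variance submatrix falls back to the mean profile with a warning
  const <- expression_matrix(matrix(2, 4, 4, dimnames = NULL),
                             gene_ids = paste0("g", 1:4),
                             sample_ids = paste0("s", 1:4))
  expect_warning(pm <- bicluster_pc1_profile(const, bicluster(1, paste0("s", 1:4), paste0("g", 1:4))),
                 "zero-variance")
  expect_equal(unname(pm), rep(2, 4))
})

test_that("PC1 profile tracks the planted pattern on a noisy block", {
  pb <- planted_bicluster(1:40, 1:40, expression_shift = 3)
  d <- simulation_design(n_genes = 150, n_samples = 100, n_cohorts = 1,
                         cohort_shift_sd = 0, cohort_scale_sd = 0,
                         noise_sd = 0.5, planted = list(pb), seed = 43)
  sim <- simulate_dataset(d)
  b <- sim$truth$biclusters[[1]]
  prof <- bicluster_pc1_profile(sim$expression, b)
  p_true <- attr(sim$truth, "patterns")[[1]]
  expect_gte(cor(prof, p_true[names(prof)]), 0.95)
})

test_that("tumours are assigned to biclusters by profile correlation", {
  set.seed(44)
  p1 <- rnorm(30, 1, 0.5)
  p2 <- rnorm(30, 1, 0.5)
  vals <- matrix(rnorm(80 * 40, sd = 0.4), 80, 40)
  vals[1:30, 1:12] <- vals[1:30, 1:12] + 3 * (p1 %o% abs(rnorm(12, 1, 0.3)))
  vals[41:70, 21:32] <- vals[41:70, 21:32] + 3 * (p2 %o% abs(rnorm(12, 1, 0.3)))
  x <- expression_matrix(vals, gene_ids = sprintf("g%02d", 1:80),
                         sample_ids = sprintf("s%02d", 1:40))
  bcs <- bicluster_set(list(
    bicluster(1, x$sample_ids[1:12], x$gene_ids[1:30]),
    bicluster(2, x$sample_ids[21:32], x$gene_ids[41:70])
  ))
  profiles <- lapply(bcs$biclusters, function(b) bicluster_pc1_profile(x, b))

  member <- setNames(x$values[, "s03"], x$gene_ids)
  sel <- assign_to_biclusters(member, bcs, profiles, threshold = 0.5)
  expect_true(1L %in% sel)
  expect_false(isTRUE(attr(sel, "fallback")))

  # impossible threshold: the argmax fallback fires with a single id
  sel2 <- assign_to_biclusters(member, bcs, profiles, threshold = 1.0)
  expect_equal(length(sel2), 1L)
  expect_true(attr(sel2, "fallback"))
  expect_equal(sel2[1], 1L)

  # an anti-correlated profile is never assigned by rule
  anti <- member
  anti[bcs$biclusters[[1]]$gene_ids] <- -anti[bcs$biclusters[[1]]$gene_ids]
  sel3 <- assign_to_biclusters(anti, bcs, profiles, threshold = 0.5)
  r <- attr(sel3, "correlations")
  expect_lt(r[1], 0)
})

test_that("assignment recovers own membership on a planted design", {
  sim <- simulate_dataset(small_design(seed = 45))
  x <- adjust_batch(sim$expression, sim$clinical$cohort)
  truth <- sim$truth
  profiles <- lapply(truth$biclusters, function(b) bicluster_pc1_profile(x, b))
  hits <- 0; total <- 0
  for (sid in x$sample_ids) {
    own <- which(vapply(truth$biclusters, function(b) sid %in% b$sample_ids,
                        logical(1)))
    if (length(own) == 0) next
    sel <- assign_to_biclusters(setNames(x$values[, sid], x$gene_ids),
                                truth, profiles, threshold = 0.4)
    hits <- hits + length(intersect(own, sel))
    total <- total + length(own)
  }
  expect_gte(hits / total, 0.9)
})

test_that("ridge Cox risk scores order by a dominant covariate", {
  set.seed(46)
  g <- two_group_surv(n_per = 60, hr = 3, censor = 0.05)
  xtr <- cbind(grp = g$group, n1 = rnorm(120), n2 = rnorm(120))
  xte <- cbind(grp = c(0, 1, 0, 1), n1 = 0, n2 = 0)
  risk <- ridge_cox_predict(xtr, g$times, g$events, xte, seed = 1)
  expect_equal(length(risk), 4L)
  expect_true(risk[2] > risk[1] && risk[4] > risk[3])
  expect_error(
    ridge_cox_predict(xtr, g$times, rep(0, 120), xte),
    "no events"
  )
})

test_that("time-dependent AUC has the expected limits and invariances", {
  set.seed(47)
  tt <- rexp(200, 0.2)
  ev <- rep(1L, 200)
  perfect <- as.numeric(tt <= 2)
  expect_equal(time_dependent_auc(perfect, tt, ev, horizon = 2), 1.0)
  expect_equal(time_dependent_auc(-perfect, tt, ev, horizon = 2), 0.0)

  risk <- -tt + rnorm(200, sd = 0.1)
  a1 <- time_dependent_auc(risk, tt, ev, 2)
  a2 <- time_dependent_auc(exp(3 * risk), tt, ev, 2) # monotone transform
  expect_equal(a1, a2, tolerance = 1e-12)

  rnd <- time_dependent_auc(rnorm(200), tt, ev, 2)
  expect_equal(rnd, 0.5, tolerance = 0.15)
  expect_warning(out <- time_dependent_auc(rnorm(200), tt, ev, horizon = 1e6),
                 "undefined")
  expect_true(is.na(out))
})

test_that("cross-validation is deterministic given the seed", {
  sim <- simulate_dataset(small_design(seed = 48, n_samples = 150))
  x <- adjust_batch(sim$expression, sim$clinical$cohort)
  cfg <- small_config(seed = 7, n_cv_splits = 2)
  r1 <- cross_validate(x, sim$clinical, cfg)
  r2 <- cross_validate(x, sim$clinical, cfg)
  expect_identical(r1$splits, r2$splits)
  expect_identical(r1$predictions, r2$predictions)
  expect_true(all(r1$splits$sens_clinical >= 0 & r1$splits$sens_clinical <= 1,
                  na.rm = TRUE))
  # train/test disjoint within each split
  for (p in r1$predictions) {
    expect_equal(anyDuplicated(p$sample_id), 0L)
  }
  f <- withr::local_tempfile(fileext = ".csv")
  j <- withr::local_tempfile(fileext = ".json")
  write_cv_report(r1, f, j)
  expect_true(file.exists(f) && file.exists(j))
})
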