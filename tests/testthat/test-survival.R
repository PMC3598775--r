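test_that("Kaplan-Meier estimate matches hand product-limit fixtures", {
  km <- km_estimate(c(1, 2, 4), c(1, 1, 1))
  expect_equal(km$event_times, c(1, 2, 4))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3L, 2L, 1L))

  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival, c(2 / 3, 0)) # risk set of 1 at t = 3
  expect_equal(km_survival_at(km, c(0.5, 1, 2.5)), c(1, 2 / 3, 2 / 3))

  km <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(length(km$event_times), 0L)
  expect_equal(km_survival_at(km, 5), 1)

  expect_error(km_estimate(numeric(0), integer(0)), "empty")
})

test_that("Kaplan-Meier agrees with the survival package on censored data", {
  set.seed(11)
  for (r in 1:5) {
    tt <- round(rexp(40, 0.3), 1) # rounding forces ties
    ev <- rbinom(40, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1L
    km <- km_estimate(tt, ev)
    sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    keep <- sf$n.event > 0
    expect_equal(km$survival, sf$surv[keep], tolerance = 1e-10)
    expect_equal(km$at_risk, sf$n.risk[keep])
  }
})

test_that("without censoring the KM estimate is the empirical survival function", {
  set.seed(12)
  tt <- rexp(60, 0.2)
  km <- km_estimate(tt, rep(1, 60))
  expect_equal(km$survival, vapply(km$event_times, function(u) mean(tt > u),
                                   numeric(1)))
})

test_that("logrank matches the hand-evaluated singleton fixture", {
  lr <- logrank_test(1, 1, 2, 1)
  expect_equal(lr$chi_square, 1.0, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(1, 1, lower.tail = FALSE))

  ident <- suppressWarnings(logrank_test(c(1, 2), c(1, 1), c(1, 2), c(1, 1)))
  expect_equal(ident$chi_square, 0)
  expect_equal(ident$p, 1)

  expect_warning(out <- logrank_test(c(1, 2), c(0, 0), c(3), c(0)),
                 "no events")
  expect_equal(out$p, 1)
  expect_error(logrank_test(numeric(0), integer(0), 1, 1), "non-empty")
})

test_that("logrank agrees with survdiff and is label-symmetric", {
  set.seed(13)
  for (r in 1:8) {
    g <- two_group_surv(n_per = 30, hr = 1.6, censor = 0.1)
    a <- g$group == 0
    lr <- logrank_test(g$times[a], g$events[a], g$times[!a], g$events[!a])
    sd_fit <- survival::survdiff(survival::Surv(g$times, g$events) ~ g$group)
    expect_equal(lr$chi_square, sd_fit$chisq, tolerance = 1e-8)
    swapped <- logrank_test(g$times[!a], g$events[!a], g$times[a], g$events[a])
    expect_equal(lr$chi_square, swapped$chi_square, tolerance = 1e-12)
  }
})

test_that("pairwise logrank enumerates all stable unordered pairs", {
  set.seed(14)
  groups <- lapply(1:5, function(i) {
    list(times = rexp(20, 0.2), events = rbinom(20, 1, 0.8))
  })
  pl <- pairwise_logrank(groups)
  expect_equal(nrow(pl), choose(5, 2))
  expect_true(all(pl$i < pl$j))

  gA <- list(times = c(1, 2, 3, 4), events = c(1, 1, 1, 1))
  gC <- list(times = c(11, 12, 13, 14), events = c(1, 1, 1, 1))
  pl3 <- pairwise_logrank(list(gA, gA, gC))
  expect_equal(pl3$p[pl3$i == 1 & pl3$j == 2], 1) # the identical pair
  expect_lt(max(pl3$p[pl3$j == 3]), 0.05)
})

test_that("size-matched random groups preserve the size multiset", {
  ids <- sprintf("s%03d", 1:100)
  sizes <- c(5, 5, 12, 20)
  g <- random_size_matched_groups(ids, sizes, seed = 3)
  expect_equal(lengths(g), sizes)
  expect_identical(g, random_size_matched_groups(ids, sizes, seed = 3))
  expect_error(random_size_matched_groups(ids, c(3, 0)), ">= 1")
  # sampling with replacement: expected memberships per id = sum(sizes)/n
  set.seed(15)
  counts <- table(unlist(replicate(300, random_size_matched_groups(ids, sizes),
                                   simplify = FALSE)))
  expect_lt(abs(mean(counts) / 300 - sum(sizes) / 100), 0.05)
})

test_that("separation test is reproducible and well-formed", {
  set.seed(16)
  cl <- tiny_clinical(n = 60)
  bcs <- bicluster_set(list(
    bicluster(1, sample(cl$sample_id, 12), "g1"),
    bicluster(2, sample(cl$sample_id, 15), "g2"),
    bicluster(3, sample(cl$sample_id, 10), "g3")
  ))
  st <- separation_test(bcs, cl, n_rand = 4, seed = 9)
  expect_equal(length(st$observed_p_values), choose(3, 2))
  expect_equal(length(st$null_p_values), 4 * choose(3, 2))
  expect_true(all(st$observed_p_values >= 0 & st$observed_p_values <= 1))
  expect_true(st$ks_statistic >= 0 && st$ks_statistic <= 1)
  st2 <- separation_test(bcs, cl, n_rand = 4, seed = 9)
  expect_identical(st$null_p_values, st2$null_p_values)
  expect_error(separation_test(bicluster_set(list(bcs$biclusters[[1]])), cl),
               "at least 2")
})

test_that("planted hazard structure is detected by the separation test", {
  sim <- simulate_dataset(default_design(seed = 9))
  st <- separation_test(sim$truth, sim$clinical, n_rand = 120, seed = 2)
  expect_lt(st$ks_p, 0.01)
})

test_that("Cox score test at beta = 0 equals the logrank chi-square", {
  set.seed(17)
  for (r in 1:5) {
    g <- two_group_surv(n_per = 40, hr = 1.8)
    g$times <- g$times + runif(80, 0, 1e-4) # ensure untied
    fit <- cox_fit(matrix(g$group, ncol = 1), g$times, g$events)
    a <- g$group == 0
    lr <- logrank_test(g$times[a], g$events[a], g$times[!a], g$events[!a])
    expect_equal(fit$score_chisq, lr$chi_square, tolerance = 1e-6)
  }
})

test_that("ridge penalty shrinks coefficients to zero in the limit", {
  set.seed(18)
  g <- two_group_surv(n_per = 50, hr = 2)
  x <- cbind(grp = g$group, noise = rnorm(100))
  fit <- cox_fit(x, g$times, g$events, lambda = 1e6)
  expect_lt(sqrt(sum(fit$coefficients^2)), 1e-3)
  expect_error(cox_fit(matrix(1, 100, 1), g$times, g$events), "constant")
})

test_that("a covariate independent of survival gives near-zero coefficients", {
  set.seed(19)
  coefs <- vapply(1:50, function(r) {
    tt <- rexp(80, 0.2)
    x <- matrix(rnorm(80), ncol = 1)
    cox_fit(x, tt, rep(1, 80))$coefficients[1]
  }, numeric(1))
  expect_lt(abs(mean(coefs)), 0.05)
})

test_that("survival-gene screen finds planted hazard genes and skips constants", {
  set.seed(20)
  n <- 80
  tt <- numeric(n)
  risk <- rnorm(n)
  tt <- rexp(n, 0.2 * exp(0.9 * risk))
  vals <- rbind(risk + rnorm(n, sd = 0.2),
                matrix(rnorm(20 * n), 20, n),
                rep(1, n)) # constant gene
  x <- expression_matrix(vals, gene_ids = sprintf("g%02d", 1:22),
                         sample_ids = sprintf("s%02d", 1:n))
  cl <- clinical_table(data.frame(
    sample_id = x$sample_ids, cohort = "c1", ln_status = "LN-",
    er_status = "ER+", pgr_status = "PgR+", grade = "G2", subtype = "LumA",
    size_mm = 20, age_years = 55, dfs_time_years = tt, dfs_event = 1,
    stringsAsFactors = FALSE
  ))
  b <- bicluster(1, x$sample_ids, x$gene_ids[1:5])
  suppressMessages(sel <- select_survival_genes(x, b, cl, p_cutoff = 0.01))
  expect_true("g01" %in% sel$gene_id)
  expect_false("g22" %in% attr(sel, "all")$gene_id[!is.na(attr(sel, "all")$p)])
  expect_error(select_survival_genes(x, bicluster(1, x$sample_ids[1:5], "g01"), cl),
               ">= 10 samples")
})
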