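# planted two-class fixture: identical noise in both classes (exactly
# zero centroid difference) plus `n_signal` genes shifted in class 2
pam_fixture <- function(n_noise = 500, n_signal = 10, n_per = 40,
                        shift = 5, seed = 21) {
  set.seed(seed)
  noise <- matrix(rnorm(n_noise * n_per), n_noise, n_per)
  # identical signal rows give every planted gene exactly the same
  # standardized centroid difference
  v <- as.numeric(scale(rnorm(n_per)))
  sig_a <- matrix(rep(v, each = n_signal), n_signal, n_per, byrow = FALSE)
  a <- rbind(sig_a, noise)
  b <- rbind(sig_a + shift, noise) # same values, signal genes shifted
  x <- cbind(a, b)
  rownames(x) <- c(sprintf("sig%02d", seq_len(n_signal)),
                   sprintf("noise%03d", seq_len(n_noise)))
  colnames(x) <- sprintf("t%03d", seq_len(2 * n_per))
  list(x = x, labels = factor(rep(c("lo", "hi"), each = n_per),
                              levels = c("lo", "hi")))
}

test_that("shrunken centroids recover exactly the planted genes at zero CV error", {
  fx <- pam_fixture()
  fit <- fit_shrunken_centroids(fx$x, fx$labels, seed = 1)
  expect_setequal(fit$surviving_genes, sprintf("sig%02d", 1:10))
  expect_equal(min(fit$cv$cv_error), 0)
  expect_equal(fit$cv$cv_error[fit$cv$delta == fit$delta], 0)

  # held-out samples from the same generative rule classify perfectly
  set.seed(2)
  new_lo <- rnorm(510)
  names(new_lo) <- rownames(fx$x)
  new_hi <- new_lo
  new_hi[1:10] <- new_hi[1:10] + 5
  expect_equal(predict_class(fit, new_lo)$label, "lo")
  expect_equal(predict_class(fit, new_hi)$label, "hi")
})

test_that("shrinkage behaves monotonically over the delta grid", {
  set.seed(22)
  x <- matrix(rnorm(120 * 30), 120, 30)
  x[1:5, 16:30] <- x[1:5, 16:30] + 2
  rownames(x) <- sprintf("g%03d", 1:120)
  labels <- factor(rep(c("a", "b"), each = 15))
  fit <- fit_shrunken_centroids(x, labels, seed = 3)
  expect_true(all(diff(fit$cv$n_genes) <= 0)) # survivors shrink with delta
  expect_equal(fit$cv$n_genes[1], nrow(x)) # delta = 0 keeps all genes
  expect_equal(fit$cv$n_genes[nrow(fit$cv)], 0) # max delta kills all
})

test_that("prediction ties go to the first class and missing genes error", {
  x <- matrix(c(0, 0, 2, 2, 0, 2), 1, 6)
  rownames(x) <- "g1"
  labels <- factor(c("a", "a", "b", "b", "a", "b"))
  fit <- fit_shrunken_centroids(x, labels, delta_grid = 0, n_folds = 3, seed = 4)
  # sample equal to a class centroid goes to that class
  expect_equal(predict_class(fit, c(g1 = 0))$label, "a")
  expect_equal(predict_class(fit, c(g1 = 2))$label, "b")
  # equidistant sample with equal priors: first level wins
  expect_equal(predict_class(fit, c(g1 = 1))$label, "a")
  expect_error(predict_class(fit, c(g2 = 1)), "missing model gene")
  expect_error(fit_shrunken_centroids(x, factor(c("a", "a", "b", "b", "b", "c"))),
               "2 classes")
})

test_that("differential expression matches the closed-form t on exact data", {
  v <- as.numeric(scale(rnorm(20))) # mean 0, sd 1 exactly
  x <- rbind(g1 = c(v, v + 2), g2 = rnorm(40))
  colnames(x) <- sprintf("s%02d", 1:40)
  de <- differential_expression(x, group_a = 21:40, group_b = 1:20)
  expect_equal(de$t[1], 2 / sqrt(0.1), tolerance = 1e-10)
  expect_equal(de$log2fc[1], 2, tolerance = 1e-12)

  # identical groups: p = 1, fold change 0
  de0 <- differential_expression(cbind(x[, 1:20], x[, 1:20]),
                                 group_a = 1:20, group_b = 21:40)
  expect_true(all(de0$p == 1))
  expect_true(all(de0$log2fc == 0))
})

test_that("differential expression is antisymmetric under group swap", {
  set.seed(23)
  x <- matrix(rnorm(50 * 20), 50, 20)
  colnames(x) <- sprintf("s%02d", 1:20)
  de1 <- differential_expression(x, 1:10, 11:20)
  de2 <- differential_expression(x, 11:20, 1:10)
  expect_equal(de1$t, -de2$t)
  expect_equal(de1$log2fc, -de2$log2fc)
  expect_equal(de1$p, de2$p)
  expect_true(all(de1$p_bh >= de1$p))
})

test_that("null genes yield calibrated raw p and near-zero BH discoveries", {
  set.seed(24)
  x <- matrix(rnorm(1000 * 30), 1000, 30)
  de <- differential_expression(x, 1:15, 16:30)
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.02)
  expect_lte(sum(de$p_bh < 0.05), 2)
  expect_true(all(de$q >= 0 & de$q <= 1))
})

test_that("volcano selection applies both cutoffs with inclusive fold boundary", {
  de <- structure(
    data.frame(gene_id = c("a", "b", "c", "d"),
               t = c(2, 2, 2, 2),
               p = c(0.04, 0.04, 0.2, 0.001),
               log2fc = c(1.0, 0.5, 3, -2),
               p_bh = rep(0.2, 4), q = rep(0.2, 4),
               stringsAsFactors = FALSE),
    class = c("de_result", "data.frame")
  )
  expect_equal(volcano_select(de), c("a", "d")) # |log2fc| >= 1 inclusive
  expect_equal(volcano_select(de[0, ]), character(0))
})
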