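# Centroid statistics for nearest-shrunken-centroids on a fixed
# training set. x: genes x samples, labels: factor with 2 levels.
nsc_stats <- function(x, labels) {
  lv <- levels(labels)
  n <- ncol(x)
  nk <- table(labels)[lv]
  xbar <- rowMeans(x)
  cent <- vapply(lv, function(l) rowMeans(x[, labels == l, drop = FALSE]),
                 numeric(nrow(x)))
  if (is.null(dim(cent))) cent <- matrix(cent, nrow = 1, dimnames = list(NULL, lv))
  ss <- 0
  for (l in lv) {
    sub <- x[, labels == l, drop = FALSE]
    ss <- ss + rowSums((sub - cent[, l])^2)
  }
  s <- sqrt(ss / (n - length(lv)))
  # fudge factor; floored so degenerate all-zero-variance toys stay finite
  s0 <- max(median(s), 1e-8)
  mk <- sqrt(pmax(1 / as.numeric(nk) - 1 / n, 0))
  d <- sweep(cent - xbar, 2, mk, "/") / (s + s0)
  list(levels = lv, nk = nk, xbar = xbar, cent = cent, s = s, s0 = s0,
       mk = mk, d = d)
}

nsc_shrink <- function(stats, delta) {
  d <- stats$d
  sign(d) * pmax(abs(d) - delta, 0)
}

nsc_predict_raw <- function(stats, dshr, newx, priors) {
  # shrunken class centroids
  cent_shr <- stats$xbar + sweep(dshr, 2, stats$mk, "*") * (stats$s + stats$s0)
  denom <- (stats$s + stats$s0)^2
  scores <- vapply(seq_along(stats$levels), function(k) {
    colSums((newx - cent_shr[, k])^2 / denom) - 2 * log(priors[k])
  }, numeric(ncol(newx)))
  if (ncol(newx) == 1L) scores <- matrix(scores, nrow = 1)
  # ties go to the first class in level order
  lab <- stats$levels[max.col(-scores, ties.method = "first")]
  list(labels = lab, scores = scores)
}

#' Fit a nearest-shrunken-centroids (PAM) two-class gene classifier
#'
#' Class centroid differences from the overall centroid, standardized by
#' `m_k * (s_g + s0)` with `m_k = sqrt(1/n_k - 1/n)` and fudge factor
#' `s0 = median(s_g)`, are soft-thresholded by `delta`; genes whose
#' shrunken difference is zero in every class drop out of the
#' classifier. The shrinkage is chosen by K-fold cross-validated
#' misclassification over a `delta` grid: the largest `delta` attaining
#' the minimal CV error (i.e. the fewest genes at the best error).
#'
#' @param x an [expression_matrix()] or genes x samples matrix.
#' @param labels two-level factor, one label per sample, each class with
#'   at least 3 samples.
#' @param delta_grid shrinkage grid; default 30 equal steps from 0 to
#'   the largest standardized centroid difference.
#' @param n_folds CV folds (reduced to leave-one-out when a class has
#'   fewer samples than folds).
#' @param priors class priors, default equal.
#' @param seed optional seed for the CV fold assignment.
#' @return An object of class `shrunken_centroids`: selected `delta`,
#'   `surviving_genes`, the CV error curve (`cv`), and the centroid
#'   statistics needed for prediction.
#' @export
fit_shrunken_centroids <- function(x, labels, delta_grid = NULL,
                                   n_folds = 10L, priors = c(0.5, 0.5),
                                   seed = NULL) {
  vals <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  gene_ids <- rownames(vals) %||% paste0("g", seq_len(nrow(vals)))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("exactly 2 classes required")
  if (any(table(labels) < 3)) stop("each class needs at least 3 samples")
  if (length(labels) != ncol(vals)) stop("one label per sample required")
  stats <- nsc_stats(vals, labels)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(stats$d)), length.out = 30)
  }
  n_folds <- min(n_folds, min(table(labels)))
  # stratified fold assignment
  assign_folds <- function() {
    fold <- integer(length(labels))
    for (l in levels(labels)) {
      idx <- which(labels == l)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    fold
  }
  fold <- if (is.null(seed)) assign_folds() else local_seed(seed, assign_folds())
  errs <- matrix(0, length(delta_grid), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    st <- nsc_stats(vals[, tr, drop = FALSE], labels[tr])
    newx <- vals[, !tr, drop = FALSE]
    truth <- labels[!tr]
    for (di in seq_along(delta_grid)) {
      pr <- nsc_predict_raw(st, nsc_shrink(st, delta_grid[di]), newx, priors)
      errs[di, f] <- sum(pr$labels != as.character(truth))
    }
  }
  cv_err <- rowSums(errs) / length(labels)
  surviving <- vapply(delta_grid, function(dl) {
    sum(rowSums(abs(nsc_shrink(stats, dl)) > 0) > 0)
  }, numeric(1))
  best <- max(which(cv_err == min(cv_err)))
  delta <- delta_grid[best]
  dshr <- nsc_shrink(stats, delta)
  surv_genes <- gene_ids[rowSums(abs(dshr) > 0) > 0]
  structure(list(levels = stats$levels, gene_ids = gene_ids, stats = stats,
                 delta = delta, dshr = dshr, priors = priors,
                 surviving_genes = surv_genes,
                 cv = data.frame(delta = delta_grid, cv_error = cv_err,
                                 n_genes = surviving)),
            class = "shrunken_centroids")
}

#' @export
print.shrunken_centroids <- function(x, ...) {
  cat("shrunken_centroids classifier: classes ",
      paste(x$levels, collapse = " vs "), "; delta = ", signif(x$delta, 4),
      "; ", length(x$surviving_genes), " surviving gene(s); CV error ",
      signif(x$cv$cv_error[x$cv$delta == x$delta][1], 3), "\n", sep = "")
  invisible(x)
}

#' Classify a sample profile with a shrunken-centroids model
#'
#' Standardized squared distance to each shrunken centroid minus
#' `2 log(prior)`; smallest score wins, ties to the first class in level
#' order. All model genes must be present (no imputation).
#'
#' @param model a [fit_shrunken_centroids()] fit.
#' @param profile named numeric vector (a single sample) or genes x
#'   samples matrix covering the model's genes.
#' @return A list with `label` (character vector) and `scores`
#'   (samples x classes discriminant matrix).
#' @export
predict_class <- function(model, profile) {
  stopifnot(inherits(model, "shrunken_centroids"))
  if (is.null(dim(profile))) {
    profile <- matrix(profile, ncol = 1,
                      dimnames = list(names(profile), NULL))
  }
  missing_g <- setdiff(model$gene_ids, rownames(profile))
  if (length(missing_g) > 0) {
    stop("profile is missing model gene(s): ",
         paste(head(missing_g, 5), collapse = ", "))
  }
  newx <- profile[model$gene_ids, , drop = FALSE]
  pr <- nsc_predict_raw(model$stats, model$dshr, newx, model$priors)
  colnames(pr$scores) <- model$levels
  list(label = pr$labels, scores = pr$scores)
}

#' @export
predict.shrunken_centroids <- function(object, newdata, ...) {
  predict_class(object, newdata)$label
}

#' Per-gene two-sample differential expression
#'
#' Two-sample t-test per gene (pooled variance by default, Welch
#' optional), log2 fold change = mean(A) - mean(B),
#' Benjamini-Hochberg adjusted p-values and Storey q-values (lambda =
#' 0.5 plug-in). Genes constant in both groups with equal means get
#' `t = 0, p = 1`.
#'
#' @param x an [expression_matrix()] or genes x samples matrix.
#' @param group_a,group_b sample ids (or column indices), at least 2
#'   each, disjoint interpretation is the caller's responsibility.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return A data.frame of class `de_result`: `gene_id`, `t`, `p`,
#'   `log2fc`, `p_bh`, `q`.
#' @export
differential_expression <- function(x, group_a, group_b, var_equal = TRUE) {
  vals <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  ids <- if (inherits(x, "expression_matrix")) x$gene_ids else rownames(vals) %||% paste0("g", seq_len(nrow(vals)))
  universe <- if (inherits(x, "expression_matrix")) x$sample_ids else colnames(vals) %||% as.character(seq_len(ncol(vals)))
  ia <- resolve_idx(group_a, universe, "sample")
  ib <- resolve_idx(group_b, universe, "sample")
  na <- length(ia); nb <- length(ib)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples")
  a <- vals[, ia, drop = FALSE]
  b <- vals[, ib, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  fc <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- ifelse(se > 0, fc / se, ifelse(abs(fc) < 1e-12, 0, sign(fc) * Inf))
  p <- ifelse(is.finite(tstat), 2 * pt(-abs(tstat), df), 0)
  p[tstat == 0 & se == 0] <- 1
  out <- data.frame(gene_id = ids, t = tstat, p = p, log2fc = fc,
                    p_bh = p.adjust(p, "BH"), q = storey_q(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

# Storey q-values with the lambda = 0.5 plug-in estimate of pi0.
storey_q <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- cummin(pi0 * p[o] * m / rank(p, ties.method = "max")[o])
  pmin(q, 1)
}

#' Volcano selection of differentially expressed genes
#'
#' Genes significant at the raw p cutoff AND changed by at least the
#' given fold (boundary inclusive on the fold change).
#'
#' @param de a [differential_expression()] result.
#' @param p_cut raw p-value cutoff (default 0.05).
#' @param fc_cut fold-change cutoff on the natural scale (default 2,
#'   i.e. |log2 FC| >= 1).
#' @return Character vector of selected gene ids (possibly empty).
#' @export
volcano_select <- function(de, p_cut = 0.05, fc_cut = 2) {
  stopifnot(inherits(de, "de_result"))
  de$gene_id[de$p < p_cut & abs(de$log2fc) >= log2(fc_cut)]
}
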