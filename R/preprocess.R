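#' Low-expression filter specification
#'
#' @param noise_threshold log2 intensity treated as the noise floor;
#'   `NULL` means the data-driven default, the 20th percentile of all
#'   matrix values (the array-derived noise estimate is not recoverable
#'   from a processed matrix, so the floor is a parameter).
#' @param min_expressed_fraction a gene is kept if it exceeds the noise
#'   threshold in at least this fraction of samples (boundary inclusive).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(noise_threshold = NULL, min_expressed_fraction = 0.10) {
  if (!is.null(noise_threshold) &&
      (is.na(noise_threshold) || is.nan(noise_threshold) ||
         noise_threshold == Inf)) {
    stop("noise_threshold must be a number or -Inf (no filtering), or NULL ",
         "for the data-driven default")
  }
  if (!(min_expressed_fraction > 0 && min_expressed_fraction <= 1)) {
    stop("min_expressed_fraction must lie in (0, 1]")
  }
  structure(list(noise_threshold = noise_threshold,
                 min_expressed_fraction = min_expressed_fraction),
            class = "filter_spec")
}

#' Remove genes expressed only at noise level
#'
#' Retains exactly the genes whose value exceeds the noise threshold in
#' at least `ceiling(min_expressed_fraction * n_samples)` samples; the
#' sample set and retained gene order are unchanged.
#'
#' @param x an [expression_matrix()].
#' @param spec a [filter_spec()].
#' @return The filtered `expression_matrix`. The applied threshold and
#'   the ids of removed genes are attached as attributes
#'   `noise_threshold` and `removed_genes`.
#' @export
filter_low_expression <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "expression_matrix"), inherits(spec, "filter_spec"))
  if (nrow(x$values) == 0 || ncol(x$values) == 0) stop("empty expression matrix")
  thr <- spec$noise_threshold
  if (is.null(thr)) thr <- as.numeric(quantile(x$values, 0.20))
  need <- ceiling(spec$min_expressed_fraction * ncol(x$values))
  keep <- rowSums(x$values > thr) >= need
  if (!any(keep)) {
    stop("empty result: no gene exceeds the noise threshold (", thr,
         ") in at least ", need, " samples")
  }
  out <- em_subset(x, genes = which(keep))
  attr(out, "noise_threshold") <- thr
  attr(out, "removed_genes") <- x$gene_ids[!keep]
  out
}

#' Collapse probes to one representative per gene symbol
#'
#' For every symbol measured by several probes, the probe whose profile
#' has the highest Pearson correlation with the per-sample median of all
#' the symbol's probes is retained; singleton symbols pass through.
#' Ties are broken by lexicographic gene id; zero-variance probes get
#' correlation -Inf and are never chosen unless every candidate is
#' zero-variance (then lexicographic). Probes must all carry a symbol --
#' remove unannotated probes first.
#'
#' @param x an [expression_matrix()] with `gene_symbols`.
#' @return An `expression_matrix` with one row per distinct symbol,
#'   original row order preserved.
#' @export
collapse_probes <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.null(x$gene_symbols)) stop("collapse_probes requires gene_symbols")
  if (anyNA(x$gene_symbols) || any(x$gene_symbols == "")) {
    stop("probes without a gene symbol must be removed before collapsing")
  }
  groups <- split(seq_along(x$gene_ids), x$gene_symbols)
  keep <- integer(length(groups))
  j <- 0L
  for (idx in groups) {
    j <- j + 1L
    if (length(idx) == 1L) {
      keep[j] <- idx
      next
    }
    sub <- x$values[idx, , drop = FALSE]
    med <- apply(sub, 2, median)
    cors <- vapply(seq_along(idx), function(i) {
      v <- sub[i, ]
      if (sd(v) < 1e-12 || sd(med) < 1e-12) -Inf else cor(v, med)
    }, numeric(1))
    best <- which(cors == max(cors))
    if (length(best) > 1) {
      best <- best[order(x$gene_ids[idx[best]])[1]]
    }
    keep[j] <- idx[best]
  }
  em_subset(x, genes = sort(keep))
}

#' Remove cohort-correlated location/scale batch effects
#'
#' Per gene and cohort, values are standardized by the cohort mean and
#' SD, then restored to the gene's grand mean and pooled within-cohort
#' SD. After adjustment every gene has equal cohort means and equal
#' cohort variances; applying the adjustment twice is a no-op. This is
#' the location/scale core of batch correction, without
#' empirical-Bayes shrinkage of the batch parameters -- exact for
#' additive-shift + multiplicative-scale batch structure.
#'
#' @param x an [expression_matrix()].
#' @param cohort per-sample cohort labels (character/factor, length =
#'   number of samples); every cohort needs at least 2 samples.
#' @return The adjusted `expression_matrix`.
#' @export
adjust_batch <- function(x, cohort) {
  stopifnot(inherits(x, "expression_matrix"))
  cohort <- as.character(cohort)
  if (length(cohort) != ncol(x$values)) {
    stop("cohort must have one label per sample")
  }
  sizes <- table(cohort)
  if (any(sizes < 2)) {
    stop("cohort(s) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "),
         "; merge them with another cohort or exclude those samples")
  }
  v <- x$values
  n <- ncol(v)
  cohorts <- names(sizes)
  C <- length(cohorts)
  grand_mean <- rowMeans(v)
  cmeans <- matrix(0, nrow(v), C)
  cvars <- matrix(0, nrow(v), C)
  for (j in seq_len(C)) {
    cols <- which(cohort == cohorts[j])
    sub <- v[, cols, drop = FALSE]
    cm <- rowMeans(sub)
    cmeans[, j] <- cm
    cvars[, j] <- rowSums((sub - cm)^2) / (length(cols) - 1)
  }
  nc <- as.numeric(sizes[cohorts])
  pooled_sd <- sqrt(as.vector(cvars %*% (nc - 1)) / (n - C))
  out <- v
  for (j in seq_len(C)) {
    cols <- which(cohort == cohorts[j])
    csd <- sqrt(cvars[, j])
    z <- (v[, cols, drop = FALSE] - cmeans[, j])
    ok <- csd > 1e-12
    z[ok, ] <- z[ok, , drop = FALSE] / csd[ok] * pooled_sd[ok]
    z[!ok, ] <- 0
    out[, cols] <- z + grand_mean
  }
  expression_matrix(out, gene_ids = x$gene_ids, sample_ids = x$sample_ids,
                    gene_symbols = x$gene_symbols)
}

#' Run the full preprocessing chain
#'
#' Noise filter, optional probe collapse, optional cohort batch
#' adjustment, in that order.
#'
#' @param x an [expression_matrix()].
#' @param cohort per-sample cohort labels (required unless
#'   `skip_batch`).
#' @param spec a [filter_spec()].
#' @param skip_collapse,skip_batch stage switches.
#' @return The preprocessed `expression_matrix` with attribute `report`,
#'   a character vector describing genes removed at each step.
#' @export
preprocess_expression <- function(x, cohort = NULL, spec = filter_spec(),
                                  skip_collapse = FALSE, skip_batch = FALSE) {
  n0 <- nrow(x$values)
  x <- filter_low_expression(x, spec)
  report <- sprintf("noise filter: %d of %d genes removed (threshold %.4g)",
                    n0 - nrow(x$values), n0, attr(x, "noise_threshold"))
  if (!skip_collapse && !is.null(x$gene_symbols)) {
    n1 <- nrow(x$values)
    x <- collapse_probes(x)
    report <- c(report, sprintf("probe collapse: %d probes merged into %d symbols",
                                n1, nrow(x$values)))
  }
  if (!skip_batch) {
    if (is.null(cohort)) stop("cohort labels required for batch adjustment")
    x <- adjust_batch(x, cohort)
    report <- c(report, "batch adjustment: cohort location/scale removed")
  }
  attr(x, "report") <- report
  x
}
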