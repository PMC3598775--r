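# Chi-square statistics of every candidate covariate against a binary
# label, with a shared set of label permutations: returns per-covariate
# Monte-Carlo p-values and the min-p (Westfall-Young style) globally
# adjusted p for the node. Discreteness- and correlation-aware, unlike
# plain Bonferroni.
node_test_all <- function(data, y, n_perm) {
  y01 <- as.numeric(y == levels(y)[1])
  n <- length(y01)
  ne <- sum(y01)
  cov_names <- names(data)
  blocks <- list()
  for (nm in cov_names) {
    v <- droplevels(as.factor(data[[nm]]))
    if (nlevels(v) < 2) next
    m <- stats::model.matrix(~ v - 1)
    blocks[[nm]] <- m
  }
  if (length(blocks) == 0) return(NULL)
  Mall <- do.call(cbind, blocks)
  cov_of <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  nl <- colSums(Mall)
  e <- nl * ne / n
  d <- 1 / e + 1 / (nl - e)

  stat_from_counts <- function(o) {
    # full 2 x L chi-square per covariate from early counts per level
    contrib <- (o - e)^2 * d
    vapply(names(blocks), function(nm) sum(contrib[cov_of == nm]), numeric(1))
  }

  s_obs <- stat_from_counts(as.vector(crossprod(Mall, y01)))
  Yp <- replicate(n_perm, sample(y01))
  O <- crossprod(Mall, Yp) # levels x n_perm
  contrib <- (O - e)^2 * d
  Sperm <- rowsum(contrib, cov_of) # covariates x n_perm (alphabetical rows)
  Sperm <- Sperm[names(blocks), , drop = FALSE]

  J <- length(blocks)
  p_obs <- (1 + rowSums(Sperm >= s_obs - 1e-12)) / (n_perm + 1)
  # per-permutation p-values (rank within each covariate's null sample)
  Pperm <- t(apply(Sperm, 1, function(s) rank(-s, ties.method = "max") / n_perm))
  minp_perm <- apply(Pperm, 2, min)
  p_adj <- (1 + sum(minp_perm <= min(p_obs) + 1e-12)) / (n_perm + 1)
  list(p_obs = setNames(as.numeric(p_obs), names(blocks)),
       p_adj = p_adj, n_candidates = J)
}

chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e, na.rm = TRUE)
}

# Best binary partition of the covariate's observed categories:
# exhaustive over subsets for <= 8 categories, else greedy on categories
# ordered by event (second label level) rate.
best_subset_split <- function(v, y, min_leaf) {
  v <- droplevels(as.factor(v))
  lv <- levels(v)
  k <- length(lv)
  cand <- list()
  if (k <= 8) {
    for (code in seq_len(2^(k - 1) - 1)) {
      cand[[length(cand) + 1]] <- lv[as.logical(bitwAnd(code, 2^(seq_len(k) - 1)))]
    }
  } else {
    rate <- vapply(lv, function(l) mean(y[v == l] == levels(y)[2]), numeric(1))
    ord <- lv[order(rate)]
    for (i in seq_len(k - 1)) cand[[i]] <- ord[seq_len(i)]
  }
  best <- NULL
  best_stat <- -Inf
  for (subset in cand) {
    left <- v %in% subset
    if (sum(left) < min_leaf || sum(!left) < min_leaf) next
    stat <- chisq_stat(table(factor(left, c(TRUE, FALSE)), y))
    if (stat > best_stat) {
      best_stat <- stat
      best <- subset
    }
  }
  list(subset = best, stat = best_stat)
}

grow_node <- function(data, y, alpha, min_leaf, n_perm, trim, adjust,
                      depth, node_id) {
  counts <- table(y)
  props <- counts / sum(counts)
  leaf <- function() {
    list(id = node_id, is_leaf = TRUE, n = length(y), class_counts = counts,
         class_props = props,
         prediction = names(counts)[which.max(counts)], depth = depth)
  }
  if (length(y) < 2 * min_leaf || length(unique(y)) < 2) return(leaf())
  tst <- node_test_all(data, y, n_perm)
  if (is.null(tst)) return(leaf())
  p_adj <- if (adjust == "bonferroni") {
    min(1, min(tst$p_obs) * tst$n_candidates)
  } else {
    tst$p_adj
  }
  shadow_p <- pmin(1, tst$p_obs * tst$n_candidates)
  shadow <- names(tst$p_obs)[shadow_p >= alpha & shadow_p < trim]
  if (p_adj >= alpha) {
    nd <- leaf()
    nd$shadow_covariates <- shadow
    return(nd)
  }
  var <- names(tst$p_obs)[which.min(tst$p_obs)]
  sp <- best_subset_split(data[[var]], y, min_leaf)
  if (is.null(sp$subset)) {
    nd <- leaf()
    nd$shadow_covariates <- shadow
    return(nd)
  }
  left <- data[[var]] %in% sp$subset
  left_node <- grow_node(data[left, , drop = FALSE], droplevels(y[left]),
                         alpha, min_leaf, n_perm, trim, adjust,
                         depth + 1, node_id * 2L)
  right_node <- grow_node(data[!left, , drop = FALSE], droplevels(y[!left]),
                          alpha, min_leaf, n_perm, trim, adjust,
                          depth + 1, node_id * 2L + 1L)
  list(id = node_id, is_leaf = FALSE, n = length(y), class_counts = counts,
       class_props = props, covariate = var, p_adjusted = p_adj,
       left_levels = sp$subset, shadow_covariates = setdiff(shadow, var),
       children = list(left = left_node, right = right_node), depth = depth)
}

#' Fit a conditional inference tree for a binary outcome
#'
#' Recursive binary partitioning: at each node the association between
#' every candidate categorical covariate and the label is measured by a
#' Monte-Carlo chi-square permutation test on a shared set of label
#' permutations; the node's global p-value is the min-p
#' (permutation-based, Westfall-Young style) multiplicity adjustment
#' over the candidates, which respects the discreteness and correlation
#' of the individual tests (`adjust = "bonferroni"` gives the classical,
#' more conservative alternative). The node splits on the smallest-p
#' covariate only if the adjusted p is below `alpha`; the binary split
#' is the category subset maximizing the chi-square statistic
#' (exhaustive for up to 8 categories, otherwise greedy on category
#' event rates). Recursion stops when no covariate is significant or a
#' child would fall below `min_leaf`. Covariates with Bonferroni p in
#' `[alpha, trim)` are recorded per node as greyed "shadow" candidates
#' for display; they never split.
#'
#' @param data data.frame of factor covariates (one row per sample).
#' @param labels binary factor outcome.
#' @param alpha split significance level (default 0.05).
#' @param min_leaf minimum samples per leaf (default 7).
#' @param n_perm Monte-Carlo label permutations per node (default 9999).
#' @param trim display-trim level (default 0.5).
#' @param adjust `"minp"` (default) or `"bonferroni"`.
#' @param seed optional seed (permutation tests draw from the RNG).
#' @return An object of class `cond_tree`.
#' @export
fit_conditional_tree <- function(data, labels, alpha = 0.05, min_leaf = 7L,
                                 n_perm = 9999L, trim = 0.5,
                                 adjust = c("minp", "bonferroni"),
                                 seed = NULL) {
  stopifnot(is.data.frame(data))
  adjust <- match.arg(adjust)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(data)) stop("one label per row required")
  data <- as.data.frame(lapply(data, as.factor), stringsAsFactors = TRUE)
  grow <- function() {
    grow_node(data, labels, alpha, as.integer(min_leaf), as.integer(n_perm),
              trim, adjust, depth = 0L, node_id = 1L)
  }
  root <- if (is.null(seed)) grow() else local_seed(seed, grow())
  structure(list(root = root, levels = levels(labels), alpha = alpha,
                 min_leaf = as.integer(min_leaf), trim = trim,
                 adjust = adjust),
            class = "cond_tree")
}

tree_route <- function(node, row) {
  while (!node$is_leaf) {
    v <- as.character(row[[node$covariate]])
    node <- if (v %in% node$left_levels) node$children$left else node$children$right
  }
  node
}

#' Predict with a conditional inference tree
#'
#' Each sample is routed to a leaf and assigned the leaf's majority
#' label.
#'
#' @param object a `cond_tree`.
#' @param newdata data.frame with the covariates the tree was grown on.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.cond_tree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i) {
    tree_route(object$root, newdata[i, , drop = FALSE])$prediction
  }, character(1))
}

print_node <- function(node, indent = "") {
  if (node$is_leaf) {
    cat(indent, "* leaf n=", node$n, " -> ", node$prediction, " (",
        paste(sprintf("%s:%.2f", names(node$class_props), node$class_props),
              collapse = ", "), ")\n", sep = "")
  } else {
    cat(indent, "[", node$covariate, " in {",
        paste(node$left_levels, collapse = ","), "}] p_adj=",
        signif(node$p_adjusted, 3), " n=", node$n, "\n", sep = "")
    if (length(node$shadow_covariates %||% character(0)) > 0) {
      cat(indent, "  (greyed: ", paste(node$shadow_covariates, collapse = ", "),
          ")\n", sep = "")
    }
    print_node(node$children$left, paste0(indent, "  "))
    print_node(node$children$right, paste0(indent, "  "))
  }
}

#' @export
print.cond_tree <- function(x, ...) {
  cat("conditional inference tree (alpha=", x$alpha, ", min_leaf=",
      x$min_leaf, ", adjust=", x$adjust, ")\n", sep = "")
  print_node(x$root)
  invisible(x)
}

tree_depth <- function(node) {
  if (node$is_leaf) return(0L)
  1L + max(tree_depth(node$children$left), tree_depth(node$children$right))
}
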