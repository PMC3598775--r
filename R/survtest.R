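#' Kaplan-Meier estimate of a survival distribution
#'
#' Product-limit estimator with the standard convention that events
#' precede censorings at tied times (subjects censored at an event time
#' remain in the risk set for that event).
#'
#' @param times non-negative event/censoring times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return An object of class `survival_curve`: `event_times` (distinct
#'   times with at least one event, increasing), `survival` (step value
#'   just after each event time), `at_risk`, `events` (counts at each
#'   event time), and `n`.
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times)
  events <- as.integer(events)
  if (length(times) == 0) stop("km_estimate: empty input")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0L, 1L)))
  et <- sort(unique(times[events == 1L]))
  at_risk <- integer(length(et))
  d <- integer(length(et))
  for (i in seq_along(et)) {
    at_risk[i] <- sum(times >= et[i])
    d[i] <- sum(times == et[i] & events == 1L)
  }
  surv <- cumprod(1 - d / at_risk)
  structure(list(event_times = et, survival = surv, at_risk = at_risk,
                 events = d, n = length(times)),
            class = "survival_curve")
}

#' Evaluate a survival curve at arbitrary times
#' @param curve a `survival_curve`.
#' @param t times at which to evaluate (right-continuous step function).
#' @param left if `TRUE`, return the left limit S(t-).
#' @return Survival probabilities.
#' @export
km_survival_at <- function(curve, t, left = FALSE) {
  stopifnot(inherits(curve, "survival_curve"))
  s <- c(1, curve$survival)
  idx <- if (left) {
    findInterval(t, curve$event_times, left.open = TRUE)
  } else {
    findInterval(t, curve$event_times)
  }
  s[idx + 1]
}

#' Two-group logrank test
#'
#' Standard (unweighted) logrank: at each distinct event time the
#' observed minus hypergeometric-expected events in group A are
#' accumulated; the statistic is `(sum(O-E))^2 / sum(Var)`, referred to
#' a chi-square with 1 df. With zero events in total the test is
#' undefined and `p = 1` is returned with a warning.
#'
#' @param times_a,events_a group A follow-up times and event indicators.
#' @param times_b,events_b group B likewise.
#' @return A list with `chi_square` and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop("logrank_test: both groups must be non-empty")
  }
  times <- c(times_a, times_b)
  events <- c(as.integer(events_a), as.integer(events_b))
  grp_a <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
  et <- sort(unique(times[events == 1L]))
  if (length(et) == 0) {
    warning("logrank_test: no events in either group; p = 1 by convention")
    return(list(chi_square = 0, p = 1))
  }
  sa <- sort(times[grp_a])
  st <- sort(times)
  n_at <- length(st) - findInterval(et, st, left.open = TRUE)
  na_at <- length(sa) - findInterval(et, sa, left.open = TRUE)
  d <- vapply(et, function(tt) sum(events == 1L & times == tt), numeric(1))
  da <- vapply(et, function(tt) sum(events == 1L & times == tt & grp_a), numeric(1))
  keep <- n_at > 1
  o_minus_e <- sum(da - d * na_at / n_at)
  v <- sum((d * (na_at / n_at) * (1 - na_at / n_at) *
              (n_at - d) / (n_at - 1))[keep])
  if (v <= 0) {
    warning("logrank_test: zero variance (no informative event times); p = 1")
    return(list(chi_square = 0, p = 1))
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE))
}

#' All-pairs logrank p-values
#'
#' @param groups list of groups, each a list with elements `times` and
#'   `events`.
#' @return A data.frame with columns `i`, `j` (i < j, stable order),
#'   `chi_square`, `p` -- one row per unordered pair.
#' @export
pairwise_logrank <- function(groups) {
  if (length(groups) < 2) stop("pairwise_logrank needs at least 2 groups")
  pairs <- combn(length(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    a <- groups[[ij[1]]]
    b <- groups[[ij[2]]]
    lr <- withCallingHandlers(
      logrank_test(a$times, a$events, b$times, b$events),
      warning = function(w) invokeRestart("muffleWarning")
    )
    c(lr$chi_square, lr$p)
  })
  data.frame(i = pairs[1, ], j = pairs[2, ],
             chi_square = res[1, ], p = res[2, ])
}

#' Size-matched random groups (sampling with replacement)
#'
#' Builds one random group per requested size by sampling sample ids
#' *with replacement*, so groups may overlap and repeat ids -- mirroring
#' the overlap structure of biclusters. Used as the null for the
#' survival-separation test.
#'
#' @param sample_ids pool of ids.
#' @param sizes multiset of group sizes (all >= 1).
#' @param seed optional seed (otherwise the session RNG is used).
#' @return A list of character vectors, one per size.
#' @export
random_size_matched_groups <- function(sample_ids, sizes, seed = NULL) {
  if (length(sizes) == 0) stop("sizes must be non-empty")
  if (any(sizes < 1)) stop("group sizes must be >= 1")
  draw <- function() lapply(sizes, function(s) sample(sample_ids, s, replace = TRUE))
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

survival_groups <- function(sample_sets, clinical) {
  idx <- match(unlist(sample_sets), clinical$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) without survival data: ",
         paste(head(unlist(sample_sets)[is.na(idx)], 3), collapse = ", "))
  }
  lapply(sample_sets, function(ids) {
    i <- match(ids, clinical$sample_id)
    list(times = clinical$dfs_time_years[i], events = clinical$dfs_event[i])
  })
}

#' Do biclusters separate survival more than size-matched random groups?
#'
#' Computes the all-pairs logrank p-values over the biclusters, then the
#' same quantity for each of `n_rand` random size-matched groupings of
#' the same patients (sampling with replacement, same size multiset).
#' The reported `ks_statistic` is the two-sample Kolmogorov-Smirnov
#' distance between the observed p-values and the pooled null p-values;
#' a large value indicates the bicluster survival curves are more widely
#' separated than expected by chance. Because pairwise p-values within
#' one grouping are strongly dependent (groups share patients), the
#' asymptotic KS p-value would be badly anti-conservative; `ks_p` is
#' therefore calibrated by exchangeability: each randomization's own
#' pair p-values are compared against the pool of the remaining
#' randomizations, and `ks_p` is the rank of the observed KS distance in
#' that empirical null, `(1 + #{D_r >= D_obs}) / (n_rand + 1)` --
#' uniform under the null by construction, with resolution
#' `1/(n_rand + 1)`.
#'
#' @param bcs a [bicluster_set()] (at least 2 biclusters).
#' @param clinical a [clinical_table()] covering every member sample.
#' @param n_rand number of randomizations (also sets the p-value
#'   resolution).
#' @param seed optional seed for the randomizations.
#' @return An object of class `separation_test`: `observed_p_values`,
#'   `null_p_values` (pooled), `ks_statistic`, `ks_p`,
#'   `n_randomizations`.
#' @export
separation_test <- function(bcs, clinical, n_rand = 20L, seed = NULL) {
  stopifnot(inherits(bcs, "bicluster_set"), inherits(clinical, "clinical_table"))
  if (length(bcs) < 2) stop("separation_test needs at least 2 biclusters")
  sets <- lapply(bcs$biclusters, `[[`, "sample_ids")
  obs_groups <- survival_groups(sets, clinical)
  observed <- pairwise_logrank(obs_groups)$p
  sizes <- lengths(sets)
  run <- function() {
    lapply(seq_len(n_rand), function(r) {
      rg <- random_size_matched_groups(clinical$sample_id, sizes)
      pairwise_logrank(survival_groups(rg, clinical))$p
    })
  }
  null_sets <- if (is.null(seed)) run() else local_seed(seed, run())
  null_p <- unlist(null_sets)
  ks_stat <- function(a, b) {
    unname(suppressWarnings(ks.test(a, b))$statistic)
  }
  d_obs <- ks_stat(observed, null_p)
  d_null <- vapply(seq_len(n_rand), function(r) {
    ks_stat(null_sets[[r]], unlist(null_sets[-r]))
  }, numeric(1))
  ks_p <- (1 + sum(d_null >= d_obs - 1e-12)) / (n_rand + 1)
  structure(list(observed_p_values = observed, null_p_values = null_p,
                 ks_statistic = d_obs, ks_p = ks_p,
                 n_randomizations = n_rand),
            class = "separation_test")
}

#' @export
print.separation_test <- function(x, ...) {
  cat("separation_test: ", length(x$observed_p_values), " observed pairs vs ",
      length(x$null_p_values), " null pairs (", x$n_randomizations,
      " randomizations)\n  KS statistic = ", signif(x$ks_statistic, 4),
      ", p = ", signif(x$ks_p, 4), "\n", sep = "")
  invisible(x)
}

#' Cox proportional hazards fit (plain or ridge-penalized)
#'
#' Maximizes the Breslow partial likelihood, minus `lambda * ||beta||^2`
#' when `lambda > 0` (via the `ridge()` penalty of a standard Cox
#' fitter, unscaled covariates). With `lambda = 0` the fit is ordinary
#' Cox PH with Wald p-values, a likelihood-ratio p and the score
#' statistic (which for a single binary covariate equals the logrank
#' chi-square).
#'
#' @param covariates numeric matrix or data.frame (samples x covariates).
#' @param times,events follow-up and event indicator.
#' @param lambda ridge penalty (>= 0).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_fit`: `coefficients`, `se`,
#'   `p_values`, `lrt_p`, `score_chisq` (lambda = 0 only), `lambda`,
#'   `converged`.
#' @export
cox_fit <- function(covariates, times, events, lambda = 0, ties = "breslow") {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(times), length(times) == length(events),
            lambda >= 0)
  y <- survival::Surv(as.numeric(times), as.integer(events))
  converged <- TRUE
  flag <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("converge|infinit|beta may be infinite|loglik", conditionMessage(w),
                ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  }
  if (lambda == 0) {
    if (any(apply(x, 2, sd) < 1e-12)) {
      stop("constant covariate not allowed in an unpenalized Cox fit")
    }
    fit <- flag(survival::coxph(y ~ x, ties = ties))
    sm <- summary(fit)
    coefs <- setNames(as.numeric(coef(fit)), colnames(x))
    se <- setNames(sm$coefficients[, "se(coef)"], colnames(x))
    pv <- setNames(sm$coefficients[, "Pr(>|z|)"], colnames(x))
    if (any(!is.finite(coefs)) || any(abs(coefs) > 20)) converged <- FALSE
    out <- list(coefficients = coefs, se = se, p_values = pv,
                lrt_p = unname(sm$logtest["pvalue"]),
                score_chisq = unname(sm$sctest["test"]),
                lambda = 0, converged = converged)
  } else {
    # survival's ridge() penalizes theta/2 * sum(beta^2)
    fit <- flag(survival::coxph(y ~ survival::ridge(x, theta = 2 * lambda,
                                                    scale = FALSE),
                                ties = ties))
    coefs <- setNames(as.numeric(coef(fit)), colnames(x))
    se <- sqrt(diag(fit$var))[seq_len(ncol(x))]
    out <- list(coefficients = coefs, se = setNames(se, colnames(x)),
                p_values = setNames(rep(NA_real_, ncol(x)), colnames(x)),
                lrt_p = NA_real_, score_chisq = NA_real_,
                lambda = lambda, converged = converged)
  }
  structure(out, class = "cox_fit")
}

#' Genes whose expression predicts survival within a bicluster
#'
#' Univariate Cox PH per gene, restricted to the bicluster's member
#' samples; genes with Wald p below the cutoff are returned. Genes that
#' are (near-)constant within the subgroup are skipped with a message.
#'
#' @param x an [expression_matrix()].
#' @param b a [bicluster()] with at least 10 member samples.
#' @param clinical a [clinical_table()].
#' @param p_cutoff significance cutoff (default 0.01).
#' @return A data.frame (`gene_id`, `coef`, `p`) of selected genes,
#'   possibly empty, ordered by p. The full per-gene results are
#'   attached as attribute `all`.
#' @export
select_survival_genes <- function(x, b, clinical, p_cutoff = 0.01) {
  stopifnot(inherits(x, "expression_matrix"), inherits(b, "bicluster"))
  if (length(b$sample_ids) < 10) {
    stop("select_survival_genes needs a bicluster with >= 10 samples")
  }
  idx <- match(b$sample_ids, clinical$sample_id)
  if (anyNA(idx)) stop("bicluster samples missing from clinical table")
  tt <- clinical$dfs_time_years[idx]
  ev <- clinical$dfs_event[idx]
  y <- survival::Surv(tt, ev)
  si <- resolve_idx(b$sample_ids, x$sample_ids, "sample")
  res <- lapply(seq_along(x$gene_ids), function(g) {
    v <- x$values[g, si]
    if (sd(v) < 1e-12) {
      message("select_survival_genes: skipping constant gene ", x$gene_ids[g])
      return(c(NA_real_, NA_real_))
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ v, ties = "breslow")),
      error = function(e) NULL
    )
    if (is.null(fit) || is.na(coef(fit))) return(c(NA_real_, NA_real_))
    sm <- summary(fit)$coefficients
    c(sm[1, "coef"], sm[1, "Pr(>|z|)"])
  })
  res <- do.call(rbind, res)
  all_df <- data.frame(gene_id = x$gene_ids, coef = res[, 1], p = res[, 2],
                       stringsAsFactors = FALSE)
  sel <- all_df[!is.na(all_df$p) & all_df$p < p_cutoff, , drop = FALSE]
  sel <- sel[order(sel$p), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "all") <- all_df
  sel
}
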