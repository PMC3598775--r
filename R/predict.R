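#' Dichotomize disease-free survival into early/late relapse
#'
#' Early relapse: a relapse event at or before the early cutoff. Late
#' relapse (good outcome): disease-free survival at or past the late
#' cutoff, whether the follow-up ends in an event or censoring.
#' Everything else -- including patients censored before the early
#' cutoff, who are not confirmed relapses -- is intermediate.
#'
#' @param clinical a [clinical_table()].
#' @param early_cutoff,late_cutoff boundaries in years (defaults 2, 8).
#' @return A factor with levels `early`, `late`, `intermediate`, named
#'   by sample id.
#' @export
dichotomize <- function(clinical, early_cutoff = 2, late_cutoff = 8) {
  stopifnot(inherits(clinical, "clinical_table"),
            early_cutoff < late_cutoff)
  tt <- clinical$dfs_time_years
  ev <- clinical$dfs_event
  lab <- ifelse(ev == 1 & tt <= early_cutoff, "early",
                ifelse(tt >= late_cutoff, "late", "intermediate"))
  setNames(factor(lab, levels = c("early", "late", "intermediate")),
           clinical$sample_id)
}

size_breaks <- c(-Inf, 10, 20, 40, Inf)
size_labels <- c("<10", "[10,20)", "[20,40)", ">=40")
age_breaks <- c(-Inf, 40, 50, 60, Inf)
age_labels <- c("<40", "[40,50)", "[50,60)", ">=60")

to_factor_na <- function(v, levels) {
  v <- as.character(v)
  v[is.na(v)] <- "NA"
  factor(v, levels = c(levels, if (any(v == "NA")) "NA"))
}

#' Encode clinical covariates (and bicluster membership) for prediction
#'
#' Categorical encoding: ER/PgR/LN status and grade as-is; tumour size
#' classed as `<10`, `[10,20)`, `[20,40)`, `>=40` mm; age classed as
#' `<40`, `[40,50)`, `[50,60)`, `>=60` years; one 0/1 factor per
#' bicluster. Missing values become an explicit `"NA"` level.
#'
#' @param clinical a [clinical_table()].
#' @param membership optional binary samples x biclusters matrix (row
#'   names = sample ids) adding one indicator column per bicluster.
#' @return A data.frame of factors with rownames = sample ids.
#' @export
encode_covariates <- function(clinical, membership = NULL) {
  stopifnot(inherits(clinical, "clinical_table"))
  if (any(!is.na(clinical$size_mm) & clinical$size_mm < 0) ||
      any(!is.na(clinical$age_years) & clinical$age_years < 0)) {
    stop("negative size_mm or age_years")
  }
  out <- data.frame(
    er_status = to_factor_na(clinical$er_status, clinical_vocab$er_status),
    pgr_status = to_factor_na(clinical$pgr_status, clinical_vocab$pgr_status),
    ln_status = to_factor_na(clinical$ln_status, clinical_vocab$ln_status),
    grade = to_factor_na(clinical$grade, clinical_vocab$grade),
    size_class = to_factor_na(
      as.character(cut(clinical$size_mm, size_breaks, size_labels,
                       right = FALSE)), size_labels),
    age_class = to_factor_na(
      as.character(cut(clinical$age_years, age_breaks, age_labels,
                       right = FALSE)), age_labels),
    row.names = clinical$sample_id
  )
  if (!is.null(membership)) {
    membership <- as.matrix(membership)
    if (is.null(rownames(membership))) {
      stop("membership matrix needs sample ids as row names")
    }
    idx <- match(clinical$sample_id, rownames(membership))
    if (anyNA(idx)) stop("membership matrix missing sample(s)")
    for (k in seq_len(ncol(membership))) {
      nm <- colnames(membership)[k] %||% paste0("bc", k)
      out[[nm]] <- factor(as.integer(membership[idx, k] > 0), levels = c(0, 1))
    }
  }
  out
}

#' Representative gene-expression profile of a bicluster (PC1)
#'
#' First principal axis of the bicluster's samples x genes submatrix
#' (samples as observations, genes as variables, columns centered),
#' with the sign fixed so that its correlation with the bicluster's mean
#' gene profile is non-negative. If the submatrix carries (essentially)
#' no variance the mean profile is returned with a warning.
#'
#' @param x an [expression_matrix()].
#' @param b a [bicluster()] with at least 2 samples and 2 genes.
#' @return Named numeric vector over the bicluster's genes.
#' @export
bicluster_pc1_profile <- function(x, b) {
  stopifnot(inherits(x, "expression_matrix"), inherits(b, "bicluster"))
  if (length(b$sample_ids) < 2 || length(b$gene_ids) < 2) {
    stop("bicluster_pc1_profile needs >= 2 samples and >= 2 genes")
  }
  gi <- resolve_idx(b$gene_ids, x$gene_ids, "gene")
  si <- resolve_idx(b$sample_ids, x$sample_ids, "sample")
  sub <- t(x$values[gi, si, drop = FALSE]) # samples x genes
  mean_profile <- colMeans(sub)
  centered <- sub - rep(mean_profile, each = nrow(sub))
  if (sum(centered^2) < 1e-12) {
    warning("bicluster ", b$id, ": zero-variance submatrix; returning mean profile")
    return(setNames(mean_profile, b$gene_ids))
  }
  pc <- prcomp(sub, center = TRUE, scale. = FALSE)
  profile <- pc$rotation[, 1]
  r <- suppressWarnings(cor(profile, mean_profile))
  if (!is.na(r) && r < 0) profile <- -profile
  setNames(profile, b$gene_ids)
}

#' Assign a test tumour to biclusters by profile correlation
#'
#' Pearson correlation between the tumour's expression (restricted to
#' each bicluster's genes) and that bicluster's PC1 profile; biclusters
#' with r above the threshold are returned (a tumour may match several).
#' When none passes the threshold the single best-correlated bicluster
#' is returned with attribute `fallback = TRUE`, so downstream
#' covariates are always defined.
#'
#' @param profile named numeric vector: the tumour's expression over
#'   (at least) all bicluster genes.
#' @param bcs a [bicluster_set()].
#' @param profiles list of PC1 profiles from [bicluster_pc1_profile()],
#'   one per bicluster, in id order.
#' @param threshold correlation threshold (default 0.9).
#' @return Integer vector of assigned bicluster ids, with attributes
#'   `correlations` (all K correlations) and `fallback`.
#' @export
assign_to_biclusters <- function(profile, bcs, profiles, threshold = 0.9) {
  stopifnot(inherits(bcs, "bicluster_set"),
            length(profiles) == length(bcs))
  rs <- vapply(seq_len(length(bcs)), function(k) {
    g <- bcs$biclusters[[k]]$gene_ids
    v <- profile[g]
    if (anyNA(v)) stop("profile is missing gene(s) of bicluster ", k)
    suppressWarnings(r <- cor(v, profiles[[k]]))
    if (is.na(r)) -Inf else r
  }, numeric(1))
  sel <- which(rs > threshold)
  fallback <- FALSE
  if (length(sel) == 0) {
    sel <- which.max(rs)
    fallback <- TRUE
  }
  structure(as.integer(sel), correlations = rs, fallback = fallback)
}

#' Ridge-penalized Cox risk scores for test samples
#'
#' Fits an L2-penalized Cox model on the training covariates with the
#' penalty chosen by 10-fold cross-validated partial likelihood, then
#' returns the linear predictor for the test covariates as a risk score
#' (higher = earlier expected relapse).
#'
#' @param train_x,test_x numeric model matrices (samples x covariates).
#' @param times,events training follow-up and event indicators; at
#'   least one event required.
#' @param n_folds CV folds (default 10).
#' @param seed optional seed for the fold assignment.
#' @return Numeric risk scores (one per test row) with attribute
#'   `lambda`, the selected penalty.
#' @export
ridge_cox_predict <- function(train_x, times, events, test_x,
                              n_folds = 10L, seed = NULL) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (sum(events) == 0) stop("ridge_cox_predict: training data has no events")
  y <- survival::Surv(as.numeric(times), as.integer(events))
  run <- function() sample(rep_len(seq_len(n_folds), nrow(train_x)))
  foldid <- if (is.null(seed)) run() else local_seed(seed, run())
  cv <- glmnet::cv.glmnet(train_x, y, family = "cox", alpha = 0,
                          foldid = foldid, standardize = TRUE)
  risk <- as.numeric(predict(cv, newx = test_x, s = "lambda.min"))
  attr(risk, "lambda") <- cv$lambda.min
  risk
}

#' Cumulative/dynamic time-dependent AUC at a horizon
#'
#' Probability that a subject with an event by time `horizon` receives a
#' higher risk score than a subject still event-free at `horizon`, with
#' inverse-probability-of-censoring weights from the Kaplan-Meier
#' estimate of the censoring distribution (cases weighted by
#' `1/G(T_i-)`). Ties in the score count 1/2.
#'
#' @param risk numeric risk scores (higher = higher risk).
#' @param times,events follow-up and event indicators.
#' @param horizon evaluation time.
#' @return AUC in \[0, 1\]; `NA` with a warning when there are no cases
#'   or no controls at the horizon.
#' @export
time_dependent_auc <- function(risk, times, events, horizon) {
  stopifnot(length(risk) == length(times), length(times) == length(events))
  cases <- which(times <= horizon & events == 1)
  controls <- which(times > horizon)
  if (length(cases) == 0 || length(controls) == 0) {
    warning("time_dependent_auc undefined at horizon ", horizon,
            ": no ", if (length(cases) == 0) "cases" else "controls")
    return(NA_real_)
  }
  cens_km <- km_estimate(times, 1 - events)
  g_case <- km_survival_at(cens_km, times[cases], left = TRUE)
  w <- 1 / pmax(g_case, 1e-8)
  rc <- sort(risk[controls])
  num <- 0
  for (i in seq_along(cases)) {
    r <- risk[cases[i]]
    below <- findInterval(r, rc, left.open = TRUE) # controls strictly below
    ties <- sum(rc == r)
    num <- num + w[i] * (below + 0.5 * ties)
  }
  num / (sum(w) * length(controls))
}

#' Cross-validated early-relapse prediction with and without biclusters
#'
#' Repeats `cfg$n_cv_splits` times: stratified 80/20 split of the
#' early/late-labeled patients (intermediates stay in the training pool
#' for biclustering but are excluded from supervised fitting and
#' evaluation); biclusters are searched on the training samples only;
#' test tumours are assigned to training biclusters by PC1-profile
#' correlation; then two predictors of early relapse are fitted with
#' clinical covariates only and with clinical + bicluster indicators --
#' a conditional inference tree (evaluated by early-relapse sensitivity)
#' and a ridge-penalized Cox model (evaluated by time-dependent AUC at
#' `cfg$auc_horizon_years`).
#'
#' Deterministic given `cfg$seed`: split s derives its stream from
#' `(seed, "crossval-split-s")`.
#'
#' @param x a preprocessed [expression_matrix()].
#' @param clinical a [clinical_table()] for the same samples.
#' @param cfg a [run_config()].
#' @return An object of class `cv_report`: `splits` (one row per split
#'   with sensitivities, specificities and AUCs for both covariate
#'   sets), `aggregate` (means/medians plus the paired sign-test p for
#'   the sensitivity improvement), and `predictions` (per split, the
#'   test ids with tree predictions and risk scores).
#' @export
cross_validate <- function(x, clinical, cfg) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(clinical, "clinical_table"),
            inherits(cfg, "run_config"))
  stopifnot(all(clinical$sample_id %in% x$sample_ids))
  labels <- dichotomize(clinical, cfg$early_cutoff_years, cfg$late_cutoff_years)
  early_ids <- names(labels)[labels == "early"]
  late_ids <- names(labels)[labels == "late"]
  if (length(early_ids) < 5 || length(late_ids) < 5) {
    stop("too few early/late labeled samples for cross-validation")
  }
  splits <- vector("list", cfg$n_cv_splits)
  preds <- vector("list", cfg$n_cv_splits)
  for (s in seq_len(cfg$n_cv_splits)) {
    split_seed <- stage_seed(cfg$seed, paste0("crossval-split-", s))
    res <- local_seed(split_seed, {
      test_ids <- NULL
      for (try in seq_len(10L)) {
        cand <- c(sample(early_ids, max(1, round(cfg$test_fraction * length(early_ids)))),
                  sample(late_ids, max(1, round(cfg$test_fraction * length(late_ids)))))
        if (any(labels[cand] == "early")) {
          test_ids <- cand
          break
        }
        message("cross_validate: redrawing split ", s, " (no early test sample)")
      }
      train_ids <- setdiff(clinical$sample_id, test_ids)
      run_split(x, clinical, labels, train_ids, test_ids, cfg, split_seed)
    })
    splits[[s]] <- res$row
    preds[[s]] <- res$pred
  }
  splits <- do.call(rbind, splits)
  splits <- cbind(split = seq_len(cfg$n_cv_splits), splits)
  improved <- splits$sens_bicluster > splits$sens_clinical
  worsened <- splits$sens_bicluster < splits$sens_clinical
  n_eff <- sum(improved) + sum(worsened)
  sign_p <- if (n_eff == 0) 1 else {
    binom.test(sum(improved), n_eff, 0.5, alternative = "greater")$p.value
  }
  aggregate <- list(
    sensitivity_clinical = mean(splits$sens_clinical, na.rm = TRUE),
    sensitivity_with_biclusters = mean(splits$sens_bicluster, na.rm = TRUE),
    specificity_clinical = mean(splits$spec_clinical, na.rm = TRUE),
    specificity_with_biclusters = mean(splits$spec_bicluster, na.rm = TRUE),
    auc_clinical_median = median(splits$auc_clinical, na.rm = TRUE),
    auc_with_biclusters_median = median(splits$auc_bicluster, na.rm = TRUE),
    sensitivity_sign_test_p = sign_p,
    auc_horizon_years = cfg$auc_horizon_years
  )
  structure(list(splits = splits, aggregate = aggregate, predictions = preds,
                 config = cfg),
            class = "cv_report")
}

run_split <- function(x, clinical, labels, train_ids, test_ids, cfg, split_seed) {
  cfg_split <- cfg
  cfg_split$seed <- split_seed
  x_train <- em_subset(x, samples = train_ids)
  bcs <- run_biclustering(x_train, cfg_split)
  profiles <- lapply(bcs$biclusters, function(b) bicluster_pc1_profile(x_train, b))

  train_memb <- t(vapply(train_ids, function(sid) {
    as.integer(vapply(bcs$biclusters, function(b) sid %in% b$sample_ids,
                      logical(1)))
  }, integer(length(bcs))))
  test_memb <- t(vapply(test_ids, function(sid) {
    v <- setNames(x$values[, sid], x$gene_ids)
    sel <- assign_to_biclusters(v, bcs, profiles, cfg$correlation_threshold)
    out <- integer(length(bcs))
    out[sel] <- 1L
    out
  }, integer(length(bcs))))
  rownames(train_memb) <- train_ids
  rownames(test_memb) <- test_ids
  colnames(train_memb) <- colnames(test_memb) <- paste0("bc", seq_len(length(bcs)))
  memb <- rbind(train_memb, test_memb)

  cov_clin <- encode_covariates(clinical)
  cov_bc <- encode_covariates(clinical, memb)

  tr_lab <- intersect(train_ids, names(labels)[labels %in% c("early", "late")])
  te_lab <- intersect(test_ids, names(labels)[labels %in% c("early", "late")])
  y_tr <- droplevels(labels[tr_lab])
  y_te <- droplevels(labels[te_lab])

  tree_c <- fit_conditional_tree(cov_clin[tr_lab, , drop = FALSE], y_tr,
                                 alpha = cfg$tree_alpha,
                                 min_leaf = cfg$tree_min_leaf,
                                 n_perm = cfg$tree_n_perm, trim = cfg$tree_trim)
  tree_b <- fit_conditional_tree(cov_bc[tr_lab, , drop = FALSE], y_tr,
                                 alpha = cfg$tree_alpha,
                                 min_leaf = cfg$tree_min_leaf,
                                 n_perm = cfg$tree_n_perm, trim = cfg$tree_trim)
  pred_c <- predict(tree_c, cov_clin[te_lab, , drop = FALSE])
  pred_b <- predict(tree_b, cov_bc[te_lab, , drop = FALSE])

  sens <- function(pred) {
    true_early <- y_te == "early"
    if (!any(true_early)) return(NA_real_)
    mean(pred[true_early] == "early")
  }
  spec <- function(pred) {
    true_late <- y_te == "late"
    if (!any(true_late)) return(NA_real_)
    mean(pred[true_late] == "late")
  }

  ci <- match(tr_lab, clinical$sample_id)
  ti <- match(te_lab, clinical$sample_id)
  mm <- function(cov) {
    f <- ~ . - 1
    m <- stats::model.matrix(f, cov[c(tr_lab, te_lab), , drop = FALSE])
    list(train = m[seq_along(tr_lab), , drop = FALSE],
         test = m[length(tr_lab) + seq_along(te_lab), , drop = FALSE])
  }
  m_clin <- mm(cov_clin)
  m_bc <- mm(cov_bc)
  risk_c <- ridge_cox_predict(m_clin$train, clinical$dfs_time_years[ci],
                              clinical$dfs_event[ci], m_clin$test)
  risk_b <- ridge_cox_predict(m_bc$train, clinical$dfs_time_years[ci],
                              clinical$dfs_event[ci], m_bc$test)
  auc_c <- suppressWarnings(time_dependent_auc(
    risk_c, clinical$dfs_time_years[ti], clinical$dfs_event[ti],
    cfg$auc_horizon_years))
  auc_b <- suppressWarnings(time_dependent_auc(
    risk_b, clinical$dfs_time_years[ti], clinical$dfs_event[ti],
    cfg$auc_horizon_years))

  list(
    row = data.frame(
      n_train = length(train_ids), n_test = length(test_ids),
      sens_clinical = sens(pred_c), sens_bicluster = sens(pred_b),
      spec_clinical = spec(pred_c), spec_bicluster = spec(pred_b),
      auc_clinical = auc_c, auc_bicluster = auc_b
    ),
    pred = data.frame(sample_id = te_lab, true = as.character(y_te),
                      tree_clinical = pred_c, tree_bicluster = pred_b,
                      risk_clinical = risk_c[match(te_lab, te_lab)],
                      risk_bicluster = risk_b[match(te_lab, te_lab)],
                      stringsAsFactors = FALSE)
  )
}

#' @export
print.cv_report <- function(x, ...) {
  a <- x$aggregate
  cat("cv_report over ", nrow(x$splits), " splits\n",
      "  early-relapse sensitivity: clinical ",
      sprintf("%.3f", a$sensitivity_clinical), " -> with biclusters ",
      sprintf("%.3f", a$sensitivity_with_biclusters),
      " (sign test p = ", signif(a$sensitivity_sign_test_p, 3), ")\n",
      "  median AUC at ", a$auc_horizon_years, "y: clinical ",
      sprintf("%.3f", a$auc_clinical_median), " -> with biclusters ",
      sprintf("%.3f", a$auc_with_biclusters_median), "\n", sep = "")
  invisible(x)
}

#' Write a CV report to CSV + JSON summary
#' @param report a `cv_report`.
#' @param csv_path per-split CSV path.
#' @param json_path aggregate JSON path (requires jsonlite).
#' @return `csv_path`, invisibly.
#' @export
write_cv_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  write.csv(report$splits, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite required to write the JSON summary")
    }
    jsonlite::write_json(report$aggregate, json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(csv_path)
}
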