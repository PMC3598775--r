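row_vars <- function(m) {
  rm_ <- rowMeans(m)
  rowSums((m - rm_)^2) / (ncol(m) - 1)
}

# Relative two-way residue of a submatrix: mean squared residue of the
# additive (row + column effect) fit, divided by the submatrix's total
# variance around its grand mean (floored). Equivalently 1 - R^2 of the
# two-way additive model -- scale invariant, 0 for constant or additive
# blocks, ~ (1-1/n)(1-1/m) for an i.i.d. noise block. The compiled
# annealing loop (src/anneal.cpp) implements the identical quantity.
coh_resid <- function(vals, gi, si) {
  sub <- vals[gi, si, drop = FALSE]
  rm_ <- rowMeans(sub)
  cm_ <- colMeans(sub)
  m <- mean(cm_)
  res <- (sub - rm_) - rep(cm_, each = length(gi)) + m
  num <- mean(res * res)
  if (num < 1e-12) return(0)
  den <- mean((sub - m)^2)
  num / max(den, 1e-8)
}

#' Coherence score of a candidate bicluster
#'
#' Mean squared two-way-centered residue of the bicluster's submatrix
#' (the residue of the additive row + column effect fit), normalized by
#' the submatrix's total variance around its grand mean -- i.e.
#' `1 - R^2` of the two-way additive model. Zero for any constant or
#' additive submatrix; about `(1 - 1/n_samples)(1 - 1/n_genes)` for an
#' i.i.d. noise block. Lower is more coherent; a rank-one expression
#' module (gene loading x sample activity) scores far below a noise
#' block of the same size.
#'
#' @param x an [expression_matrix()] (or plain genes x samples matrix).
#' @param samples,genes member sample/gene ids (or indices); both sets
#'   need at least 2 elements.
#' @return A non-negative number.
#' @export
coherence_score <- function(x, samples, genes) {
  vals <- if (inherits(x, "expression_matrix")) x$values else x
  gi <- if (inherits(x, "expression_matrix")) resolve_idx(genes, x$gene_ids, "gene") else resolve_idx(genes, rownames(vals) %||% as.character(seq_len(nrow(vals))), "gene")
  si <- if (inherits(x, "expression_matrix")) resolve_idx(samples, x$sample_ids, "sample") else resolve_idx(samples, colnames(vals) %||% as.character(seq_len(ncol(vals))), "sample")
  if (length(si) < 2 || length(gi) < 2) {
    stop("coherence_score needs at least 2 samples and 2 genes")
  }
  coh_resid(vals, gi, si)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quality-coupled extensive volume term (negative = reward): growth is
# rewarded exactly while the bicluster is more coherent than the noise
# level `coherence_null`. Must match src/anneal.cpp.
size_penalty <- function(coh, ns, ng, cfg) {
  cfg$lambda_size * (ns * ng / (cfg$target_samples * cfg$target_genes)) *
    (coh - cfg$coherence_null)
}

state_total_score <- function(state) {
  olap <- 0
  if (state$K > 1L) {
    jd <- state$jacc
    diag(jd) <- 0
    olap <- sum(apply(jd, 1, max))
  }
  sum(state$coh) + sum(state$pen) + state$cfg$lambda_overlap * olap
}

# run n_iter compiled annealing toggles on a search_state
anneal_steps <- function(state, n_iter, trace_every = 0L) {
  res <- .bc_anneal_cpp(state$vals, state$Smem, state$Gmem, state$coh,
                        state$jacc, state$pen, state$iter, as.integer(n_iter),
                        state$cfg[c("t_initial", "cooling", "coherence_null", "min_samples",
                                    "max_samples", "min_genes", "max_genes",
                                    "lambda_size", "lambda_overlap",
                                    "target_samples", "target_genes")],
                        as.integer(trace_every))
  state$Smem <- res$Smem
  state$Gmem <- res$Gmem
  state$coh <- as.numeric(res$coh)
  state$jacc <- res$jacc
  state$pen <- as.numeric(res$pen)
  state$iter <- res$iter
  attr(state, "trace") <- res$trace
  state
}

#' Initialize the annealing search state
#'
#' Each of the K biclusters is seeded from a distinct randomly chosen
#' tumour, its most-correlated neighbour tumours, and the genes with
#' lowest variance across that seed set. The search operates on
#' per-gene standardized values (mean 0, sd 1 across samples), so
#' between-gene location/scale differences cannot masquerade as
#' coherence.
#'
#' @param x an [expression_matrix()].
#' @param cfg a [run_config()]; `k_biclusters` must not exceed the
#'   number of samples.
#' @return An object of class `search_state` holding the standardized
#'   values, binary sample/gene memberships, per-bicluster scores and
#'   penalties, the pairwise sample-Jaccard matrix and the iteration
#'   counter. Uses the session RNG; seed beforehand for
#'   reproducibility.
#' @export
new_search_state <- function(x, cfg) {
  stopifnot(inherits(x, "expression_matrix"), inherits(cfg, "run_config"))
  vals <- x$values
  n <- ncol(vals)
  G <- nrow(vals)
  K <- cfg$k_biclusters
  if (K > n) stop("k_biclusters (", K, ") exceeds the number of samples (", n, ")")
  # scoring operates on row-centered values: between-gene location
  # differences cannot masquerade as coherence, while per-gene signal
  # amplitude is preserved (full standardization would equalize module
  # gene loadings and let sample main effects absorb the membership
  # signal). Seed-gene selection uses scale-free (standardized) variance
  # so genes of different amplitude are comparable.
  vals <- vals - rowMeans(vals)
  zvals <- vals / pmax(sqrt(row_vars(vals)), 1e-8)
  Smem <- matrix(FALSE, n, K)
  Gmem <- matrix(FALSE, G, K)
  seeds <- sample.int(n, K)
  for (k in seq_len(K)) {
    cors <- suppressWarnings(as.vector(cor(vals[, seeds[k]], vals)))
    cors[is.na(cors)] <- -Inf
    cors[seeds[k]] <- -Inf
    nb <- order(cors, decreasing = TRUE)[seq_len(min(cfg$seed_neighbours, n - 1L))]
    S <- c(seeds[k], nb)
    rv <- row_vars(zvals[, S, drop = FALSE])
    gsel <- order(rv)[seq_len(min(cfg$seed_genes, G))]
    Smem[S, k] <- TRUE
    Gmem[gsel, k] <- TRUE
  }
  coh <- vapply(seq_len(K), function(k) {
    coh_resid(vals, which(Gmem[, k]), which(Smem[, k]))
  }, numeric(1))
  pen <- vapply(seq_len(K), function(k) {
    size_penalty(coh[k], sum(Smem[, k]), sum(Gmem[, k]), cfg)
  }, numeric(1))
  jacc <- matrix(0, K, K)
  if (K > 1L) {
    for (a in seq_len(K - 1L)) {
      for (b in (a + 1L):K) {
        inter <- sum(Smem[, a] & Smem[, b])
        jacc[a, b] <- jacc[b, a] <- inter / sum(Smem[, a] | Smem[, b])
      }
    }
  }
  structure(list(vals = vals, Smem = Smem, Gmem = Gmem, coh = coh,
                 jacc = jacc, pen = pen, iter = 0L, cfg = cfg, n = n,
                 G = G, K = K),
            class = "search_state")
}

#' One Markov-chain move of the bicluster search
#'
#' Picks one bicluster, then one eligible toggle (a sample or gene,
#' uniform over toggles respecting the size bounds), and accepts the
#' toggled state with probability `min(1, exp(-delta/T))`, where `delta`
#' is the change in total score (coherence + size penalty + overlap
#' penalty) and `T` the current annealing temperature. Rejected
#' proposals leave the memberships unchanged (the RNG still advances).
#' Moves that would leave a bicluster below its minimum size (or above
#' its maximum) are never proposed.
#'
#' @param state a `search_state` from [new_search_state()].
#' @param x the expression matrix the state was built from (accepted
#'   for interface symmetry; the state carries the standardized values).
#' @return The updated `search_state`.
#' @export
propose_move <- function(state, x = NULL) {
  stopifnot(inherits(state, "search_state"))
  anneal_steps(state, 1L)
}

#' Search for K overlapping tumour biclusters by simulated annealing
#'
#' Runs the full annealing schedule (geometric cooling, `t_initial *
#' cooling^i`, over `iters_per_bicluster * K` toggles) from the
#' correlation-based seeding of [new_search_state()]. Deterministic
#' given `cfg$seed` (stream derived from `(seed, "bicluster")`). After
#' cooling, any bicluster left below its minimum size is topped up
#' greedily with the least score-increasing elements.
#'
#' @param x a preprocessed [expression_matrix()].
#' @param cfg a [run_config()].
#' @return A [bicluster_set()] with `cfg$k_biclusters` biclusters
#'   (scores = final coherence on the standardized matrix), the config
#'   snapshot as provenance, and attributes `trace` (total score every
#'   200 iterations), `initial_score` and `final_score`.
#' @export
run_biclustering <- function(x, cfg) {
  stopifnot(inherits(x, "expression_matrix"), inherits(cfg, "run_config"))
  local_seed(stage_seed(cfg$seed, "bicluster"), {
    state <- new_search_state(x, cfg)
    n_iter <- cfg$iters_per_bicluster * state$K
    score0 <- state_total_score(state)
    # run in three phases; between phases, searchers that failed to find
    # structure (objective near the noise level) are re-seeded from a
    # sample not yet covered by any bicluster, so every planted module
    # has a chance of attracting its own searcher
    phases <- diff(round(n_iter * c(0, 0.3, 0.5, 0.7, 1)))
    trace <- score0
    for (ph in seq_along(phases)) {
      state <- anneal_steps(state, phases[ph], trace_every = 200L)
      trace <- c(trace, attr(state, "trace"))
      if (ph < length(phases)) state <- reseed_dead(state)
    }
    state <- greedy_polish(state)
    # redundancy can re-form after the last reseed round: recycle any
    # remaining duplicated/dead searcher and let it regrow greedily
    for (round in 1:2) {
      dead_before <- state_total_score(state)
      state2 <- reseed_dead(state)
      if (identical(state2$Smem, state$Smem) && identical(state2$Gmem, state$Gmem)) break
      state <- greedy_polish(state2)
    }
    state <- repair_min_sizes(state)
    bcl <- lapply(seq_len(state$K), function(k) {
      bicluster(k, x$sample_ids[state$Smem[, k]], x$gene_ids[state$Gmem[, k]],
                score = state$coh[k])
    })
    out <- bicluster_set(bcl, config = cfg)
    attr(out, "trace") <- trace
    attr(out, "initial_score") <- score0
    attr(out, "final_score") <- state_total_score(state)
    out
  })
}

# Deterministic full-neighbourhood hill climbing on the final state:
# systematic sweeps applying every strictly improving toggle until a
# local optimum (or max_sweeps sweeps).
greedy_polish <- function(state, max_sweeps = 8L) {
  res <- .bc_polish_cpp(state$vals, state$Smem, state$Gmem, state$coh,
                        state$jacc, state$pen,
                        state$cfg[c("coherence_null", "min_samples",
                                    "max_samples", "min_genes", "max_genes",
                                    "lambda_size", "lambda_overlap",
                                    "target_samples", "target_genes")],
                        as.integer(max_sweeps))
  state$Smem <- res$Smem
  state$Gmem <- res$Gmem
  state$coh <- as.numeric(res$coh)
  state$jacc <- res$jacc
  state$pen <- as.numeric(res$pen)
  state
}

# Re-seed biclusters whose objective (coherence + volume term) is close
# to that of a structureless block: draw a fresh seed among samples not
# currently in any bicluster (fallback: any sample), with correlated
# neighbours and low-variance seed genes as in the initial seeding.
reseed_dead <- function(state, threshold = -0.4) {
  cfg <- state$cfg
  obj <- state$coh + state$pen
  dead <- which(obj > threshold)
  # redundancy: two searchers on the same module -- either overlapping
  # sample sets, or partitioning one module (disjoint samples but
  # largely shared gene sets) -- recycle the one with the worse
  # objective; the winner is then free to cover the whole module
  if (state$K > 1L) {
    gsize <- colSums(state$Gmem)
    for (a in seq_len(state$K - 1L)) {
      for (b in (a + 1L):state$K) {
        ginter <- sum(state$Gmem[, a] & state$Gmem[, b])
        gj <- ginter / (gsize[a] + gsize[b] - ginter)
        if (state$jacc[a, b] > 0.4 || gj > 0.3) {
          dead <- union(dead, if (obj[a] <= obj[b]) b else a)
        }
      }
    }
  }
  dead <- sort(dead)
  if (length(dead) == 0) return(state)
  zvals <- state$vals / pmax(sqrt(row_vars(state$vals)), 1e-8)
  for (k in dead) {
    uncovered <- which(rowSums(state$Smem) == 0)
    seed <- if (length(uncovered) > cfg$seed_neighbours + 1L) {
      # most "modular" uncovered sample: highest mean correlation to its
      # nearest uncovered neighbours -- points at an undiscovered module
      cu <- suppressWarnings(cor(state$vals[, uncovered, drop = FALSE]))
      cu[!is.finite(cu)] <- -1
      diag(cu) <- NA
      modularity <- apply(cu, 2, function(v) {
        mean(sort(v, decreasing = TRUE)[seq_len(min(cfg$seed_neighbours, length(v) - 1L))])
      })
      uncovered[which.max(modularity)]
    } else if (length(uncovered) > 0) {
      uncovered[sample.int(length(uncovered), 1)]
    } else {
      sample.int(state$n, 1)
    }
    cors <- suppressWarnings(as.vector(cor(state$vals[, seed], state$vals)))
    cors[is.na(cors)] <- -Inf
    cors[seed] <- -Inf
    # bootstrap the fresh searcher past minimum size so it can grow
    # greedily even late in the schedule
    n_nb <- max(cfg$seed_neighbours, cfg$min_samples - 1L)
    nb <- order(cors, decreasing = TRUE)[seq_len(min(n_nb, state$n - 1L))]
    S <- c(seed, nb)
    rv <- row_vars(zvals[, S, drop = FALSE])
    gsel <- order(rv)[seq_len(min(cfg$seed_genes, state$G))]
    state$Smem[, k] <- FALSE
    state$Smem[S, k] <- TRUE
    state$Gmem[, k] <- FALSE
    state$Gmem[gsel, k] <- TRUE
    state$coh[k] <- coh_resid(state$vals, gsel, S)
    state$pen[k] <- size_penalty(state$coh[k], length(S), length(gsel), cfg)
  }
  if (state$K > 1L) {
    for (a in seq_len(state$K - 1L)) {
      for (b in (a + 1L):state$K) {
        inter <- sum(state$Smem[, a] & state$Smem[, b])
        state$jacc[a, b] <- state$jacc[b, a] <-
          inter / sum(state$Smem[, a] | state$Smem[, b])
      }
    }
  }
  state
}

# Greedy top-up of any bicluster left below minimum size: repeatedly add
# the element whose addition increases the coherence least.
repair_min_sizes <- function(state) {
  cfg <- state$cfg
  for (k in seq_len(state$K)) {
    while (sum(state$Smem[, k]) < cfg$min_samples) {
      cand <- which(!state$Smem[, k])
      gi <- which(state$Gmem[, k])
      si <- which(state$Smem[, k])
      scores <- vapply(cand, function(s) {
        coh_resid(state$vals, gi, c(si, s))
      }, numeric(1))
      best <- cand[which.min(scores)]
      state$Smem[best, k] <- TRUE
      state$coh[k] <- min(scores)
    }
    while (sum(state$Gmem[, k]) < cfg$min_genes) {
      cand <- which(!state$Gmem[, k])
      gi <- which(state$Gmem[, k])
      si <- which(state$Smem[, k])
      scores <- vapply(cand, function(g) {
        coh_resid(state$vals, c(gi, g), si)
      }, numeric(1))
      best <- cand[which.min(scores)]
      state$Gmem[best, k] <- TRUE
      state$coh[k] <- min(scores)
    }
    state$pen[k] <- size_penalty(state$coh[k], sum(state$Smem[, k]),
                                 sum(state$Gmem[, k]), cfg)
  }
  if (state$K > 1L) {
    for (a in seq_len(state$K - 1L)) {
      for (b in (a + 1L):state$K) {
        inter <- sum(state$Smem[, a] & state$Smem[, b])
        state$jacc[a, b] <- state$jacc[b, a] <-
          inter / sum(state$Smem[, a] | state$Smem[, b])
      }
    }
  }
  state
}
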