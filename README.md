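# bistrat — bicluster-based stratification of breast tumours

`bistrat` implements a stratified-biomarker analysis of tumour expression
data: instead of one fixed gene panel for all patients, it searches for
**biclusters** — subgroups of tumours that co-express a specific subset
of genes — and asks whether membership of these subgroups (i) separates
disease-free survival (DFS) beyond chance and (ii) improves the
prediction of early relapse over standard clinical covariates. It is
aimed at researchers studying expression-based patient stratification and
ships a synthetic-data generator with planted ground truth, so the whole
pipeline is testable end to end without any external download.

## The method in brief

**Biclustering.** For a candidate tumour set *S* and gene set *G*, the
coherence score is the relative residue of the additive two-way fit on
the submatrix,

    score(S, G) = mean squared residue of (m + r_g + c_t) / total submatrix variance = 1 − R²,

which is 0 for constant or additive blocks and ≈ (1−1/|S|)(1−1/|G|) for
noise. K overlapping biclusters are found by simulated annealing over
single tumour/gene toggles (Metropolis acceptance, geometric cooling),
with a quality-coupled volume reward — growth counts while a searcher is
more coherent than noise — a weak overlap penalty, mid-run re-seeding of
dead or duplicated searchers, and a greedy polish. The inner loop is
compiled (Rcpp).

**Survival.** Kaplan–Meier curves and all-pairs logrank p-values over
the biclusters are compared with the same quantity over size-matched
random groups (sampled with replacement, mirroring bicluster overlap)
using a two-sample Kolmogorov–Smirnov test. Cox proportional-hazards
models (plain and ridge-penalized) quantify prognostic effects.

**Classification and prediction.** Nearest-shrunken-centroid (PAM)
classifiers give minimal gene sets for bicluster pairs; a conditional
inference tree and a cross-validated ridge-Cox model predict early
relapse (event ≤ 2 years) vs late relapse (disease-free ≥ 8 years) from
clinical covariates with and without per-bicluster membership
indicators, over 50 stratified 80/20 splits.

See the methods vignette (`vignettes/bistrat-methods.Rmd`) for the full
model, parameter defaults and design rationale.

## Worked example

```r
library(bistrat)

# simulate a small multi-cohort dataset with 4 planted modules
design <- default_design(seed = 7, n_genes = 400, n_samples = 150, n_planted = 4)
sim <- simulate_dataset(design)
sim$expression
#> expression_matrix: 400 genes x 150 samples (with gene symbols)

# remove cohort batch effects, then search for 4 biclusters
x <- adjust_batch(sim$expression, sim$clinical$cohort)
cfg <- run_config(seed = 1, k_biclusters = 4, n_cv_splits = 10)
bcs <- run_biclustering(x, cfg)
bcs
#> bicluster_set with 4 biclusters; samples per bicluster 16-60 (mean 30.8), genes 89-120
recovery_jaccard(bcs, sim$truth)
#> [1] 0.7539683

# do the biclusters separate disease-free survival?
separation_test(bcs, sim$clinical, n_rand = 20, seed = 1)
#> separation_test: 6 observed pairs vs 120 null pairs (20 randomizations)
#>   KS statistic = 0.8333, p = 9.353e-05

# does membership improve early-relapse prediction?
cross_validate(x, sim$clinical, cfg)
#> cv_report over 10 splits
#>   early-relapse sensitivity: clinical 0.583 -> with biclusters 0.600 (sign test p = 0.313)
#>   median AUC at 2y: clinical 0.701 -> with biclusters 0.799
```

Reading the numbers: the search recovered the planted tumour subgroups
with a mean best-match Jaccard of 0.75; the bicluster survival curves
are far more separated than size-matched random groups (KS p ≈ 1e-4);
and adding bicluster membership to the clinical covariates raises the
median 2-year AUC of the ridge-Cox model from 0.70 to 0.80 (at this toy
scale of 10 splits the tree-sensitivity sign test is not yet
significant; at the default 50-split scale it is).

A thin command-line interface over the same functions is installed at
`inst/cli/bistrat-cli.R` with subcommands `simulate`, `preprocess`,
`bicluster`, `survtest`, `classify` and `crossval`.

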