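#include <Rcpp.h>
using namespace Rcpp;

// Relative two-way residue of the submatrix vals[g in genes, s in samples]:
// mean squared residue of the additive row+column fit divided by the
// submatrix's total variance around its grand mean (floored at 1e-8).
// Must agree exactly with the R-level coherence_score().
static double coh_resid_c(const NumericMatrix &vals,
                          const std::vector<int> &gi,
                          const std::vector<int> &si) {
  const int ng = gi.size(), ns = si.size();
  if (ng < 1 || ns < 1) return 0.0;
  std::vector<double> rowm(ng, 0.0), colm(ns, 0.0);
  double grand = 0.0;
  for (int j = 0; j < ns; ++j) {
    const double *col = &vals(0, si[j]);
    for (int i = 0; i < ng; ++i) {
      double v = col[gi[i]];
      rowm[i] += v;
      colm[j] += v;
    }
  }
  for (int i = 0; i < ng; ++i) { grand += rowm[i]; rowm[i] /= ns; }
  for (int j = 0; j < ns; ++j) colm[j] /= ng;
  grand /= (double)ng * ns;
  double num = 0.0, den = 0.0;
  for (int j = 0; j < ns; ++j) {
    const double *col = &vals(0, si[j]);
    for (int i = 0; i < ng; ++i) {
      double v = col[gi[i]];
      double r = v - rowm[i] - colm[j] + grand;
      num += r * r;
      double d = v - grand;
      den += d * d;
    }
  }
  num /= (double)ng * ns;
  den /= (double)ng * ns;
  if (num < 1e-12) return 0.0;
  return num / std::max(den, 1e-8);
}

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// [[Rcpp::export(name = ".coh_resid_cpp")]]
double coh_resid_cpp(NumericMatrix vals, IntegerVector gi0, IntegerVector si0) {
  std::vector<int> gi(gi0.begin(), gi0.end()), si(si0.begin(), si0.end());
  for (size_t i = 0; i < gi.size(); ++i) gi[i] -= 1;
  for (size_t j = 0; j < si.size(); ++j) si[j] -= 1;
  return coh_resid_c(vals, gi, si);
}

static std::vector<int> which_true(const LogicalMatrix &m, int k) {
  std::vector<int> idx;
  for (int i = 0; i < m.nrow(); ++i) if (m(i, k)) idx.push_back(i);
  return idx;
}

// Run n_iter annealing toggles in place on copies of the membership
// state; returns the updated state plus a score trace. Uses R's RNG
// (seed with set.seed for reproducibility).
// [[Rcpp::export(name = ".bc_anneal_cpp")]]
List bc_anneal_cpp(NumericMatrix vals, LogicalMatrix Smem, LogicalMatrix Gmem,
                   NumericVector coh, NumericMatrix jacc, NumericVector pen,
                   int iter0, int n_iter, List cfg, int trace_every) {
  RNGScope scope;
  LogicalMatrix S = clone(Smem);
  LogicalMatrix Gm = clone(Gmem);
  NumericVector co = clone(coh);
  NumericMatrix J = clone(jacc);
  NumericVector pe = clone(pen);

  const int n = S.nrow(), G = Gm.nrow(), K = S.ncol();
  const double t0 = as<double>(cfg["t_initial"]);
  const double cooling = as<double>(cfg["cooling"]);
  const int min_s = as<int>(cfg["min_samples"]), max_s = as<int>(cfg["max_samples"]);
  const int min_g = as<int>(cfg["min_genes"]), max_g = as<int>(cfg["max_genes"]);
  const double lam_size = as<double>(cfg["lambda_size"]);
  const double lam_olap = as<double>(cfg["lambda_overlap"]);
  const double targ_s = as<double>(cfg["target_samples"]);
  const double targ_g = as<double>(cfg["target_genes"]);

  std::vector<int> ssize(K), gsize(K);
  for (int k = 0; k < K; ++k) {
    ssize[k] = 0; gsize[k] = 0;
    for (int i = 0; i < n; ++i) if (S(i, k)) ssize[k]++;
    for (int i = 0; i < G; ++i) if (Gm(i, k)) gsize[k]++;
  }

  const double c0 = as<double>(cfg["coherence_null"]);
  // extensive volume term coupled to quality: growth is rewarded
  // (negative contribution) exactly while the bicluster stays more
  // coherent than the noise level c0, so coherent modules are covered
  // in full while incoherent ones cannot balloon.
  auto size_pen = [&](double coh_k, int ns, int ng) {
    return lam_size * ((double)ns * ng / (targ_s * targ_g)) * (coh_k - c0);
  };

  std::vector<double> trace;
  // overlap term: sum over biclusters of their maximum sample-Jaccard
  // with any other bicluster (repels duplicated biclusters)
  auto olap_term = [&](const NumericMatrix &Jm) {
    if (K < 2) return 0.0;
    double s = 0.0;
    for (int a = 0; a < K; ++a) {
      double mx = 0.0;
      for (int b = 0; b < K; ++b) if (b != a && Jm(a, b) > mx) mx = Jm(a, b);
      s += mx;
    }
    return s;
  };
  auto total_score = [&]() {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += co[k] + pe[k];
    return s + lam_olap * olap_term(J);
  };

  int iter = iter0;
  for (int it = 0; it < n_iter; ++it) {
    iter++;
    double temp = t0 * std::pow(cooling, iter - 1);
    int k = runif_int(K);

    int j = -1;
    bool is_sample = false;
    for (int t = 0; t < 50; ++t) {
      int cand = runif_int(n + G);
      if (cand < n) {
        bool inb = S(cand, k);
        if (inb && ssize[k] - 1 < min_s) continue;
        if (!inb && ssize[k] + 1 > max_s) continue;
        j = cand; is_sample = true; break;
      } else {
        cand -= n;
        bool inb = Gm(cand, k);
        if (inb && gsize[k] - 1 < min_g) continue;
        if (!inb && gsize[k] + 1 > max_g) continue;
        j = cand; is_sample = false; break;
      }
    }
    if (j < 0) continue;

    std::vector<int> gi = which_true(Gm, k);
    if (is_sample) {
      bool adding = !S(j, k);
      S(j, k) = !S(j, k);
      std::vector<int> si = which_true(S, k);
      double new_coh = coh_resid_c(vals, gi, si);
      int new_ns = ssize[k] + (adding ? 1 : -1);
      double new_pen = size_pen(new_coh, new_ns, gsize[k]);
      double d_olap = 0.0;
      std::vector<double> newj;
      if (K > 1) {
        newj.assign(K, 0.0);
        double old_olap = olap_term(J);
        NumericMatrix J2 = clone(J);
        for (int m = 0; m < K; ++m) {
          if (m == k) continue;
          int inter = 0, uni = 0;
          for (int i = 0; i < n; ++i) {
            bool a = S(i, k), b = S(i, m);
            if (a && b) inter++;
            if (a || b) uni++;
          }
          newj[m] = uni > 0 ? (double)inter / uni : 0.0;
          J2(m, k) = newj[m];
          J2(k, m) = newj[m];
        }
        d_olap = olap_term(J2) - old_olap;
      }
      double delta = (new_coh - co[k]) + (new_pen - pe[k]) + lam_olap * d_olap;
      if (delta <= 0 || unif_rand() < std::exp(-delta / temp)) {
        co[k] = new_coh;
        pe[k] = new_pen;
        ssize[k] = new_ns;
        if (K > 1) {
          for (int m = 0; m < K; ++m) {
            if (m == k) continue;
            J(m, k) = newj[m];
            J(k, m) = newj[m];
          }
        }
      } else {
        S(j, k) = !S(j, k); // revert
      }
    } else {
      bool adding = !Gm(j, k);
      Gm(j, k) = !Gm(j, k);
      std::vector<int> gi2 = which_true(Gm, k);
      std::vector<int> si = which_true(S, k);
      double new_coh = coh_resid_c(vals, gi2, si);
      int new_ng = gsize[k] + (adding ? 1 : -1);
      double new_pen = size_pen(new_coh, ssize[k], new_ng);
      double delta = (new_coh - co[k]) + (new_pen - pe[k]);
      if (delta <= 0 || unif_rand() < std::exp(-delta / temp)) {
        co[k] = new_coh;
        pe[k] = new_pen;
        gsize[k] = new_ng;
      } else {
        Gm(j, k) = !Gm(j, k); // revert
      }
    }
    if (trace_every > 0 && iter % trace_every == 0) trace.push_back(total_score());
  }

  return List::create(_["Smem"] = S, _["Gmem"] = Gm, _["coh"] = co,
                      _["jacc"] = J, _["pen"] = pe, _["iter"] = iter,
                      _["trace"] = wrap(trace),
                      _["total"] = total_score());
}

// Deterministic greedy polish: systematic sweeps over every
// (bicluster, toggle) pair, applying any move that strictly lowers the
// total objective, until a full sweep makes no change (or max_sweeps).
// [[Rcpp::export(name = ".bc_polish_cpp")]]
List bc_polish_cpp(NumericMatrix vals, LogicalMatrix Smem, LogicalMatrix Gmem,
                   NumericVector coh, NumericMatrix jacc, NumericVector pen,
                   List cfg, int max_sweeps) {
  LogicalMatrix S = clone(Smem);
  LogicalMatrix Gm = clone(Gmem);
  NumericVector co = clone(coh);
  NumericMatrix J = clone(jacc);
  NumericVector pe = clone(pen);

  const int n = S.nrow(), G = Gm.nrow(), K = S.ncol();
  const int min_s = as<int>(cfg["min_samples"]), max_s = as<int>(cfg["max_samples"]);
  const int min_g = as<int>(cfg["min_genes"]), max_g = as<int>(cfg["max_genes"]);
  const double lam_size = as<double>(cfg["lambda_size"]);
  const double lam_olap = as<double>(cfg["lambda_overlap"]);
  const double targ_s = as<double>(cfg["target_samples"]);
  const double targ_g = as<double>(cfg["target_genes"]);
  const double c0 = as<double>(cfg["coherence_null"]);

  std::vector<int> ssize(K), gsize(K);
  for (int k = 0; k < K; ++k) {
    ssize[k] = 0; gsize[k] = 0;
    for (int i = 0; i < n; ++i) if (S(i, k)) ssize[k]++;
    for (int i = 0; i < G; ++i) if (Gm(i, k)) gsize[k]++;
  }
  auto size_pen = [&](double coh_k, int ns, int ng) {
    return lam_size * ((double)ns * ng / (targ_s * targ_g)) * (coh_k - c0);
  };
  auto olap_term = [&](const NumericMatrix &Jm) {
    if (K < 2) return 0.0;
    double s = 0.0;
    for (int a = 0; a < K; ++a) {
      double mx = 0.0;
      for (int b = 0; b < K; ++b) if (b != a && Jm(a, b) > mx) mx = Jm(a, b);
      s += mx;
    }
    return s;
  };

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < n; ++j) {
        bool inb = S(j, k);
        if (inb && ssize[k] - 1 < min_s) continue;
        if (!inb && ssize[k] + 1 > max_s) continue;
        S(j, k) = !inb;
        std::vector<int> gi = which_true(Gm, k);
        std::vector<int> si = which_true(S, k);
        double new_coh = coh_resid_c(vals, gi, si);
        int new_ns = ssize[k] + (inb ? -1 : 1);
        double new_pen = size_pen(new_coh, new_ns, gsize[k]);
        double d_olap = 0.0;
        std::vector<double> newj(K, 0.0);
        if (K > 1) {
          double old_olap = olap_term(J);
          NumericMatrix J2 = clone(J);
          for (int m = 0; m < K; ++m) {
            if (m == k) continue;
            int inter = 0, uni = 0;
            for (int i = 0; i < n; ++i) {
              bool a = S(i, k), b = S(i, m);
              if (a && b) inter++;
              if (a || b) uni++;
            }
            newj[m] = uni > 0 ? (double)inter / uni : 0.0;
            J2(m, k) = newj[m];
            J2(k, m) = newj[m];
          }
          d_olap = olap_term(J2) - old_olap;
        }
        double delta = (new_coh - co[k]) + (new_pen - pe[k]) + lam_olap * d_olap;
        if (delta < -1e-10) {
          co[k] = new_coh;
          pe[k] = new_pen;
          ssize[k] = new_ns;
          if (K > 1) {
            for (int m = 0; m < K; ++m) {
              if (m == k) continue;
              J(m, k) = newj[m];
              J(k, m) = newj[m];
            }
          }
          changed = true;
        } else {
          S(j, k) = inb;
        }
      }
      for (int j = 0; j < G; ++j) {
        bool inb = Gm(j, k);
        if (inb && gsize[k] - 1 < min_g) continue;
        if (!inb && gsize[k] + 1 > max_g) continue;
        Gm(j, k) = !inb;
        std::vector<int> gi = which_true(Gm, k);
        std::vector<int> si = which_true(S, k);
        double new_coh = coh_resid_c(vals, gi, si);
        int new_ng = gsize[k] + (inb ? -1 : 1);
        double new_pen = size_pen(new_coh, ssize[k], new_ng);
        double delta = (new_coh - co[k]) + (new_pen - pe[k]);
        if (delta < -1e-10) {
          co[k] = new_coh;
          pe[k] = new_pen;
          gsize[k] = new_ng;
          changed = true;
        } else {
          Gm(j, k) = inb;
        }
      }
    }
    if (!changed) break;
  }
  return List::create(_["Smem"] = S, _["Gmem"] = Gm, _["coh"] = co,
                      _["jacc"] = J, _["pen"] = pe);
}
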