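#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Soft-threshold operator.
static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Lasso sub-problem by coordinate descent:
//   min_b 1/2 b' W11 b - s12' b + rho * ||b||_1
// Warm-started on `b`. W11 has strictly positive diagonal.
static void lasso_cd(const mat& W11, const vec& s12, double rho, vec& b,
                     double tol, int maxit) {
  const uword p = s12.n_elem;
  std::vector<uword> active;
  active.reserve(p);
  int it = 0;
  while (it < maxit) {
    // full sweep: updates every coordinate and rebuilds the active set
    double dmax = 0.0;
    active.clear();
    for (uword k = 0; k < p; ++k) {
      double old = b(k);
      double r = s12(k) - dot(W11.col(k), b) + W11(k, k) * old;
      double bnew = soft(r, rho) / W11(k, k);
      if (bnew != old) {
        b(k) = bnew;
        double d = std::abs(bnew - old);
        if (d > dmax) dmax = d;
      }
      if (b(k) != 0.0) active.push_back(k);
    }
    ++it;
    if (dmax < tol) break;
    // inner sweeps over the active set only
    while (it < maxit) {
      double amax = 0.0;
      for (uword k : active) {
        double old = b(k);
        double r = s12(k) - dot(W11.col(k), b) + W11(k, k) * old;
        double bnew = soft(r, rho) / W11(k, k);
        if (bnew != old) {
          b(k) = bnew;
          double d = std::abs(bnew - old);
          if (d > amax) amax = d;
        }
      }
      ++it;
      if (amax < tol) break;  // then re-verify with a full sweep
    }
  }
}

// Block coordinate descent glasso on a (sub)correlation matrix. Fills
// theta; B holds per-column lasso coefficients (warm start, updated in
// place). Returns true on convergence.
static bool glasso_block(const mat& S, double rho, double thr, int maxit,
                         mat& theta, mat& B) {
  const uword p = S.n_rows;
  if (p == 1) {
    theta(0, 0) = 1.0 / S(0, 0);
    return true;
  }
  mat W = S;
  uvec all = regspace<uvec>(0, p - 1);
  bool converged = false;
  for (int outer = 0; outer < maxit && !converged; ++outer) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec b = B.col(j);
      lasso_cd(W11, s12, rho, b, thr * 0.1, 500);
      B.col(j) = b;
      vec w12 = W11 * b;
      for (uword k = 0; k < idx.n_elem; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > dmax) dmax = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (dmax < thr) converged = true;
  }
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec b = B.col(j);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double t22 = 1.0 / (W(j, j) - dot(w12, b));
    theta(j, j) = t22;
    for (uword k = 0; k < idx.n_elem; ++k)
      theta(idx(k), j) = -b(k) * t22;
  }
  theta = 0.5 * (theta + theta.t());
  return converged;
}

// Connected components of the screening graph |S_ij| > rho (exact
// block-diagonal decomposition of the off-diagonal-penalized glasso).
static std::vector<std::vector<uword>> screen_components(const mat& S,
                                                         double rho) {
  const uword p = S.n_rows;
  std::vector<int> comp(p, -1);
  std::vector<std::vector<uword>> blocks;
  for (uword i = 0; i < p; ++i) {
    if (comp[i] >= 0) continue;
    std::vector<uword> queue{i};
    comp[i] = (int)blocks.size();
    std::vector<uword> members;
    while (!queue.empty()) {
      uword v = queue.back();
      queue.pop_back();
      members.push_back(v);
      for (uword u = 0; u < p; ++u)
        if (comp[u] < 0 && u != v && std::abs(S(v, u)) > rho) {
          comp[u] = comp[i];
          queue.push_back(u);
        }
    }
    blocks.push_back(members);
  }
  return blocks;
}

// Glasso with screening; theta assembled from per-block solutions.
// Bglob is a p x p warm-start cache of lasso coefficients (Bglob(i, j) =
// coefficient of variable i in column j's subproblem), shared across path
// steps so solutions at neighbouring penalties start close.
static bool glasso_screened(const mat& S, double rho, double thr, int maxit,
                            mat& theta, mat& Bglob) {
  const uword p = S.n_rows;
  theta.zeros(p, p);
  bool ok = true;
  for (const auto& blk : screen_components(S, rho)) {
    uvec idx(blk.size());
    for (size_t k = 0; k < blk.size(); ++k) idx(k) = blk[k];
    if (blk.size() == 1) {
      theta(idx(0), idx(0)) = 1.0 / S(idx(0), idx(0));
      continue;
    }
    const uword pb = blk.size();
    mat Sb = S.submat(idx, idx);
    mat thb(pb, pb, fill::zeros);
    mat Bb(pb - 1, pb, fill::zeros);
    for (uword j = 0; j < pb; ++j) {
      uword r = 0;
      for (uword i = 0; i < pb; ++i) {
        if (i == j) continue;
        Bb(r++, j) = Bglob(idx(i), idx(j));
      }
    }
    if (!glasso_block(Sb, rho, thr, maxit, thb, Bb)) ok = false;
    theta.submat(idx, idx) = thb;
    for (uword j = 0; j < pb; ++j) {
      uword r = 0;
      for (uword i = 0; i < pb; ++i) {
        if (i == j) continue;
        Bglob(idx(i), idx(j)) = Bb(r++, j);
      }
    }
  }
  return ok;
}

static double conv_scale(const mat& S, double tol) {
  const uword p = S.n_rows;
  if (p < 2) return tol;
  double sbar = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) sbar += std::abs(S(i, j));
  sbar /= (double)(p * (p - 1));
  return tol * (sbar > 0 ? sbar : 1.0);
}

// Graphical lasso: maximises log det(Theta) - tr(S Theta) - rho*||Theta||_1
// over the off-diagonal entries. Block coordinate descent over columns with
// exact connected-component screening.
// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho, double tol = 1e-5,
                      int maxit = 200) {
  mat theta;
  mat Bglob(S.n_rows, S.n_rows, fill::zeros);
  bool ok = glasso_screened(S, rho, conv_scale(S, tol), maxit, theta, Bglob);
  return Rcpp::List::create(Rcpp::Named("theta") = theta,
                            Rcpp::Named("converged") = ok);
}

// Glasso along a decreasing lambda path; returns the off-diagonal support
// pattern (logical) for each lambda, and optionally the precision matrices.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol = 1e-5, int maxit = 200,
                           bool keep_theta = false) {
  const uword p = S.n_rows;
  const uword L = lambdas.n_elem;
  Rcpp::List supports(L);
  Rcpp::List thetas(L);
  Rcpp::LogicalVector conv(L);
  double thr = conv_scale(S, tol);

  mat theta;
  mat Bglob(p, p, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    conv(l) = glasso_screened(S, lambdas(l), thr, maxit, theta, Bglob);
    Rcpp::LogicalMatrix supp(p, p);
    for (uword i = 0; i < p; ++i)
      for (uword j = 0; j < p; ++j)
        supp(i, j) = (i != j) && std::abs(theta(i, j)) > 1e-12;
    supports[l] = supp;
    if (keep_theta) thetas[l] = Rcpp::wrap(theta);
  }

  return Rcpp::List::create(Rcpp::Named("supports") = supports,
                            Rcpp::Named("thetas") = thetas,
                            Rcpp::Named("converged") = conv);
}
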