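// Compiled solvers for the three optimization problems at the heart of the
// package: graphical-LASSO precision estimation (block coordinate descent),
// the L1-norm squared-hinge linear SVM (proximal gradient / FISTA), and the
// L2-norm hinge linear SVM (dual coordinate descent, no bias term).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coordinate-descent lasso for the glasso column subproblem:
//   min_b 0.5 b' W11 b - s12' b + lam ||b||_1
// W11 is PD (a principal submatrix of W = S + lam I after updates).
static void lasso_cd(const mat& W11, const vec& s12, double lam,
                     vec& beta, int max_iter, double tol) {
  const uword p = s12.n_elem;
  for (int it = 0; it < max_iter; ++it) {
    double maxdiff = 0.0;
    for (uword k = 0; k < p; ++k) {
      const double old = beta(k);
      const double r = s12(k) - dot(W11.col(k), beta) + W11(k, k) * old;
      double bnew = 0.0;
      if (r > lam)       bnew = (r - lam) / W11(k, k);
      else if (r < -lam) bnew = (r + lam) / W11(k, k);
      beta(k) = bnew;
      const double d = std::fabs(bnew - old);
      if (d > maxdiff) maxdiff = d;
    }
    if (maxdiff < tol) break;
  }
}

// Graphical LASSO by block coordinate descent over columns of the working
// covariance W.  The L1 penalty covers every entry of Omega including the
// diagonal, hence the initialization W = S + lam*I.  Exact zeros in Omega
// come from exact zeros of the lasso coefficients; no thresholding.
// [[Rcpp::export]]
Rcpp::List glasso_bcd(const arma::mat& S, double lambda, double tol,
                      int max_iter, double inner_tol, int inner_max_iter) {
  const uword p = S.n_rows;
  if (p == 1) {
    mat Omega(1, 1); Omega(0, 0) = 1.0 / (S(0, 0) + lambda);
    return Rcpp::List::create(Rcpp::Named("omega") = Omega,
                              Rcpp::Named("w") = mat(S + lambda),
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true);
  }

  mat W = S + lambda * eye(p, p);
  mat B(p - 1, p, fill::zeros);  // lasso coefficients per column

  // convergence threshold scaled by the mean absolute off-diagonal of S
  double offsum = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) offsum += std::fabs(S(i, j));
  const double offmean = offsum / (double)(p * (p - 1));
  const double thr = tol * std::max(offmean, 1e-12);

  std::vector<uvec> idxs(p);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1); uword c = 0;
    for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
    idxs[j] = idx;
  }

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double change = 0.0;
    for (uword j = 0; j < p; ++j) {
      const uvec& idx = idxs[j];
      mat W11 = W(idx, idx);
      vec s12 = S.col(j); s12 = s12(idx);
      vec beta = B.col(j);
      lasso_cd(W11, s12, lambda, beta, inner_max_iter, inner_tol);
      B.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        change += std::fabs(W(idx(k), j) - w12(k));
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (change / (double)(p * (p - 1)) < thr) { converged = true; break; }
  }

  // Recover Omega column-wise: omega_jj = 1/(w_jj - w12' beta),
  // omega_(idx,j) = -beta * omega_jj.  The two estimates of each symmetric
  // off-diagonal pair are averaged; an entry is an exact zero only when both
  // column problems set it to zero.
  mat Oraw(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    const uvec& idx = idxs[j];
    vec beta = B.col(j);
    vec w12 = W.col(j); w12 = w12(idx);
    const double denom = W(j, j) - dot(w12, beta);
    const double o22 = 1.0 / denom;
    Oraw(j, j) = o22;
    for (uword k = 0; k < p - 1; ++k) Oraw(idx(k), j) = -beta(k) * o22;
  }
  mat Omega(p, p, fill::zeros);
  Omega.diag() = Oraw.diag();
  for (uword i = 0; i < p; ++i) {
    for (uword j = i + 1; j < p; ++j) {
      const double a = Oraw(i, j), b = Oraw(j, i);
      // exact zero only when both column problems agree on zero; the
      // average keeps the estimate close to either one-sided solution
      const double v = (a == 0.0 && b == 0.0) ? 0.0 : 0.5 * (a + b);
      Omega(i, j) = v;
      Omega(j, i) = v;
    }
  }

  return Rcpp::List::create(Rcpp::Named("omega") = Omega,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = converged);
}

// Largest squared singular value of X by deterministic power iteration.
static double sigma_max2(const mat& X) {
  const uword q = X.n_cols;
  vec v(q, fill::ones);
  v /= norm(v);
  double est = 0.0;
  for (int it = 0; it < 60; ++it) {
    vec u = X.t() * (X * v);
    const double nu = norm(u);
    if (nu < 1e-300) return 0.0;
    v = u / nu;
    est = nu;
  }
  return est;  // eigenvalue of X'X, i.e. sigma_max(X)^2
}

// L1-norm SVM with squared hinge loss, no intercept:
//   min_w ||w||_1 + C * sum_i max(0, 1 - y_i x_i' w)^2
// Solved by FISTA with soft-thresholding (exact zeros) and adaptive
// restart; stops when the subgradient optimality conditions hold within
// tol, or at max_iter.
// [[Rcpp::export]]
Rcpp::List l1svm_fista(const arma::mat& X, const arma::vec& y, double C,
                       double tol, int max_iter,
                       Rcpp::Nullable<Rcpp::NumericVector> w0 = R_NilValue) {
  const uword q = X.n_cols;
  const double L = 2.0 * C * sigma_max2(X) * 1.02 + 1e-12;
  const double step = 1.0 / L;

  vec w(q, fill::zeros);
  if (w0.isNotNull()) {
    Rcpp::NumericVector wv(w0);
    if ((uword)wv.size() == q) w = Rcpp::as<vec>(wv);
  }
  vec z = w, wprev = w;
  double t = 1.0;
  bool kkt_ok = false;
  int iter = 0;

  auto loss_grad = [&](const vec& v) -> vec {
    vec m = 1.0 - y % (X * v);
    m.transform([](double x) { return x > 0.0 ? x : 0.0; });
    return -2.0 * C * (X.t() * (y % m));
  };

  for (iter = 1; iter <= max_iter; ++iter) {
    vec g = loss_grad(z);
    vec wn = z - step * g;
    // prox of step * ||.||_1
    for (uword j = 0; j < q; ++j) {
      if (wn(j) > step)       wn(j) -= step;
      else if (wn(j) < -step) wn(j) += step;
      else                    wn(j) = 0.0;
    }
    // adaptive restart (function-scheme-free gradient test)
    if (dot(z - wn, wn - w) > 0.0) { t = 1.0; z = wn; }
    else {
      const double tn = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
      z = wn + ((t - 1.0) / tn) * (wn - w);
      t = tn;
    }
    wprev = w; w = wn;

    if (iter % 10 == 0 || iter == max_iter) {
      vec gw = loss_grad(w);
      double viol = 0.0;
      for (uword j = 0; j < q; ++j) {
        double v;
        if (w(j) > 0.0)      v = std::fabs(gw(j) + 1.0);
        else if (w(j) < 0.0) v = std::fabs(gw(j) - 1.0);
        else                 v = std::max(std::fabs(gw(j)) - 1.0, 0.0);
        if (v > viol) viol = v;
      }
      if (viol < tol) { kkt_ok = true; break; }
    }
  }

  vec m = 1.0 - y % (X * w);
  m.transform([](double x) { return x > 0.0 ? x : 0.0; });
  const double obj = accu(abs(w)) + C * accu(square(m));

  return Rcpp::List::create(Rcpp::Named("weights") = w,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = kkt_ok);
}

// L2-norm SVM with hinge loss, no intercept:
//   min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i x_i' w)
// Dual coordinate descent (cyclic order, deterministic), box 0 <= a_i <= C.
// [[Rcpp::export]]
Rcpp::List l2svm_dcd(const arma::mat& X, const arma::vec& y, double C,
                     double tol, int max_iter) {
  const uword n = X.n_rows, q = X.n_cols;
  vec alpha(n, fill::zeros), w(q, fill::zeros);
  vec Qii(n);
  for (uword i = 0; i < n; ++i) Qii(i) = dot(X.row(i), X.row(i));

  bool converged = false;
  int epoch = 0;
  for (epoch = 1; epoch <= max_iter; ++epoch) {
    double maxPG = 0.0;
    for (uword i = 0; i < n; ++i) {
      const double G = y(i) * dot(w, X.row(i).t()) - 1.0;
      double PG = G;
      if (alpha(i) <= 0.0)      PG = std::min(G, 0.0);
      else if (alpha(i) >= C)   PG = std::max(G, 0.0);
      if (std::fabs(PG) > maxPG) maxPG = std::fabs(PG);
      if (std::fabs(PG) > 1e-14) {
        double anew;
        if (Qii(i) <= 0.0) anew = (G < 0.0) ? C : 0.0;
        else anew = std::min(std::max(alpha(i) - G / Qii(i), 0.0), C);
        if (anew != alpha(i)) {
          w += (anew - alpha(i)) * y(i) * X.row(i).t();
          alpha(i) = anew;
        }
      }
    }
    if (maxPG < tol) { converged = true; break; }
  }

  vec m = 1.0 - y % (X * w);
  m.transform([](double x) { return x > 0.0 ? x : 0.0; });
  const double obj = 0.5 * dot(w, w) + C * accu(m);

  return Rcpp::List::create(Rcpp::Named("weights") = w,
                            Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("iterations") = epoch,
                            Rcpp::Named("converged") = converged);
}
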