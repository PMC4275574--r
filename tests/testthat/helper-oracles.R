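# Independent oracles used to cross-check the compiled solvers.  These use
# different algorithm families than the implementations they validate.

# Penalized Gaussian log-likelihood of a precision estimate.
glasso_objective <- function(omega, S, lambda) {
  ld <- determinant(omega, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  as.numeric(ld$modulus) - sum(omega * S) - lambda * sum(abs(omega))
}

# ADMM solver for the graphical LASSO (eigendecomposition-based X-update,
# elementwise soft-threshold Z-update, penalty on all entries).
glasso_admm <- function(S, lambda, rho = 1, iters = 5000, tol = 1e-9) {
  p <- nrow(S)
  Xm <- diag(p); Z <- diag(p); U <- matrix(0, p, p)
  for (k in seq_len(iters)) {
    A <- rho * (Z - U) - S
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    xi <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    Xm <- e$vectors %*% (xi * t(e$vectors))
    Zold <- Z
    M <- Xm + U
    Z <- sign(M) * pmax(abs(M) - lambda / rho, 0)
    U <- U + Xm - Z
    if (max(abs(Xm - Z)) < tol && max(abs(Z - Zold)) < tol) break
  }
  Z
}

# Smooth convex reformulation of the L1 squared-hinge SVM: w = u - v with
# u, v >= 0 makes the objective differentiable, solved by box-constrained
# L-BFGS-B.  Returns the optimal objective value.
l1svm_oracle_objective <- function(X, y, C) {
  q <- ncol(X)
  fn <- function(uv) {
    w <- uv[1:q] - uv[(q + 1):(2 * q)]
    m <- pmax(0, 1 - y * drop(X %*% w))
    sum(uv) + C * sum(m^2)
  }
  gr <- function(uv) {
    w <- uv[1:q] - uv[(q + 1):(2 * q)]
    m <- pmax(0, 1 - y * drop(X %*% w))
    g <- -2 * C * drop(crossprod(X, y * m))
    c(1 + g, 1 - g)
  }
  o <- stats::optim(rep(0, 2 * q), fn, gr, method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 5000, factr = 1e3))
  o$value
}

# Largest violation of the KKT conditions of the no-bias L2-SVM dual at the
# returned (w, alpha) pair; zero at the optimum of this convex QP.
l2svm_kkt_violation <- function(model, X, y, C) {
  G <- y * drop(X %*% model$weights) - 1
  a <- model$alpha
  recon <- max(abs(model$weights - drop(crossprod(X, a * y))))
  viol <- max(ifelse(a <= 1e-10, pmax(-G, 0),
                     ifelse(a >= C - 1e-10, pmax(G, 0), abs(G))))
  max(viol, recon)
}

# Small deterministic two-group dataset for pipeline-level tests.
tiny_dataset <- function(n_per_group = 5, n_p = 8, n_t = 80, effect = 0.5,
                         seed = 3, subject_noise = 0.05, ...) {
  simulate_dataset(simulation_spec(
    n_p = n_p, n_t = n_t, n_per_group = n_per_group,
    n_diff_edges = 3, effect = effect, seed = seed,
    subject_noise = subject_noise, ...))
}
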