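test_that("sample covariance matches hand arithmetic and the MLE scaling", {
  # 3 time-points x 2 regions toy: columns (1,2,3) and (2,2,5)
  X <- cbind(a = c(1, 2, 3), b = c(2, 2, 5))
  S <- sample_covariance(X)
  # centered columns: (-1,0,1), (-1,-1,2); crossprod/3
  expect_equal(unclass(S),
               matrix(c(2/3, 1, 1, 2), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)
  Su <- sample_covariance(X, unbiased = TRUE)
  expect_equal(unclass(Su), unclass(S) * 3 / 2, ignore_attr = TRUE)

  # identical columns: off-diagonal equals the shared variance
  Y <- cbind(x = rnorm(50))
  Y <- cbind(Y, y = Y[, 1])
  S2 <- sample_covariance(Y)
  expect_equal(S2[1, 2], S2[1, 1])

  expect_error(sample_covariance(cbind(a = rep(1, 10), b = rnorm(10))), "a")
})

test_that("standardized white noise has near-zero off-diagonal covariance", {
  set.seed(123)
  X <- scale(matrix(rnorm(1e4 * 4), 1e4, 4))
  S <- unclass(sample_covariance(X))
  expect_lt(max(abs(S[upper.tri(S)])), 0.05)
})

test_that("Pearson correlation matches the pairwise formula", {
  set.seed(4)
  X <- matrix(rnorm(50 * 4), 50, 4)
  R <- pearson_correlation(X)
  expect_equal(unclass(R), unname(cor(X)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(diag(unclass(R)), rep(1, 4))
  # a column against its negation
  Y <- cbind(a = rnorm(30))
  Y <- cbind(Y, b = -Y[, 1])
  expect_equal(pearson_correlation(Y)[1, 2], -1)
})

test_that("full inverse covariance inverts and flags singular input", {
  S <- new_cov <- structure(diag(c(2, 4)), kind = "covariance")
  P <- full_inverse_covariance(S)
  expect_equal(unclass(P), diag(c(0.5, 0.25)), ignore_attr = TRUE)

  set.seed(8)
  A <- matrix(rnorm(100 * 6), 100, 6)
  S2 <- sample_covariance(A)
  P2 <- full_inverse_covariance(S2)
  expect_lt(max(abs(unclass(P2) %*% unclass(S2) - diag(6))), 1e-8)

  # rank-deficient covariance (more regions than time-points)
  B <- matrix(rnorm(4 * 6), 4, 6)
  expect_error(full_inverse_covariance(sample_covariance(B)), "graphical_lasso")
})

test_that("partial correlation follows the normalized-precision formula", {
  P <- structure(matrix(c(2, -1, -1, 2), 2), kind = "inverse_covariance")
  Th <- partial_correlation(P)
  expect_equal(Th[1, 2], 0.5)
  expect_equal(diag(unclass(Th)), c(1, 1))

  # diagonal precision -> zero partials; zero precision entry -> zero partial
  P2 <- structure(diag(c(1, 2, 3)), kind = "inverse_covariance")
  expect_true(all(unclass(partial_correlation(P2))[upper.tri(diag(3))] == 0))
  chain <- structure(matrix(c(2, -0.5, 0, -0.5, 2, -0.5, 0, -0.5, 2), 3),
                     kind = "inverse_covariance")
  expect_equal(partial_correlation(chain)[1, 3], 0)

  P3 <- structure(matrix(c(-1, 0, 0, 1), 2), kind = "inverse_covariance")
  expect_error(partial_correlation(P3), "diagonal")
})

test_that("partial correlation of an inverted correlation matrix is bounded", {
  set.seed(11)
  X <- matrix(rnorm(200 * 5), 200, 5) %*% matrix(rnorm(25), 5)
  Th <- unclass(partial_correlation(full_inverse_covariance(sample_covariance(X))))
  expect_lt(max(abs(Th - t(Th))), 1e-10)
  expect_true(all(Th >= -1 - 1e-10 & Th <= 1 + 1e-10))
})

test_that("graphical lasso reproduces closed forms", {
  # lambda = 0 on a well-conditioned covariance recovers the plain inverse
  set.seed(21)
  A <- crossprod(matrix(rnorm(60 * 4), 60, 4)) / 60
  om0 <- graphical_lasso(structure(A, kind = "covariance"), 0)
  expect_lt(max(abs(unclass(om0) - solve(A))), 1e-6)

  # 2x2 soft-threshold closed form: |s12| <= lambda kills the off-diagonal
  S <- structure(matrix(c(1, 0.5, 0.5, 1), 2), kind = "covariance")
  om <- graphical_lasso(S, 0.6)
  expect_equal(unclass(om), diag(c(0.625, 0.625)), ignore_attr = TRUE)
  expect_identical(unclass(om)[1, 2], 0)
})

test_that("graphical lasso matches an independent ADMM solver on random problems", {
  set.seed(42)
  for (r in 1:20) {
    A <- matrix(rnorm(25), 5)
    S <- crossprod(A) / 5 + diag(0.5, 5)
    lam <- sample(c(0.05, 0.1, 0.2), 1)
    om <- graphical_lasso(structure(S, kind = "covariance"), lam)
    oracle <- glasso_admm(S, lam)
    gap <- abs(glasso_objective(unclass(om), S, lam) -
                 glasso_objective(oracle, S, lam))
    expect_lt(gap, 1e-6)
    expect_lt(glasso_kkt_residual(om, S, lam), 1e-4)
  }
})

test_that("graphical-lasso support shrinks monotonically with the penalty", {
  set.seed(33)
  X <- matrix(rnorm(100 * 8), 100, 8) %*% (diag(8) + 0.3)
  S <- sample_covariance(X)
  nnz <- sapply(c(0.001, 0.01, 0.1), function(l)
    sum(unclass(graphical_lasso(S, l)) != 0))
  expect_true(all(diff(nnz) <= 0))
})

test_that("BIC combines likelihood and support size as defined", {
  I2 <- structure(diag(2), kind = "sparse_inverse_covariance")
  S <- structure(diag(2), kind = "covariance")
  b <- bic_score(I2, S, n_t = 100)
  # L = logdet(I) - tr(I) = -2; m = 2 diagonal entries; d = 1
  expect_equal(b$loglik, -2)
  expect_equal(b$m, 2)
  expect_equal(b$df, 1)
  expect_equal(b$bic, 4 + log(100))

  # denser precision with the same likelihood scores strictly worse
  set.seed(3)
  X <- matrix(rnorm(300 * 5), 300, 5)
  S5 <- sample_covariance(X)
  om_sparse <- graphical_lasso(S5, 0.1)
  om_dense <- graphical_lasso(S5, 0.001)
  bs <- bic_score(om_sparse, S5, 300)
  bd <- bic_score(om_dense, S5, 300)
  expect_gt(bd$m, bs$m)
  expect_equal(bd$df, bd$m * (bd$m - 1) / 2)

  # independent recomputation from definitions
  om <- om_sparse
  L <- log(det(unclass(om))) - sum(unclass(om) * unclass(S5))
  m <- sum(unclass(om)[lower.tri(unclass(om), diag = TRUE)] != 0)
  expect_equal(bs$bic, -2 * L + m * (m - 1) / 2 * log(300))

  # both-copies counting flag
  b2 <- bic_score(om, S5, 300, count_symmetric = TRUE)
  expect_gte(b2$m, bs$m)
})

test_that("penalty selection pools the group winners onto the grid", {
  set.seed(14)
  # strongly equicorrelated data with long series: every candidate penalty
  # keeps the dense support, so BIC reduces to the likelihood and the
  # smallest penalty wins in each group
  p <- 6
  Sig <- matrix(0.6, p, p); diag(Sig) <- 1
  ch <- chol(Sig)
  mk <- function(seed) {
    set.seed(seed)
    raw_timeseries(matrix(rnorm(1000 * p), 1000, p) %*% ch, tr_seconds = 2,
                   subject_id = paste0("s", seed))
  }
  pats <- list(p1 = mk(1), p2 = mk(2), p3 = mk(3))
  ctls <- list(c1 = mk(4), c2 = mk(5), c3 = mk(6))
  sel <- select_lambda(pats, ctls)
  expect_equal(unname(sel$per_group), c(0.001, 0.001))
  expect_equal(sel$lambda, 0.001)
  expect_true(all(c("group", "fold", "lambda", "bic") %in% names(sel$trace)))
})

test_that("pooled-penalty snapping follows the documented log-scale tie rule", {
  # winners 0.1 and 0.001 average to 0.0505, whose log-scale nearest grid
  # value is 0.1 (log10(0.0505) = -1.30)
  grid <- c(0.1, 0.01, 0.001)
  pooled_raw <- mean(c(0.1, 0.001))
  d <- abs(log(grid) - log(pooled_raw))
  expect_equal(max(grid[d == min(d)]), 0.1)
})

test_that("vectorization uses the canonical lower-triangle order and round-trips", {
  M <- matrix(0, 3, 3)
  M[lower.tri(M)] <- c(21, 31, 32)   # (2,1), (3,1), (3,2) column-major
  M <- M + t(M)
  dimnames(M) <- list(c("A", "B", "C"), c("A", "B", "C"))
  v <- vectorize_lower(M)
  expect_equal(length(v), 3L)
  expect_equal(names(v), c("A|B", "A|C", "B|C"))
  expect_equal(as.vector(v), c(21, 31, 32))
  expect_equal(unname(attr(v, "index_map")[, "i"]), c(2, 3, 3))
  expect_equal(unname(attr(v, "index_map")[, "j"]), c(1, 1, 2))

  M2 <- devectorize_lower(v)
  expect_equal(M2[lower.tri(M2)], as.vector(v))
  expect_equal(unname(M2), unname(M) - diag(diag(M)))

  # q for the full 137-region parcellation
  expect_equal(137 * (137 - 1) / 2, 9316)
  asym <- matrix(rnorm(9), 3)
  expect_error(vectorize_lower(asym), "symmetric")
})
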