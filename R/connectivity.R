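#' @useDynLib sparseFC, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

new_connectivity <- function(mat, kind, lambda = NULL) {
  structure(mat, kind = kind, lambda = lambda,
            class = c("connectivity_matrix", "matrix"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  kind <- attr(x, "kind")
  cat(sprintf("connectivity_matrix (%s), %d x %d", kind, nrow(x), ncol(x)))
  if (!is.null(attr(x, "lambda"))) cat(sprintf(", lambda = %g", attr(x, "lambda")))
  cat("\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

ts_matrix <- function(ts) {
  if (inherits(ts, "fc_timeseries")) ts$data else as.matrix(ts)
}

#' Sample covariance matrix of a regional time-series
#'
#' Centered cross-product scaled by `1/n_t` (the Gaussian maximum-likelihood
#' convention, so that the penalized log-likelihood driving the graphical
#' LASSO is exact), or by `1/(n_t - 1)` when `unbiased = TRUE`.
#'
#' @param ts An `fc_timeseries` or plain matrix (rows = time-points).
#' @param unbiased Use the `n_t - 1` denominator instead of `n_t`.
#' @return A `connectivity_matrix` of kind `"covariance"`.
#' @export
sample_covariance <- function(ts, unbiased = FALSE) {
  X <- ts_matrix(ts)
  n_t <- nrow(X)
  if (n_t < 2L) stop("need at least 2 time-points")
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    bad <- colnames(X)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / if (unbiased) (n_t - 1) else n_t
  dimnames(S) <- list(colnames(X), colnames(X))
  new_connectivity(S, "covariance")
}

#' Pearson correlation matrix of a regional time-series
#'
#' @inheritParams sample_covariance
#' @return A `connectivity_matrix` of kind `"correlation"` with unit
#'   diagonal.
#' @export
pearson_correlation <- function(ts) {
  S <- sample_covariance(ts)
  d <- sqrt(diag(S))
  R <- unclass(S) / tcrossprod(d)
  diag(R) <- 1
  new_connectivity(R, "correlation")
}

#' Full (unregularized) inverse covariance
#'
#' Direct matrix inversion of the sample covariance; only meaningful when
#' the number of regions is smaller than the number of time-points, so the
#' condition number is checked first.
#'
#' @param cov A `connectivity_matrix` of kind `"covariance"`.
#' @param max_condition Largest acceptable 2-norm condition number.
#' @return A `connectivity_matrix` of kind `"inverse_covariance"`.
#' @export
full_inverse_covariance <- function(cov, max_condition = 1e12) {
  stopifnot(identical(attr(cov, "kind"), "covariance"))
  S <- unclass(cov)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > max_condition)
    stop("covariance is singular or ill-conditioned (condition number ",
         format(max(ev) / max(min(ev), .Machine$double.xmin), digits = 3),
         "); use graphical_lasso() instead")
  P <- solve(S)
  P <- (P + t(P)) / 2
  dimnames(P) <- dimnames(S)
  new_connectivity(P, "inverse_covariance")
}

#' Partial correlation from a precision matrix
#'
#' `Theta_ij = -Pi_ij / sqrt(Pi_ii * Pi_jj)` for `i != j`; the diagonal is
#' set to 1 (and is excluded from feature vectors anyway).
#'
#' @param prec A `connectivity_matrix` of kind `"inverse_covariance"` or
#'   `"sparse_inverse_covariance"`.
#' @return A `connectivity_matrix` of kind `"partial_correlation"`.
#' @export
partial_correlation <- function(prec) {
  kind <- attr(prec, "kind")
  stopifnot(kind %in% c("inverse_covariance", "sparse_inverse_covariance"))
  P <- unclass(prec)
  d <- diag(P)
  if (any(d <= 0)) stop("precision matrix has a non-positive diagonal entry")
  Th <- -P / tcrossprod(sqrt(d))
  diag(Th) <- 1
  dimnames(Th) <- dimnames(P)
  new_connectivity(Th, "partial_correlation")
}

#' Graphical-LASSO sparse inverse covariance
#'
#' Finds the positive-definite precision matrix maximizing the penalized
#' Gaussian log-likelihood
#' `log det(Omega) - tr(Omega Sigma) - lambda * ||Omega||_1`,
#' where the L1 norm sums the absolute values of all entries including the
#' diagonal. Solved by block coordinate descent over columns, each step a
#' lasso regression; sparsity comes solely from the penalty (exact zeros
#' from the coordinate-descent solver, no thresholding).
#'
#' @param cov A `connectivity_matrix` of kind `"covariance"` (or a plain
#'   symmetric PSD matrix).
#' @param lambda Regularization penalty, `>= 0`. `lambda = 0` requires an
#'   invertible covariance and recovers its plain inverse.
#' @param tol Convergence tolerance on the mean absolute change of the
#'   working covariance per sweep, relative to the mean absolute
#'   off-diagonal of the input.
#' @param max_iter Maximum number of block-coordinate sweeps.
#' @return A `connectivity_matrix` of kind `"sparse_inverse_covariance"`
#'   with attributes `lambda`, `iterations` and `support` (logical matrix of
#'   exact nonzeros).
#' @export
graphical_lasso <- function(cov, lambda, tol = 1e-4, max_iter = 100) {
  S <- unclass(cov)
  if (max(abs(S - t(S))) > 1e-8 * max(abs(S), 1))
    stop("covariance must be symmetric")
  S <- (S + t(S)) / 2
  if (lambda < 0) stop("lambda must be non-negative")
  if (lambda == 0) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev))
      stop("lambda = 0 requires an invertible covariance")
  }
  res <- glasso_bcd(S, lambda, tol, as.integer(max_iter), 1e-7, 1000L)
  if (!res$converged)
    stop("graphical LASSO did not converge in ", max_iter,
         " sweeps (lambda = ", lambda, "); increase max_iter or tol")
  Om <- res$omega
  if (is.null(tryCatch(chol(Om), error = function(e) NULL)))
    stop("graphical LASSO produced a non-positive-definite estimate; ",
         "the covariance is likely ill-conditioned (scale the data or ",
         "increase lambda)")
  dimnames(Om) <- dimnames(S)
  out <- new_connectivity(Om, "sparse_inverse_covariance", lambda = lambda)
  attr(out, "iterations") <- res$iterations
  attr(out, "support") <- Om != 0
  out
}

#' Subgradient residual of the graphical-LASSO stationarity conditions
#'
#' For diagnostics and testing: the largest violation of
#' `Omega^{-1} - Sigma - lambda * sign(Omega) = 0` (with the sign replaced
#' by the subdifferential interval on zero entries).
#'
#' @param omega Estimated precision matrix.
#' @param cov Sample covariance it was fitted to.
#' @param lambda Penalty used in the fit.
#' @return Largest absolute stationarity violation over all entries.
#' @export
glasso_kkt_residual <- function(omega, cov, lambda) {
  Om <- unclass(omega); S <- unclass(cov)
  G <- solve(Om) - S
  nz <- Om != 0
  v1 <- if (any(nz)) max(abs(G[nz] - lambda * sign(Om[nz]))) else 0
  v0 <- if (any(!nz)) max(pmax(abs(G[!nz]) - lambda, 0)) else 0
  max(v1, v0)
}

#' BIC of a fitted sparse precision matrix
#'
#' `BIC = -2 L + d log(n_t)` with `L = log det(Omega) - tr(Omega Sigma)` and
#' `d = m(m - 1)/2`, where `m` counts the distinct nonzero entries of
#' `Omega` over the lower triangle including the diagonal (each symmetric
#' pair once). Set `count_symmetric = TRUE` to count both symmetric copies
#' instead.
#'
#' @param omega A `connectivity_matrix` of kind `"sparse_inverse_covariance"`
#'   (or any PD precision matrix).
#' @param cov The sample covariance used in the fit.
#' @param n_t Number of time-points behind `cov`.
#' @param count_symmetric Count symmetric off-diagonal copies twice.
#' @return A list with `lambda`, `loglik`, `m`, `df` and `bic`.
#' @export
bic_score <- function(omega, cov, n_t, count_symmetric = FALSE) {
  Om <- unclass(omega); S <- unclass(cov)
  stopifnot(all(dim(Om) == dim(S)))
  ch <- tryCatch(chol(Om), error = function(e) NULL)
  if (is.null(ch)) stop("precision matrix is not positive definite")
  L <- 2 * sum(log(diag(ch))) - sum(Om * S)
  m <- if (count_symmetric) sum(Om != 0)
       else sum(Om[lower.tri(Om, diag = TRUE)] != 0)
  d <- m * (m - 1) / 2
  list(lambda = attr(omega, "lambda"), loglik = L, m = m, df = d,
       bic = -2 * L + d * log(n_t))
}

#' Select the graphical-LASSO penalty by BIC over group-wise inner folds
#'
#' For each inner leave-one-subject-per-group-out fold and each group, the
#' retained subjects' series are concatenated in time, a precision matrix is
#' fitted per candidate penalty, and the BIC-minimizing penalty recorded.
#' Each group's winner is the modal penalty across folds; the pooled value
#' is the arithmetic mean of the two winners snapped to the nearest grid
#' value in log space (the grid is log-spaced; ties toward the larger,
#' i.e. sparser, penalty).
#'
#' @param ts_patients,ts_controls Lists of `fc_timeseries` (one per subject)
#'   for the two groups; both must be non-empty.
#' @param grid Candidate penalties (default `c(0.1, 0.01, 0.001)`).
#' @param tol,max_iter Passed to [graphical_lasso()].
#' @param cache Optional environment in which per-subject centered
#'   cross-products are memoized (they do not depend on the labels, so a
#'   shared cache speeds up label permutations).
#' @return A list with `lambda` (pooled), `per_group` (named winners), and
#'   `trace` (a data frame of per-fold, per-group, per-penalty BIC values).
#' @export
select_lambda <- function(ts_patients, ts_controls,
                          grid = c(0.1, 0.01, 0.001),
                          tol = 1e-4, max_iter = 100, cache = NULL) {
  if (!length(ts_patients) || !length(ts_controls))
    stop("both groups need at least one subject")
  if (!length(grid)) stop("empty penalty grid")
  grid <- sort(unique(grid), decreasing = TRUE)
  groups <- list(patient = ts_patients, control = ts_controls)
  n_folds <- min(lengths(groups))
  trace <- list()
  winners <- c(patient = NA_real_, control = NA_real_)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  xprod <- function(s, id) {
    key <- paste0("xx@", id)
    if (is.null(cache[[key]])) {
      X <- ts_matrix(s)
      Xc <- sweep(X, 2L, colMeans(X))
      cache[[key]] <- list(cp = crossprod(Xc), n = nrow(X))
    }
    cache[[key]]
  }

  for (g in names(groups)) {
    subj <- groups[[g]]
    ids <- names(subj)
    if (is.null(ids)) ids <- vapply(subj, function(s)
      if (inherits(s, "fc_timeseries")) s$subject_id else "", character(1))
    ids <- ifelse(nzchar(ids), ids, paste0(g, seq_along(subj)))
    cps <- lapply(seq_along(subj), function(i) xprod(subj[[i]], ids[i]))
    fold_best <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      keep_idx <- if (length(subj) > 1L) seq_along(subj)[-f] else seq_along(subj)
      keep <- cps[keep_idx]
      subset_key <- paste0("bic@", paste(sort(ids[keep_idx]), collapse = ","))
      bics <- cache[[subset_key]]
      if (is.null(bics) || length(bics) != length(grid)) {
        n_t <- sum(vapply(keep, `[[`, numeric(1), "n"))
        S <- new_connectivity(
          Reduce(`+`, lapply(keep, `[[`, "cp")) / n_t, "covariance")
        bics <- rep(NA_real_, length(grid))
        for (li in seq_along(grid)) {
          om <- tryCatch(graphical_lasso(S, grid[li], tol = tol,
                                         max_iter = max_iter),
                         error = function(e) NULL)
          if (!is.null(om)) bics[li] <- bic_score(om, S, n_t)$bic
        }
        cache[[subset_key]] <- bics
      }
      for (li in seq_along(grid))
        trace[[length(trace) + 1L]] <- data.frame(
          group = g, fold = f, lambda = grid[li], bic = bics[li])
      if (all(is.na(bics))) {
        warning("all penalties failed in ", g, " fold ", f, "; fold skipped")
        next
      }
      fold_best[f] <- grid[which.min(bics)]  # ties: first = larger lambda
    }
    fold_best <- fold_best[!is.na(fold_best)]
    if (!length(fold_best))
      stop("penalty selection failed in every fold for group ", g)
    tab <- table(fold_best)
    modal <- as.numeric(names(tab)[tab == max(tab)])
    winners[g] <- max(modal)  # modal ties toward sparser (larger) penalty
  }

  pooled_raw <- mean(winners)
  dist <- abs(log(grid) - log(pooled_raw))
  cand <- grid[dist == min(dist)]
  pooled <- max(cand)  # snap ties toward the larger (sparser) penalty
  list(lambda = pooled, per_group = winners,
       trace = do.call(rbind, trace))
}

#' Vectorize the lower triangle of a connectivity matrix
#'
#' Canonical edge order: pairs `(i, j)` with `i > j`, `j` ascending then `i`
#' ascending (column-major lower triangle), diagonal excluded, giving
#' `q = n_p (n_p - 1) / 2` features. Names are `"<region_j>|<region_i>"`.
#'
#' @param mat A symmetric `connectivity_matrix` (or plain matrix).
#' @param label Optional class label (`+1`/`-1`) stored as an attribute.
#' @return Named numeric vector of length `q` with attribute `index_map`
#'   (two-column matrix of `(i, j)` pairs, `i > j`).
#' @export
vectorize_lower <- function(mat, label = NULL) {
  M <- unclass(mat)
  if (max(abs(M - t(M))) > 1e-8 * max(abs(M), 1))
    stop("connectivity matrix is not symmetric")
  n_p <- nrow(M)
  lt <- which(lower.tri(M), arr.ind = TRUE)   # column-major: j asc, i asc
  v <- M[lower.tri(M)]
  labs <- rownames(M)
  if (is.null(labs)) labs <- sprintf("R%03d", seq_len(n_p))
  names(v) <- paste(labs[lt[, 2L]], labs[lt[, 1L]], sep = "|")
  attr(v, "index_map") <- cbind(i = lt[, 1L], j = lt[, 2L])
  attr(v, "label") <- label
  v
}

#' Rebuild a symmetric matrix from a lower-triangle feature vector
#'
#' Inverse of [vectorize_lower()]; the diagonal is filled with `diag_value`.
#'
#' @param v Feature vector of length `n_p (n_p - 1) / 2`.
#' @param diag_value Value placed on the diagonal (default 0).
#' @return Symmetric `n_p` x `n_p` matrix.
#' @export
devectorize_lower <- function(v, diag_value = 0) {
  q <- length(v)
  n_p <- (1 + sqrt(1 + 8 * q)) / 2
  if (abs(n_p - round(n_p)) > 1e-9)
    stop("length ", q, " is not a valid lower-triangle size")
  n_p <- as.integer(round(n_p))
  M <- matrix(diag_value, n_p, n_p)
  M[lower.tri(M)] <- v
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  if (!is.null(names(v)) && q >= 1L) {
    first <- strsplit(names(v)[1L], "|", fixed = TRUE)[[1L]][1L]
    labs <- unique(unlist(strsplit(names(v), "|", fixed = TRUE)))
    if (length(labs) == n_p) dimnames(M) <- list(labs, labs)
  }
  M
}
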