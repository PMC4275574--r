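new_linear_model <- function(weights, penalty, C, eps_support = 1e-8,
                             extra = list()) {
  support <- which(abs(weights) > eps_support)
  structure(c(list(weights = weights, penalty = penalty, C = C,
                   support = support,
                   sparsity = length(support) / length(weights),
                   eps_support = eps_support),
              extra),
            class = "fc_svm")
}

#' @export
print.fc_svm <- function(x, ...) {
  cat(sprintf("%s-norm linear SVM (C = %g): %d/%d nonzero weights (%.2f%%)\n",
              x$penalty, x$C, length(x$support), length(x$weights),
              100 * x$sparsity))
  invisible(x)
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y disagree on the number of samples")
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  if (!all(y %in% c(-1, 1))) stop("labels must be coded +1 / -1")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  list(X = X, y = y)
}

#' Train a sparse L1-norm linear SVM (squared hinge loss)
#'
#' Minimizes `||w||_1 + C * sum_i max(0, 1 - y_i w'x_i)^2` with no intercept
#' term, by accelerated proximal gradient descent with soft-thresholding,
#' which yields exact zeros. The decision function is `sign(w'x)`.
#'
#' @param X Feature matrix, samples in rows.
#' @param y Labels coded `+1` (patient) / `-1` (control).
#' @param C Cost parameter, `> 0`: trades margin width against (squared)
#'   hinge violations.
#' @param tol Tolerance on the subgradient optimality conditions.
#' @param max_iter Iteration cap.
#' @param eps_support Magnitude below which a weight is treated as zero when
#'   reporting the support (guards float noise only; the solver produces
#'   exact zeros).
#' @param standardize Z-score the columns of `X` (fitted on these data) before
#'   training; default off.
#' @param init Optional warm-start weight vector (e.g. the solution at a
#'   neighbouring cost on a regularization path).
#' @return An `fc_svm` model with fields `weights`, `support`, `sparsity`,
#'   `objective`, `converged`.
#' @export
train_l1_svm <- function(X, y, C, tol = 1e-6, max_iter = 50000L,
                         eps_support = 1e-8, standardize = FALSE,
                         init = NULL) {
  d <- check_xy(X, y)
  if (C <= 0) stop("C must be positive")
  sc <- NULL
  if (standardize) {
    sc <- list(center = colMeans(d$X), scale = apply(d$X, 2L, stats::sd))
    sc$scale[sc$scale == 0] <- 1
    d$X <- scale(d$X, center = sc$center, scale = sc$scale)
  }
  fit <- l1svm_fista(d$X, d$y, C, tol, as.integer(max_iter),
                     if (is.null(init)) NULL else as.numeric(init))
  w <- drop(fit$weights)
  names(w) <- colnames(X)
  new_linear_model(w, "L1", C, eps_support,
                   extra = list(objective = fit$objective,
                                iterations = fit$iterations,
                                converged = fit$converged,
                                standardize = sc))
}

#' Train a dense L2-norm linear SVM (hinge loss)
#'
#' Minimizes `0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w'x_i)` with no
#' intercept, by coordinate descent on the box-constrained dual.
#'
#' @inheritParams train_l1_svm
#' @param tol Tolerance on the largest projected dual gradient.
#' @return An `fc_svm` model (weights generally dense); the dual variables
#'   are kept in field `alpha`.
#' @export
train_l2_svm <- function(X, y, C, tol = 1e-8, max_iter = 20000L,
                         eps_support = 1e-8, standardize = FALSE) {
  d <- check_xy(X, y)
  if (C <= 0) stop("C must be positive")
  sc <- NULL
  if (standardize) {
    sc <- list(center = colMeans(d$X), scale = apply(d$X, 2L, stats::sd))
    sc$scale[sc$scale == 0] <- 1
    d$X <- scale(d$X, center = sc$center, scale = sc$scale)
  }
  fit <- l2svm_dcd(d$X, d$y, C, tol, as.integer(max_iter))
  w <- drop(fit$weights)
  names(w) <- colnames(X)
  new_linear_model(w, "L2", C, eps_support,
                   extra = list(alpha = drop(fit$alpha),
                                objective = fit$objective,
                                iterations = fit$iterations,
                                converged = fit$converged,
                                standardize = sc))
}

#' Predict group labels with a trained linear model
#'
#' Returns `sign(w'x)` per row; a decision value of exactly zero maps to
#' `+1` so that predictions are total.
#'
#' @param object An `fc_svm` model.
#' @param newdata Feature matrix with the same number of columns the model
#'   was trained on.
#' @param ... Unused.
#' @return Vector of `+1` / `-1` labels with attribute `decision` holding
#'   the raw values `w'x`.
#' @export
predict.fc_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$weights))
    stop("newdata has ", ncol(X), " features; model expects ",
         length(object$weights))
  if (!is.null(object$standardize))
    X <- scale(X, center = object$standardize$center,
               scale = object$standardize$scale)
  dec <- drop(X %*% object$weights)
  lab <- ifelse(dec >= 0, 1, -1)
  attr(lab, "decision") <- dec
  lab
}

#' Effective support of a dense (L2) weight vector
#'
#' Dense models have no exact zeros, so a pseudo-support is defined by
#' zeroing the largest set of smallest-magnitude nonzero weights whose
#' cumulative absolute sum stays within a fraction (default 1%) of the L1
#' norm of `w`; the surviving indices are returned.
#'
#' @param model An `fc_svm` with L2 penalty, or a plain numeric weight
#'   vector.
#' @param fraction Fraction of `||w||_1` allowed to be discarded.
#' @return Integer vector of surviving feature indices (empty for an
#'   all-zero weight vector).
#' @export
l2_stability_support <- function(model, fraction = 0.01) {
  w <- if (inherits(model, "fc_svm")) {
    if (!identical(model$penalty, "L2"))
      stop("l2_stability_support() applies to L2-penalized models")
    model$weights
  } else as.numeric(model)
  nz <- which(w != 0)
  if (!length(nz)) return(integer(0))
  a <- abs(w[nz])
  ord <- order(a)
  budget <- fraction * sum(a) * (1 + 1e-12)  # tolerate float round-off
  cum <- cumsum(a[ord])
  drop_n <- sum(cum <= budget)
  if (drop_n >= length(nz)) return(integer(0))
  sort(nz[ord[seq.int(drop_n + 1L, length(nz))]])
}

#' Model support used for stability computations
#'
#' Exact nonzeros for L1 models; the trimmed pseudo-support of
#' [l2_stability_support()] for L2 models.
#'
#' @param model An `fc_svm`.
#' @param fraction Passed to [l2_stability_support()] for L2 models.
#' @return Integer vector of feature indices.
#' @export
model_support <- function(model, fraction = 0.01) {
  if (identical(model$penalty, "L1")) model$support
  else l2_stability_support(model, fraction)
}
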