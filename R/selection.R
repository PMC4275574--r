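#' Leave-one-subject-per-group-out fold plan
#'
#' Each fold holds out exactly one patient and one control; pairing is by
#' within-group ordinal position after sorting subject identifiers, so the
#' plan is deterministic. Groups must be balanced.
#'
#' @param manifest Data frame with columns `subject_id` and `group`
#'   (`+1` patient / `-1` control).
#' @return An object of class `fold_plan`: a list of folds, each with
#'   `test` (the held-out patient/control pair) and `train` (all remaining
#'   subject ids).
#' @export
make_losgo_folds <- function(manifest) {
  stopifnot(all(c("subject_id", "group") %in% names(manifest)))
  pats <- sort(as.character(manifest$subject_id[manifest$group == 1]))
  ctls <- sort(as.character(manifest$subject_id[manifest$group == -1]))
  if (length(pats) != length(ctls))
    stop("groups are unbalanced (", length(pats), " patients vs ",
         length(ctls), " controls); leave-one-subject-per-group-out ",
         "requires equal group sizes")
  if (!length(pats)) stop("empty manifest")
  folds <- lapply(seq_along(pats), function(f) {
    test <- c(pats[f], ctls[f])
    list(test = test, train = c(pats[-f], ctls[-f]))
  })
  structure(folds, class = "fold_plan", n_per_group = length(pats))
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d leave-one-subject-per-group-out folds\n",
              length(x)))
  invisible(x)
}

#' Chance-corrected pairwise support overlap
#'
#' `O = (|Ia ∩ Ib| - E) / max(|Ia|, |Ib|)` with `E = |Ia| |Ib| / q`, the
#' expected intersection of two uniformly random supports of the same
#' sizes. Identical supports of size `k` give `1 - k/q`; independent random
#' supports average 0. If either support is empty the overlap is 0 (with a
#' warning when both are).
#'
#' @param I_a,I_b Integer index sets (subsets of `1..q`).
#' @param q Total number of features.
#' @return Scalar overlap, at most 1.
#' @export
pairwise_overlap <- function(I_a, I_b, q) {
  if (q <= 0) stop("q must be positive")
  na <- length(I_a); nb <- length(I_b)
  if (na == 0L && nb == 0L) {
    warning("both supports empty; overlap defined as 0")
    return(0)
  }
  if (na == 0L || nb == 0L) return(0)
  inter <- length(intersect(I_a, I_b))
  e <- na * nb / q
  (inter - e) / max(na, nb)
}

#' Mean pairwise stability of a set of supports
#'
#' Average of [pairwise_overlap()] over all ordered pairs of distinct
#' folds; since the overlap is symmetric this equals the unordered mean.
#'
#' @param supports List of integer index sets (one per fold), length >= 2.
#' @param q Total number of features.
#' @return A list with `mean` (the stability), `pairwise` (vector of the
#'   unordered pairwise overlaps) and `sd` (their standard deviation).
#' @export
mean_stability <- function(supports, q) {
  N <- length(supports)
  if (N < 2L) stop("need at least 2 supports")
  vals <- numeric(0)
  for (a in seq_len(N - 1L))
    for (b in seq.int(a + 1L, N))
      vals <- c(vals, pairwise_overlap(supports[[a]], supports[[b]], q))
  list(mean = mean(vals), pairwise = vals, sd = stats::sd(vals))
}

#' Distance to the ideal accuracy/stability point
#'
#' `D = sqrt((1 - Acc)^2 + (1 - Obar)^2)`: the hyperparameter minimizing D
#' jointly favors predictive accuracy and support stability.
#'
#' @param acc Accuracy in `[0, 1]`.
#' @param stability Mean support overlap.
#' @return Scalar distance.
#' @export
selection_distance <- function(acc, stability) {
  sqrt((1 - acc)^2 + (1 - stability)^2)
}

# ---- feature construction ---------------------------------------------------

#' Connectivity feature vector for one subject
#'
#' Computes the requested connectivity matrix from a (cleaned) time-series
#' and vectorizes its lower triangle.
#'
#' @param ts An `fc_timeseries`.
#' @param kind One of `"correlation"`, `"inverse_covariance"`,
#'   `"partial_correlation"`, `"sparse_inverse_covariance"`.
#' @param lambda Graphical-LASSO penalty (required for the sparse kind).
#' @param unbiased Covariance denominator flag, see [sample_covariance()].
#' @param ... Passed to [graphical_lasso()].
#' @return Named feature vector (see [vectorize_lower()]).
#' @export
connectivity_features <- function(ts,
                                  kind = c("sparse_inverse_covariance",
                                           "correlation",
                                           "inverse_covariance",
                                           "partial_correlation"),
                                  lambda = NULL, unbiased = FALSE, ...) {
  kind <- match.arg(kind)
  S <- sample_covariance(ts, unbiased = unbiased)
  M <- switch(kind,
    correlation = pearson_correlation(ts),
    inverse_covariance = full_inverse_covariance(S),
    partial_correlation = partial_correlation(full_inverse_covariance(S)),
    sparse_inverse_covariance = {
      if (is.null(lambda))
        stop("sparse_inverse_covariance features need a lambda")
      graphical_lasso(S, lambda, ...)
    })
  vectorize_lower(M)
}

# features for a set of subjects, with caching across lambda values
feature_matrix <- function(ts_list, ids, kind, lambda, cache, ...) {
  key <- function(id) paste(id, kind, format(lambda), sep = "@")
  rows <- lapply(ids, function(id) {
    k <- key(id)
    if (is.null(cache[[k]]))
      cache[[k]] <- connectivity_features(ts_list[[id]], kind,
                                          lambda = lambda, ...)
    cache[[k]]
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  X
}

# ---- nested cross-validation ------------------------------------------------

#' Nested cross-validation with joint accuracy/stability model selection
#'
#' Outer leave-one-subject-per-group-out (LOSGO) folds estimate the
#' generalization performance; inside each outer fold an inner LOSGO loop
#' (which never sees the outer held-out pair) selects the hyperparameters.
#' For sparse-inverse-covariance features the graphical-LASSO penalty is
#' chosen per outer fold by [select_lambda()]; the SVM cost is chosen as
#' the modal minimizer, across inner folds, of the distance
#' [selection_distance()] computed from that fold's held-out accuracy and
#' the inner-loop support stability at each candidate cost (ties toward the
#' smaller, sparser cost). The model is then retrained on the full outer
#' training set and the two held-out subjects are predicted.
#'
#' @param dataset An `fc_dataset` (see [fc_dataset()]), e.g. from
#'   [simulate_dataset()].
#' @param feature_kind Connectivity feature to classify on.
#' @param penalty `"L1"` (sparse, squared hinge) or `"L2"` (dense, hinge).
#' @param C_grid Candidate SVM costs (default `10^(-5:5)`).
#' @param lambda_grid Candidate graphical-LASSO penalties.
#' @param aggregate_D Select the cost by aggregating inner accuracies first
#'   and taking a single arg-min of D, instead of the default mode of
#'   per-fold arg-mins.
#' @param stability_fraction Trim fraction for the L2 pseudo-support.
#' @param svm_tol,svm_max_iter,glasso_tol,glasso_max_iter Solver controls.
#' @param unbiased Covariance denominator flag.
#' @param cache Optional environment memoizing per-subject features and
#'   cross-products; these do not depend on the labels, so one cache can be
#'   shared across label permutations.
#' @param verbose Print per-fold progress.
#' @return A `cv_report`: per-fold parameters and predictions, pooled
#'   accuracy/sensitivity/specificity (percent), sparsity and stability
#'   summaries, and the settings used.
#' @export
nested_cv <- function(dataset,
                      feature_kind = c("sparse_inverse_covariance",
                                       "correlation", "inverse_covariance",
                                       "partial_correlation"),
                      penalty = c("L1", "L2"),
                      C_grid = 10^seq(-5, 5),
                      lambda_grid = c(0.1, 0.01, 0.001),
                      aggregate_D = FALSE,
                      stability_fraction = 0.01,
                      svm_tol = 1e-5, svm_max_iter = 20000L,
                      glasso_tol = 1e-4, glasso_max_iter = 100L,
                      unbiased = FALSE, cache = NULL, verbose = FALSE) {
  feature_kind <- match.arg(feature_kind)
  penalty <- match.arg(penalty)
  if (!length(C_grid)) stop("empty C grid")
  C_grid <- sort(unique(C_grid))
  manifest <- dataset$manifest
  ts_list <- dataset$ts
  labels <- stats::setNames(manifest$group, as.character(manifest$subject_id))
  outer <- make_losgo_folds(manifest)
  sparse <- feature_kind == "sparse_inverse_covariance"
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  train_fun <- if (penalty == "L1") train_l1_svm else train_l2_svm

  fold_rows <- list(); pred_rows <- list()
  outer_supports <- list(); outer_sparsity <- numeric(0)
  n_fail <- 0L
  q <- NULL

  for (f in seq_along(outer)) {
    fold <- outer[[f]]
    res <- tryCatch({
      lam <- NA_real_
      if (sparse) {
        tr_man <- manifest[manifest$subject_id %in% fold$train, ]
        lam <- select_lambda(
          ts_list[as.character(tr_man$subject_id[tr_man$group == 1])],
          ts_list[as.character(tr_man$subject_id[tr_man$group == -1])],
          grid = lambda_grid, tol = glasso_tol,
          max_iter = glasso_max_iter, cache = cache)$lambda
      }
      feats <- function(ids) feature_matrix(ts_list, ids, feature_kind, lam,
                                            cache, tol = glasso_tol,
                                            max_iter = glasso_max_iter,
                                            unbiased = unbiased)
      inner <- make_losgo_folds(manifest[manifest$subject_id %in% fold$train, ])
      n_inner <- length(inner); n_C <- length(C_grid)
      acc <- matrix(NA_real_, n_inner, n_C)
      sup <- vector("list", n_inner * n_C)
      dim(sup) <- c(n_inner, n_C)
      for (g in seq_len(n_inner)) {
        Xtr <- feats(inner[[g]]$train); Xte <- feats(inner[[g]]$test)
        ytr <- labels[inner[[g]]$train]; yte <- labels[inner[[g]]$test]
        w_warm <- NULL
        for (ci in seq_len(n_C)) {
          m <- if (penalty == "L1")
            train_l1_svm(Xtr, ytr, C_grid[ci], tol = svm_tol,
                         max_iter = svm_max_iter, init = w_warm)
          else train_fun(Xtr, ytr, C_grid[ci], tol = svm_tol,
                         max_iter = svm_max_iter)
          if (penalty == "L1") w_warm <- m$weights
          acc[g, ci] <- mean(predict(m, Xte) == yte)
          sup[[g, ci]] <- model_support(m, stability_fraction)
        }
      }
      q <- ncol(feats(fold$test[1L]))
      stab_C <- vapply(seq_len(n_C), function(ci)
        suppressWarnings(mean_stability(sup[, ci], q)$mean), numeric(1))
      if (aggregate_D) {
        D <- selection_distance(colMeans(acc), stab_C)
        C_star <- C_grid[which.min(D)]   # ties: first = smallest C
      } else {
        picks <- vapply(seq_len(n_inner), function(g) {
          D <- selection_distance(acc[g, ], stab_C)
          C_grid[which.min(D)]
        }, numeric(1))
        tab <- table(picks)
        C_star <- min(as.numeric(names(tab)[tab == max(tab)]))
      }
      Xtr <- feats(fold$train); Xte <- feats(fold$test)
      final <- train_fun(Xtr, labels[fold$train], C_star, tol = svm_tol,
                         max_iter = svm_max_iter)
      pr <- predict(final, Xte)
      list(lambda = lam, C = C_star, model = final, pred = pr,
           inner_acc = mean(acc), inner_stab = stab_C[match(C_star, C_grid)])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_fail <- n_fail + 1L
      warning("outer fold ", f, " failed: ", conditionMessage(res))
      next
    }
    supp <- model_support(res$model, stability_fraction)
    outer_supports[[length(outer_supports) + 1L]] <- supp
    outer_sparsity <- c(outer_sparsity,
                        if (penalty == "L1") res$model$sparsity else NA_real_)
    fold_rows[[f]] <- data.frame(
      fold = f, test_patient = fold$test[1L], test_control = fold$test[2L],
      lambda = res$lambda, C = res$C, n_support = length(supp),
      sparsity = res$model$sparsity, inner_accuracy = res$inner_acc,
      inner_stability = res$inner_stab)
    pred_rows[[f]] <- data.frame(
      fold = f, subject_id = fold$test, truth = labels[fold$test],
      predicted = as.numeric(res$pred),
      decision = attr(res$pred, "decision"))
    if (verbose)
      message(sprintf("fold %d/%d: lambda=%s C=%g |support|=%d",
                      f, length(outer), format(res$lambda), res$C,
                      length(supp)))
  }

  if (n_fail > length(outer) / 2)
    stop("more than half of the outer folds failed (", n_fail, "/",
         length(outer), ")")

  preds <- do.call(rbind, pred_rows)
  rownames(preds) <- NULL
  conf <- confusion_table(preds$truth, preds$predicted)
  perf <- performance(conf)
  stab <- if (length(outer_supports) >= 2L)
    suppressWarnings(mean_stability(outer_supports, q)) else
    list(mean = NA_real_, pairwise = NA_real_, sd = NA_real_)

  structure(list(
    folds = do.call(rbind, fold_rows),
    predictions = preds,
    confusion = conf,
    metrics = perf,
    sparsity = list(mean = mean(outer_sparsity) * 100,
                    sd = stats::sd(outer_sparsity) * 100),
    stability = list(mean = stab$mean * 100, sd = stab$sd * 100,
                     pairwise = stab$pairwise),
    supports = outer_supports,
    q = q, n_failed = n_fail,
    settings = list(feature_kind = feature_kind, penalty = penalty,
                    C_grid = C_grid, lambda_grid = lambda_grid,
                    aggregate_D = aggregate_D,
                    stability_fraction = stability_fraction)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Nested LOSGO cross-validation (%s features, %s-norm SVM)\n",
              x$settings$feature_kind, x$settings$penalty))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              m$accuracy, m$sensitivity, m$specificity))
  if (!is.na(x$sparsity$mean))
    cat(sprintf("  sparsity %.2f%% +/- %.2f%%\n",
                x$sparsity$mean, x$sparsity$sd))
  cat(sprintf("  stability %.2f%% +/- %.2f%%\n",
              x$stability$mean, x$stability$sd))
  invisible(x)
}

#' Refit the final model on the whole dataset at the median parameters
#'
#' Takes the median of the per-fold selected cost (snapped down to the
#' nearest grid value when it falls between grid points) and of the per-fold
#' penalty (snapped up, i.e. toward the sparser fit), and retrains on all
#' subjects.
#'
#' @param dataset The `fc_dataset` used in [nested_cv()].
#' @param cv_report The report returned by [nested_cv()].
#' @param ... Solver controls forwarded to the trainer.
#' @return An `fc_svm` with attributes `lambda` and `feature_names`.
#' @export
refit_final <- function(dataset, cv_report, ...) {
  folds <- cv_report$folds
  if (is.null(folds) || !nrow(folds)) stop("cv_report contains no folds")
  st <- cv_report$settings
  medC <- stats::median(folds$C)
  C_star <- if (medC %in% st$C_grid) medC else {
    below <- st$C_grid[st$C_grid <= medC]
    if (length(below)) max(below) else min(st$C_grid)
  }
  lam <- NA_real_
  if (st$feature_kind == "sparse_inverse_covariance") {
    medL <- stats::median(folds$lambda)
    lam <- if (medL %in% st$lambda_grid) medL else {
      above <- st$lambda_grid[st$lambda_grid >= medL]
      if (length(above)) min(above) else max(st$lambda_grid)
    }
  }
  ids <- as.character(dataset$manifest$subject_id)
  labels <- stats::setNames(dataset$manifest$group, ids)
  cache <- new.env(parent = emptyenv())
  X <- feature_matrix(dataset$ts, ids, st$feature_kind, lam, cache)
  train_fun <- if (st$penalty == "L1") train_l1_svm else train_l2_svm
  model <- train_fun(X, labels[ids], C_star, ...)
  attr(model, "lambda") <- lam
  attr(model, "feature_names") <- colnames(X)
  model
}
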