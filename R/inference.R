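#' Confusion table for a balanced two-group classification
#'
#' Patients (`+1`) are the positive class.
#'
#' @param truth,predicted Vectors of `+1` / `-1` labels.
#' @return A list with counts `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_table <- function(truth, predicted) {
  truth <- as.numeric(truth); predicted <- as.numeric(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c(-1, 1)), all(predicted %in% c(-1, 1)))
  list(TP = sum(truth == 1 & predicted == 1),
       FP = sum(truth == -1 & predicted == 1),
       TN = sum(truth == -1 & predicted == -1),
       FN = sum(truth == 1 & predicted == -1))
}

#' Accuracy, sensitivity and specificity of a confusion table
#'
#' `sensitivity = TP/(TP + FN)` (patients classified as patients),
#' `specificity = TN/(TN + FP)`, `accuracy = (TP + TN)/n`; all reported in
#' percent. A zero denominator yields `NA` for that quantity rather than 0.
#'
#' @param conf A confusion table from [confusion_table()], or a list/vector
#'   with elements `TP`, `FP`, `TN`, `FN`.
#' @return A list with `accuracy`, `sensitivity`, `specificity` (percent).
#' @export
performance <- function(conf) {
  conf <- as.list(conf)
  tp <- conf$TP; fp <- conf$FP; tn <- conf$TN; fn <- conf$FN
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  n <- tp + fp + tn + fn
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(accuracy = pct(tp + tn, n),
       sensitivity = pct(tp, tp + fn),
       specificity = pct(tn, tn + fp))
}

#' Permutation-test p-value
#'
#' `p = max(1/n_perm, n_ge/n_perm)`, where `n_ge` counts permutations whose
#' statistic is equal to or more extreme than the observed one; the floor
#' `1/n_perm` reflects that the observed labelling is itself one admissible
#' relabelling.
#'
#' @param n_ge Number of permutations at least as extreme as observed.
#' @param n_perm Total number of permutations (at least 1).
#' @return The p-value.
#' @export
permutation_pvalue <- function(n_ge, n_perm) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (n_ge < 0 || n_ge > n_perm) stop("n_ge must lie in [0, n_perm]")
  max(1 / n_perm, n_ge / n_perm)
}

shuffle_labels <- function(manifest, stratified = FALSE) {
  m <- manifest
  if (stratified) {
    # permute subject-to-label assignment within matched pairs
    for (pair in seq_len(sum(m$group == 1))) {
      idx <- c(which(m$group == 1)[pair], which(m$group == -1)[pair])
      m$group[idx] <- sample(m$group[idx])
    }
  } else {
    m$group <- sample(m$group)
  }
  m
}

#' Permutation test of the pooled cross-validated accuracy
#'
#' Uniformly shuffles the subject labels and reruns the entire nested
#' cross-validation for each permutation; the p-value counts permuted
#' accuracies equal to or higher than the observed one, with the `1/n_perm`
#' floor of [permutation_pvalue()]. Permutation `i` is seeded with
#' `seed + i` for exact replay.
#'
#' @param dataset An `fc_dataset`.
#' @param observed Optional `cv_report` for the true labels; computed when
#'   missing.
#' @param n_perm Number of permutations (default 100).
#' @param seed Base random seed.
#' @param stratified Shuffle within matched patient/control pairs instead
#'   of over all subjects.
#' @param ... Passed to [nested_cv()] (feature kind, penalty, grids, ...).
#' @return A list of class `permutation_null` with the observed accuracy,
#'   the null accuracies, the p-value, and the seeds used.
#' @export
permutation_test_accuracy <- function(dataset, observed = NULL,
                                      n_perm = 100, seed = 1,
                                      stratified = FALSE, ...) {
  cache <- new.env(parent = emptyenv())
  if (is.null(observed)) observed <- nested_cv(dataset, cache = cache, ...)
  obs_acc <- observed$metrics$accuracy
  null_acc <- rep(NA_real_, n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(seed + i)
    d_perm <- dataset
    d_perm$manifest <- shuffle_labels(dataset$manifest, stratified)
    rep_i <- tryCatch(suppressWarnings(nested_cv(d_perm, cache = cache, ...)),
                      error = function(e) e)
    if (inherits(rep_i, "error")) {
      warning("permutation ", i, " failed: ", conditionMessage(rep_i))
      next
    }
    null_acc[i] <- rep_i$metrics$accuracy
  }
  ok <- !is.na(null_acc)
  if (!any(ok)) stop("every permutation failed")
  n_eff <- sum(ok)
  p <- permutation_pvalue(sum(null_acc[ok] >= obs_acc), n_eff)
  structure(list(observed = obs_acc, null_values = null_acc[ok],
                 n_perm = n_eff, p_value = p, seed = seed,
                 stratified = stratified),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation test: observed %.2f%%, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Permutation test of the per-edge classifier weights
#'
#' Reruns the whole framework (nested cross-validation plus final
#' median-parameter refit) on label-shuffled data for each permutation,
#' building a null distribution for every edge weight. Per-edge two-sided
#' p-values, `#{|w_null| >= |w_obs|}/n_perm`, are corrected by the
#' Benjamini-Hochberg step-up procedure over all `q` edges. By default the
#' per-edge p-value is not floored at `1/n_perm`: an edge whose observed
#' magnitude exceeds every permuted one gets p = 0, without which no edge
#' could ever survive an FDR correction across all `q` edges at feasible
#' permutation counts (`floor_p = TRUE` restores the conservative floor).
#'
#' @param dataset An `fc_dataset`.
#' @param model The final model from [refit_final()] on the true labels.
#' @param cv_report The `cv_report` the model was refit from (provides the
#'   feature kind, penalty and grids reused under each permutation).
#' @param n_perm Number of permutations.
#' @param seed Base random seed; permutation `i` uses `seed + i`.
#' @param fdr_q FDR level for the Benjamini-Hochberg correction.
#' @param floor_p Floor the per-edge p-values at `1/n_perm` (conservative;
#'   makes FDR-corrected significance unattainable for large `q`).
#' @param normalize Compare unit-L2-normalized weight vectors instead of
#'   raw weights (default). The decision function `sign(w'x)` is invariant
#'   to positive rescaling of `w`, and permuted refits may select a
#'   different cost `C` than the observed refit, which rescales the whole
#'   weight vector; normalization removes that scale confound so the null
#'   compares discriminative structure, not regularization level.
#' @param stratified Shuffle within matched pairs.
#' @param ... Extra arguments forwarded to [nested_cv()] under each
#'   permutation (e.g. solver controls).
#' @return A `discriminative_network`: data frame of the refit support
#'   edges (regions, weight, p-value, FDR-adjusted p, significance flag),
#'   per-region degrees among significant edges, and the full per-edge
#'   p-value vector.
#' @export
permutation_test_weights <- function(dataset, model, cv_report,
                                     n_perm = 100, seed = 1, fdr_q = 0.05,
                                     floor_p = FALSE, normalize = TRUE,
                                     stratified = FALSE, ...) {
  st <- cv_report$settings
  w_obs <- model$weights
  q <- length(w_obs)
  cache <- new.env(parent = emptyenv())
  null_w <- matrix(NA_real_, nrow = n_perm, ncol = q)
  for (i in seq_len(n_perm)) {
    set.seed(seed + i)
    d_perm <- dataset
    d_perm$manifest <- shuffle_labels(dataset$manifest, stratified)
    res <- tryCatch({
      rep_i <- suppressWarnings(nested_cv(
        d_perm, feature_kind = st$feature_kind, penalty = st$penalty,
        C_grid = st$C_grid, lambda_grid = st$lambda_grid,
        aggregate_D = st$aggregate_D,
        stability_fraction = st$stability_fraction, cache = cache, ...))
      suppressWarnings(refit_final(d_perm, rep_i))$weights
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("permutation ", i, " failed: ", conditionMessage(res))
      next
    }
    null_w[i, ] <- res
  }
  ok <- stats::complete.cases(null_w)
  if (!any(ok)) stop("every permutation failed")
  null_w <- null_w[ok, , drop = FALSE]
  n_eff <- nrow(null_w)
  w_cmp <- w_obs
  if (normalize) {
    unit <- function(w) { nw <- sqrt(sum(w^2)); if (nw > 0) w / nw else w }
    w_cmp <- unit(w_obs)
    null_w <- t(apply(null_w, 1L, unit))
  }
  n_ge <- colSums(abs(null_w) >= matrix(abs(w_cmp), n_eff, q, byrow = TRUE))
  p <- n_ge / n_eff
  if (floor_p) p <- pmax(1 / n_eff, p)
  p_adj <- stats::p.adjust(p, method = "BH")
  sig <- p_adj <= fdr_q

  nm <- attr(model, "feature_names")
  if (is.null(nm)) nm <- names(w_obs)
  if (is.null(nm)) nm <- paste0("e", seq_len(q))
  pairs <- do.call(rbind, strsplit(nm, "|", fixed = TRUE))
  idx <- model$support
  edges <- data.frame(region_a = pairs[idx, 1L], region_b = pairs[idx, 2L],
                      weight = unname(w_obs[idx]), p_value = p[idx],
                      p_adjusted = p_adj[idx], significant = sig[idx])
  edges <- edges[order(edges$p_adjusted, -abs(edges$weight)), ]
  rownames(edges) <- NULL
  net <- structure(list(edges = edges,
                        node_degrees = NULL,
                        p_values = stats::setNames(p, nm),
                        p_adjusted = stats::setNames(p_adj, nm),
                        n_perm = n_eff, fdr_q = fdr_q, seed = seed),
                   class = "discriminative_network")
  net$node_degrees <- node_degrees(net)
  net
}

#' @export
print.discriminative_network <- function(x, ...) {
  cat(sprintf(
    "discriminative network: %d support edges, %d significant (FDR %.2g, %d permutations)\n",
    nrow(x$edges), sum(x$edges$significant), x$fdr_q, x$n_perm))
  if (nrow(x$edges)) print(utils::head(x$edges, 10L))
  invisible(x)
}

#' Node degrees of the significant discriminative edges
#'
#' Counts, for each region, the number of FDR-significant edges it touches;
#' regions with high degree are the most discriminative hubs.
#'
#' @param net A `discriminative_network`.
#' @return Named integer vector sorted in decreasing order (empty when no
#'   edge is significant).
#' @export
node_degrees <- function(net) {
  ed <- net$edges[net$edges$significant, , drop = FALSE]
  if (!nrow(ed)) return(stats::setNames(integer(0), character(0)))
  tab <- table(c(ed$region_a, ed$region_b))
  sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}
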