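manifest_of <- function(n) data.frame(
  subject_id = c(sprintf("p%02d", 1:n), sprintf("c%02d", 1:n)),
  group = rep(c(1, -1), each = n))

test_that("LOSGO folds hold out one subject per group exactly once", {
  for (n in c(2, 19, 30)) {
    plan <- make_losgo_folds(manifest_of(n))
    expect_length(plan, n)
    held_p <- sapply(plan, function(f) f$test[1])
    held_c <- sapply(plan, function(f) f$test[2])
    expect_setequal(held_p, sprintf("p%02d", 1:n))
    expect_setequal(held_c, sprintf("c%02d", 1:n))
    for (f in plan) {
      expect_length(intersect(f$test, f$train), 0)
      expect_length(c(f$test, f$train), 2 * n)
    }
    # inner plans never contain the outer held-out pair
    m <- manifest_of(n)
    inner <- make_losgo_folds(m[m$subject_id %in% plan[[1]]$train, ])
    expect_length(inner, n - 1)
    for (g in inner)
      expect_length(intersect(c(g$test, g$train), plan[[1]]$test), 0)
  }
  expect_error(make_losgo_folds(data.frame(subject_id = c("a", "b", "c"),
                                           group = c(1, 1, -1))),
               "unbalanced")
})

test_that("pairwise overlap follows the chance-corrected formula", {
  expect_equal(pairwise_overlap(1:10, 1:10, 100), 0.9)         # (10-1)/10
  expect_equal(pairwise_overlap(1:5, 6:10, 50), -0.1)          # (0-0.5)/5
  expect_equal(pairwise_overlap(integer(0), 1:3, 10), 0)
  expect_warning(o <- pairwise_overlap(integer(0), integer(0), 10), "empty")
  expect_equal(o, 0)
  expect_error(pairwise_overlap(1:2, 1:2, 0), "positive")
})

test_that("random supports have mean overlap near zero", {
  set.seed(99)
  q <- 100; k <- 10
  vals <- replicate(1e4, pairwise_overlap(sample.int(q, k), sample.int(q, k), q))
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("mean stability equals the brute-force double loop", {
  sup <- list(c(1, 2, 3), c(2, 3, 4), c(1, 5, 9))
  q <- 20
  st <- mean_stability(sup, q)
  brute <- c()
  for (a in 1:3) for (b in 1:3) if (a != b)
    brute <- c(brute, pairwise_overlap(sup[[a]], sup[[b]], q))
  expect_equal(st$mean, mean(brute))

  # identical supports of size k give 1 - k/q
  same <- mean_stability(list(1:5, 1:5, 1:5), 50)
  expect_equal(same$mean, 1 - 5 / 50)
  # two supports: the mean is the single pairwise value
  two <- mean_stability(list(1:4, 3:6), 40)
  expect_equal(two$mean, pairwise_overlap(1:4, 3:6, 40))
  expect_error(mean_stability(list(1:3), 10), "at least 2")
})

test_that("stability is invariant to a relabelling of the features", {
  set.seed(5)
  q <- 60
  sup <- replicate(4, sample.int(q, 12), simplify = FALSE)
  perm <- sample.int(q)
  sup_p <- lapply(sup, function(s) perm[s])
  expect_equal(mean_stability(sup, q)$mean, mean_stability(sup_p, q)$mean)
})

test_that("the selection distance measures distance to the ideal point", {
  expect_equal(selection_distance(1, 1), 0)
  expect_equal(selection_distance(0.5, 0.5), sqrt(0.5))
  expect_equal(selection_distance(1, 0), 1)
})

test_that("nested CV separates a strong planted effect and stays leak-free", {
  ds <- tiny_dataset(n_per_group = 6, effect = 0.6, seed = 3)
  cv <- nested_cv(ds, C_grid = 10^seq(-2, 2))
  expect_gte(cv$metrics$accuracy, 80)
  expect_equal(nrow(cv$predictions), 12)
  expect_setequal(cv$predictions$subject_id, ds$manifest$subject_id)
  expect_equal(cv$q, 8 * 7 / 2)
  expect_true(all(cv$folds$lambda %in% c(0.1, 0.01, 0.001)))
  expect_true(all(cv$folds$C %in% 10^seq(-2, 2)))
  # deterministic: identical inputs give identical reports
  cv2 <- nested_cv(ds, C_grid = 10^seq(-2, 2))
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("a single-value C grid degenerates gracefully", {
  ds <- tiny_dataset(n_per_group = 3, seed = 5)
  cv <- nested_cv(ds, C_grid = 1, lambda_grid = c(0.1, 0.01))
  expect_true(all(cv$folds$C == 1))
  expect_true(is.finite(cv$metrics$accuracy))
  expect_error(nested_cv(ds, C_grid = numeric(0)), "empty")
})

test_that("L2 models flow through the same selection machinery", {
  ds <- tiny_dataset(n_per_group = 4, effect = 0.6, seed = 6)
  cv <- nested_cv(ds, feature_kind = "correlation", penalty = "L2",
                  C_grid = c(0.1, 1, 10))
  expect_true(is.finite(cv$stability$mean))
  expect_true(is.na(cv$sparsity$mean))   # dense weights: sparsity not reported
})

test_that("refitting uses the median parameters snapped toward sparsity", {
  ds <- tiny_dataset(n_per_group = 4, effect = 0.6, seed = 7)
  cv <- nested_cv(ds, C_grid = c(1, 10))
  model <- refit_final(ds, cv)
  expect_s3_class(model, "fc_svm")
  expect_true(model$C %in% c(1, 10))
  # median of the per-fold C values, snapped down when off-grid
  medC <- median(cv$folds$C)
  expC <- if (medC %in% c(1, 10)) medC else 1
  expect_equal(model$C, expC)
  expect_true(attr(model, "lambda") %in% c(0.1, 0.01, 0.001))
  expect_equal(length(model$weights), cv$q)
  expect_error(refit_final(ds, list(folds = NULL, settings = cv$settings)),
               "no folds")
})

test_that("fold choices {1, 10} snap the median cost down to 1", {
  # rule check on the documented snapping behaviour
  grid <- c(1, 10)
  medC <- median(c(1, 10))          # 5.5, between grid points
  below <- grid[grid <= medC]
  expect_equal(max(below), 1)
})
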