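test_that("performance reproduces the printed percentages of balanced studies", {
  # 19 + 19 subjects: 13/19 patients and 17/19 controls correct
  p1 <- performance(list(TP = 13, FN = 6, TN = 17, FP = 2))
  expect_equal(round(p1$sensitivity, 2), 68.42)
  expect_equal(round(p1$specificity, 2), 89.47)
  expect_equal(round(p1$accuracy, 2), 78.95)

  # 30 + 30 subjects: 25/30 and 26/30 correct
  p2 <- performance(list(TP = 25, FN = 5, TN = 26, FP = 4))
  expect_equal(round(p2$accuracy, 2), 85.00)
  expect_equal(round(p2$sensitivity, 2), 83.33)
  expect_equal(round(p2$specificity, 2), 86.67)

  p3 <- performance(list(TP = 10, FN = 0, TN = 10, FP = 0))
  expect_equal(unlist(p3), c(accuracy = 100, sensitivity = 100,
                             specificity = 100))

  # zero denominator -> missing, not zero
  p4 <- performance(list(TP = 0, FN = 0, TN = 3, FP = 1))
  expect_true(is.na(p4$sensitivity))
})

test_that("accuracy decomposes into the class-weighted sensitivity/specificity", {
  set.seed(31)
  for (r in 1:20) {
    tp <- sample(0:20, 1); fn <- sample(0:20, 1)
    tn <- sample(0:20, 1); fp <- sample(0:20, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    p <- performance(list(TP = tp, FN = fn, TN = tn, FP = fp))
    n_pat <- tp + fn; n_ctl <- tn + fp
    expect_equal(p$accuracy,
                 (p$sensitivity * n_pat + p$specificity * n_ctl) / (n_pat + n_ctl))
  }
})

test_that("confusion tables count patients as the positive class", {
  truth <- c(1, 1, -1, -1, 1)
  pred  <- c(1, -1, -1, 1, 1)
  conf <- confusion_table(truth, pred)
  expect_equal(conf, list(TP = 2, FP = 1, TN = 1, FN = 1))
})

test_that("permutation p-values respect the 1/n floor", {
  expect_equal(permutation_pvalue(0, 100), 0.01)
  expect_equal(permutation_pvalue(2, 100), 0.02)
  expect_equal(permutation_pvalue(50, 50), 1.0)
  expect_equal(permutation_pvalue(0, 1), 1.0)
  expect_error(permutation_pvalue(5, 0), "at least 1")
  expect_error(permutation_pvalue(7, 5), "n_ge")
  # bounds hold across the grid
  for (n in c(1, 10, 100))
    for (k in 0:n)
      expect_true(permutation_pvalue(k, n) >= 1 / n &&
                    permutation_pvalue(k, n) <= 1)
})

test_that("label shuffling preserves the group balance", {
  m <- data.frame(subject_id = letters[1:10], group = rep(c(1, -1), each = 5))
  set.seed(4)
  for (r in 1:10) {
    ms <- sparseFC:::shuffle_labels(m)
    expect_equal(sum(ms$group == 1), 5)
    expect_equal(sort(ms$subject_id), sort(m$subject_id))
  }
})

test_that("accuracy permutation test flags a strong effect and is replayable", {
  ds <- tiny_dataset(n_per_group = 5, effect = 0.6, seed = 8)
  args <- list(C_grid = c(0.1, 1, 10), lambda_grid = c(0.1, 0.01))
  cv <- do.call(nested_cv, c(list(ds), args))
  pt <- do.call(permutation_test_accuracy,
                c(list(ds, observed = cv, n_perm = 12, seed = 2), args))
  expect_equal(pt$n_perm, 12)
  expect_true(pt$p_value >= 1 / 12 && pt$p_value <= 1)
  expect_equal(pt$observed, cv$metrics$accuracy)
  # exact replay with the same seed
  pt2 <- do.call(permutation_test_accuracy,
                 c(list(ds, observed = cv, n_perm = 12, seed = 2), args))
  expect_identical(pt$null_values, pt2$null_values)
  # strong signal: observed accuracy above most of the null
  expect_gte(mean(pt$observed >= pt$null_values), 0.8)
})

test_that("weight permutation test yields a coherent discriminative network", {
  ds <- tiny_dataset(n_per_group = 5, effect = 0.6, seed = 8)
  args <- list(C_grid = c(0.1, 1, 10), lambda_grid = c(0.1, 0.01))
  cv <- do.call(nested_cv, c(list(ds), args))
  model <- refit_final(ds, cv)
  net <- permutation_test_weights(ds, model, cv, n_perm = 12, seed = 5)
  # edges are exactly the refit support; significant edges are a subset
  expect_equal(nrow(net$edges), length(model$support))
  expect_true(all(net$edges$significant %in% c(TRUE, FALSE)))
  expect_true(all(net$edges$p_value >= 0 & net$edges$p_value <= 1))
  # the conservative floored variant bounds p below by 1/n_perm
  net_f <- permutation_test_weights(ds, model, cv, n_perm = 12, seed = 5,
                                    floor_p = TRUE)
  expect_true(all(net_f$p_values >= 1 / 12))
  expect_true(all(net_f$p_values >= net$p_values))
  expect_true(all(net$edges$p_adjusted >= net$edges$p_value - 1e-12))
  # a zero observed weight can never be significant (p = 1 two-sided)
  zero_idx <- setdiff(seq_along(model$weights), model$support)
  if (length(zero_idx))
    expect_true(all(net$p_values[zero_idx] == 1))
  # BH adjustment matches stats::p.adjust
  expect_equal(unname(net$p_adjusted), unname(p.adjust(net$p_values, "BH")))
})

test_that("node degrees count significant incident edges", {
  net <- structure(list(edges = data.frame(
    region_a = c("A", "A", "A", "B"),
    region_b = c("B", "C", "D", "C"),
    weight = c(1, -1, 2, 1), p_value = c(0.01, 0.01, 0.01, 0.8),
    p_adjusted = c(0.02, 0.02, 0.02, 0.9),
    significant = c(TRUE, TRUE, TRUE, FALSE))),
    class = "discriminative_network")
  deg <- node_degrees(net)
  expect_equal(deg[["A"]], 3L)
  expect_equal(sum(deg), 6L)  # 3 edges x 2 endpoints

  # empty significant set -> empty degree table
  net$edges$significant <- FALSE
  expect_length(node_degrees(net), 0)

  # random edge lists match an incidence-matrix oracle
  set.seed(12)
  for (r in 1:5) {
    n_e <- 15
    ed <- data.frame(region_a = sample(LETTERS[1:8], n_e, TRUE),
                     region_b = sample(letters[1:8], n_e, TRUE),
                     weight = rnorm(n_e), p_value = runif(n_e),
                     p_adjusted = runif(n_e),
                     significant = sample(c(TRUE, FALSE), n_e, TRUE))
    net_r <- structure(list(edges = ed), class = "discriminative_network")
    deg_r <- node_degrees(net_r)
    sig <- ed[ed$significant, ]
    oracle <- table(c(sig$region_a, sig$region_b))
    expect_equal(sum(deg_r), sum(oracle))
    for (nm in names(deg_r)) expect_equal(deg_r[[nm]], unname(oracle[nm]),
                                          ignore_attr = TRUE)
  }
})
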