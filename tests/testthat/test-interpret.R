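test_that("beta importance reports signed weights and guards its preconditions", {
  pb <- linear_problem()
  fit <- fit_elastic_net(pb$X, pb$y, alpha = 1, lambda = 0.01)
  imp <- beta_importance(fit)
  expect_s3_class(imp, "dom_importance")
  expect_equal(imp$feature, colnames(pb$X))
  expect_equal(imp$score, unname(fit$beta))
  # the informative features carry positive weights in a positive-beta design
  expect_true(all(imp$score[1:3] > 0))
  rf <- fit_random_forest(pb$X, pb$y, num_trees = 50, seed = 1)
  expect_error(beta_importance(rf), "elastic-net")
  expect_warning(beta_importance(fit_elastic_net(pb$X, pb$y, 1, 50)),
                 "zero")
})

test_that("permutation importance ranks informative features above noise in almost all runs", {
  hits <- 0L
  null_scores <- c()
  info_scores <- c()
  for (s in 1:20) {
    pb <- linear_problem(n = 80, p = 8, informative = 3, seed = 100 + s,
                         noise_sd = 0.2)
    fit <- fit_random_forest(pb$X, pb$y, num_trees = 200, seed = s)
    imp <- permutation_importance(fit)
    info <- imp$score[imp$feature %in% pb$informative]
    noise <- imp$score[!imp$feature %in% pb$informative]
    if (min(info) > max(noise)) hits <- hits + 1L
    null_scores <- c(null_scores, noise)
    info_scores <- c(info_scores, info)
  }
  expect_gte(hits, 18)
  # noise importances scatter around zero, far below the signal features
  expect_lt(mean(null_scores), mean(info_scores) / 10)
})

test_that("tree SHAP equals brute-force Shapley values on small forests", {
  # 2 features: enumerate all coalitions per tree and compare exactly
  withr::with_seed(31, {
    X <- matrix(runif(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y <- 2 * X[, 1] - X[, 2] + rnorm(30, 0, 0.05)
  })
  fit <- fit_random_forest(X, y, num_trees = 5, min_node_size = 3, seed = 2)
  sv <- shap_values(fit, X)
  nt <- fit$model$num.trees
  expected <- matrix(0, nrow(X), 2)
  for (t in seq_len(nt)) {
    tr <- domfluor:::.rf_tree_structure(fit, t)
    for (i in seq_len(nrow(X))) {
      expected[i, ] <- expected[i, ] + brute_force_shapley(tr, X[i, ], 2) / nt
    }
  }
  expect_equal(unname(sv$shap), expected, tolerance = 1e-10)
})

test_that("tree SHAP attributions are additive and vanish for unused features", {
  withr::with_seed(17, {
    X <- cbind(matrix(runif(90), ncol = 3), constant = 0.5)
    colnames(X)[1:3] <- c("a", "b", "c")
    y <- X[, 1] + 0.5 * X[, 2] + rnorm(30, 0, 0.05)
  })
  fit <- fit_random_forest(X, y, num_trees = 50, min_node_size = 3, seed = 3)
  sv <- shap_values(fit, X)
  pred <- predict(fit, X)
  expect_lt(max(abs(rowSums(sv$shap) + sv$expected_value - pred)), 1e-6)
  # a constant column is never split on, so its attribution is exactly zero
  expect_equal(unname(sv$shap[, "constant"]), rep(0, nrow(X)))
})

test_that("sampling SHAP is additive within Monte Carlo error for linear models", {
  pb <- linear_problem(n = 30, p = 4, seed = 21)
  fit <- fit_elastic_net(pb$X, pb$y, alpha = 0, lambda = 0)
  sv <- shap_values(fit, pb$X[1:5, , drop = FALSE], background = pb$X,
                    nsim = 2000, seed = 5)
  expect_equal(sv$method, "sampling")
  pred <- predict(fit, pb$X[1:5, , drop = FALSE])
  gaps <- abs(rowSums(sv$shap) + sv$expected_value - pred)
  # each sampled ordering telescopes to f(x) - f(background row), so the
  # residual is the Monte Carlo error of the background average
  mc_err <- 4 * sd(predict(fit, pb$X)) / sqrt(2000)
  expect_lt(max(gaps), mc_err)
  # and the attributions match the closed form beta_j * (x_j - mean(bg_j))
  closed <- sweep(pb$X[1:5, , drop = FALSE], 2, colMeans(pb$X)) %*%
    diag(unname(fit$beta))
  expect_lt(max(abs(unname(sv$shap) - unname(closed))), 0.1)
})

test_that("shap_values is deterministic under a seed and rejects mismatched features", {
  pb <- linear_problem(n = 20, p = 3, seed = 8)
  fit <- fit_elastic_net(pb$X, pb$y, alpha = 0, lambda = 0)
  s1 <- shap_values(fit, pb$X, nsim = 20, seed = 9)
  s2 <- shap_values(fit, pb$X, nsim = 20, seed = 9)
  expect_equal(s1$shap, s2$shap)
  bad <- pb$X[, 1:2, drop = FALSE]
  expect_error(shap_values(fit, bad), "mismatch")
})

test_that("Jaccard similarity matches set arithmetic on marker sets", {
  # two marker lists of 3546 and 1450 formulas sharing 759
  a <- paste0("f", seq_len(3546))
  b <- c(a[seq_len(759)], paste0("g", seq_len(1450 - 759)))
  expect_equal(jaccard(a, b), 759 / 4237)
  expect_equal(round(jaccard(a, b), 2), 0.18)
  expect_equal(jaccard(a, b), jaccard(b, a))
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, paste0("z", 1:5)), 0)
  expect_gte(jaccard(letters[1:4], letters[3:8]), 0)
  expect_message(jaccard(character(0), character(0)), "empty")
})

test_that("top-k unions grow with k, collapse for identical reports, and clamp oversized k", {
  r1 <- domfluor:::.new_importance(paste0("f", 1:6),
                                   c(6, 5, 4, 3, 2, 1), "permutation")
  r2 <- domfluor:::.new_importance(paste0("g", 1:6),
                                   c(6, 5, 4, 3, 2, 1), "permutation")
  expect_equal(top_k_union(list(r1, r1), k = 3), paste0("f", 1:3))
  expect_equal(top_k_union(list(r1, r2), k = 2),
               sort(c("f1", "f2", "g1", "g2")))
  u2 <- top_k_union(list(r1, r2), k = 2)
  u4 <- top_k_union(list(r1, r2), k = 4)
  expect_true(all(u2 %in% u4))
  expect_warning(u <- top_k_union(r1, k = 50), "clamping")
  expect_equal(u, paste0("f", 1:6))
  # zero-scored features never enter the union
  r3 <- domfluor:::.new_importance(c("f1", "dead"), c(1, 0), "beta")
  expect_warning(expect_equal(top_k_union(r3, k = 5), "f1"))
})

test_that("SHAP-weighted composition averages only terrestrial-leaning formulas", {
  # single positive feature: the composition is that formula exactly
  one <- shap_composition(c(C6H12O6 = 0.4, C10H16O8 = -0.2))
  expect_equal(one$C, 6)
  expect_equal(one$H, 12)
  expect_equal(one$n_features, 1)
  # equal positive values degenerate min-max scaling into a plain average
  eq <- shap_composition(c(C6H12O6 = 0.3, C2H6O = 0.3))
  expect_equal(eq$C, 4)
  expect_equal(eq$O, 3.5)
  # hand example: min-max weights (1, 0) keep only the larger contributor
  hand <- shap_composition(c(C6H12O6 = 0.5, C2H6O = 0.25, C10H16O8 = -0.1))
  expect_equal(hand$C, 6)
  expect_equal(hand$O, 6)
  # ratios recompute from the weighted counts
  mix <- shap_composition(c(`C18H21NO9S@12.3` = 0.5, C6H12O6 = 0.1))
  expect_equal(mix$NC, mix$N / mix$C)
  expect_equal(mix$SC, mix$S / mix$C)
  # weighted means stay inside the convex hull of the contributing formulas
  expect_true(mix$C >= 6 && mix$C <= 18)
  expect_error(shap_composition(c(C6H12O6 = -1)), "positive")
  expect_error(shap_composition(c(0.5)), "named")
})

test_that("recursive elimination shrinks the feature set and degrades below the informative count", {
  pb <- linear_problem(n = 80, p = 20, informative = 3, seed = 41,
                       noise_sd = 0.15)
  rfe <- recursive_feature_elimination(pb$X, pb$y, num_trees = 150, k = 5,
                                       seed = 6)
  expect_s3_class(rfe, "dom_rfe")
  expect_true(all(diff(rfe$n_features) < 0))
  expect_equal(rfe$n_features[1], 20)
  expect_equal(dplyr::last(rfe$n_features), 1)
  # drop size is a tenth of the remaining features, at least one
  expect_equal(rfe$n_features[2], 20 - max(1, floor(0.1 * 20)))
  # pruning pure-noise features costs little: the best pruned error is
  # close to (or better than) the full-feature error
  full_err <- rfe$cv_nrmse[1]
  best_err <- min(rfe$cv_nrmse)
  expect_lt(best_err, full_err + 1)
  # once the set falls below the three informative features, error rises
  small <- rfe$cv_nrmse[rfe$n_features < 3]
  at_or_above <- rfe$cv_nrmse[rfe$n_features >= 3]
  expect_gt(min(small), min(at_or_above))
  expect_gt(dplyr::last(rfe$cv_nrmse), 1.5 * min(at_or_above))
})
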