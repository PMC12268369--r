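test_that("normalized RMSE is the error as a percentage of the target range", {
  # a 0.3-unit RMSE over a standardized target spanning -27.7 to -21.9
  expect_equal(nrmse(0.3, c(-27.7, -21.9)), 100 * 0.3 / 5.8)
  expect_equal(nrmse(0, c(0, 10)), 0)
  # range is taken over the supplied values, not their order
  expect_equal(nrmse(1, c(5, -5, 0)), 10)
  expect_error(nrmse(1, c(2, 2)), "zero range")
})

test_that("the standard error of the mean matches its definition and decays as 1/sqrt(n)", {
  expect_equal(sem(c(0, 2)), 1)  # sd sqrt(2), n 2
  expect_equal(sem(rep(1, 4)), 0)
  withr::with_seed(2, x <- rnorm(400))
  expect_equal(sem(x), sd(x) / 20)
  expect_lt(sem(x), sem(x[1:100]))
})

test_that("the paired Wilcoxon test agrees with exact sign-assignment enumeration", {
  # six concordant paired differences: smallest achievable two-sided level
  a <- c(5.1, 6.2, 4.8, 5.9, 6.4, 5.3)
  b <- a - c(0.4, 0.3, 0.5, 0.2, 0.6, 0.3)
  p_impl <- wilcoxon_compare(a, b, paired = TRUE)
  p_exact <- exact_signed_rank_p(a - b)
  expect_equal(p_exact, 2 * (1 / 2)^6)
  expect_lt(abs(p_impl - p_exact), 0.015)
  expect_equal(p_impl < 0.05, p_exact < 0.05)
})

test_that("rank-based comparison is insensitive to monotone transforms and to identical groups", {
  withr::with_seed(5, {
    a <- runif(12, 1, 2)
    b <- runif(12, 1.2, 2.2)
  })
  p1 <- wilcoxon_compare(a, b)
  p2 <- wilcoxon_compare(exp(a), exp(b))
  expect_equal(p1, p2)
  expect_gt(wilcoxon_compare(a, a), 0.99)
  expect_error(wilcoxon_compare(a, a, paired = TRUE), "zero")
})

test_that("the unpenalized elastic net reproduces zero-intercept least squares", {
  for (s in 1:10) {
    withr::with_seed(s, {
      X <- matrix(rnorm(5 * 3), nrow = 5,
                  dimnames = list(NULL, c("a", "b", "c")))
      y <- rnorm(5)
    })
    ols <- qr.solve(X, y)
    for (al in c(0, 0.5, 1)) {
      fit <- fit_elastic_net(X, y, alpha = al, lambda = 0)
      expect_lt(max(abs(unname(fit$beta) - unname(ols))), 1e-6)
    }
    expect_equal(fit_elastic_net(X, y, 1, 0)$intercept, 0)
  }
})

test_that("the lasso collapses duplicated features onto a single coefficient", {
  pb <- linear_problem(seed = 3)
  X <- cbind(pb$X, dup = pb$X[, 1])
  fit <- fit_elastic_net(X, pb$y, alpha = 1, lambda = 0.05)
  pair <- fit$beta[c("f01", "dup")]
  expect_lt(min(abs(pair)), 1e-6)
  expect_gt(max(abs(pair)), 0.1)
  # heavy regularization shrinks everything to exactly zero
  strong <- fit_elastic_net(X, pb$y, alpha = 1, lambda = 50)
  expect_equal(unname(strong$beta), rep(0, ncol(X)))
})

test_that("linear signals are recovered nearly perfectly by the linear families", {
  pb <- linear_problem()
  glm_fit <- fit_elastic_net(pb$X, pb$y, alpha = 0.5, lambda = 0)
  glm_nrmse <- nrmse(sqrt(mean((pb$y - predict(glm_fit, pb$X))^2)), pb$y)
  expect_lt(glm_nrmse, 1)
  svr_fit <- fit_svr(pb$X, pb$y, kernel = "poly", cost = 1, degree = 1,
                     epsilon = 0.01)
  svr_nrmse <- nrmse(sqrt(mean((pb$y - predict(svr_fit, pb$X))^2)), pb$y)
  expect_lt(svr_nrmse, 1)
})

test_that("a vanishing RBF bandwidth degenerates to a near-constant predictor", {
  pb <- linear_problem()
  fit <- fit_svr(pb$X, pb$y, kernel = "rbf", cost = 1, sigma = 1e-6)
  pred <- predict(fit, pb$X)
  expect_lt(sd(pred) / sd(pb$y), 0.01)
})

test_that("random forests are seed-deterministic and out-of-bag error tracks held-out error", {
  pb <- linear_problem(n = 120, noise_sd = 0.1, seed = 6)
  tr <- 1:90; te <- 91:120
  f1 <- fit_random_forest(pb$X[tr, ], pb$y[tr], num_trees = 300, seed = 7)
  f2 <- fit_random_forest(pb$X[tr, ], pb$y[tr], num_trees = 300, seed = 7)
  expect_equal(predict(f1, pb$X[te, ]), predict(f2, pb$X[te, ]))
  oob_rmse <- sqrt(mean((pb$y[tr] - f1$oob_predictions)^2))
  test_rmse <- sqrt(mean((pb$y[te] - predict(f1, pb$X[te, ]))^2))
  expect_lt(abs(oob_rmse - test_rmse) / test_rmse, 0.3)
})

test_that("the stratified split yields 76 train and 19 test samples from 95 and balances the target", {
  withr::with_seed(11, y <- runif(95, 0.00927, 0.0624))
  sp <- stratified_split(y, seed = 1)
  expect_length(sp$train, 76)
  expect_length(sp$test, 19)
  expect_setequal(c(sp$train, sp$test), 1:95)
  expect_identical(sp, stratified_split(y, seed = 1))
  expect_false(identical(sp, stratified_split(y, seed = 2)))
  # the split balances the target distribution across many seeds
  imbalance <- sapply(1:20, function(s) {
    spl <- stratified_split(y, seed = s)
    abs(mean(y[spl$train]) - mean(y[spl$test])) / sd(y)
  })
  expect_lt(max(imbalance), 0.5)
  expect_lt(median(imbalance), 0.25)
  expect_warning(stratified_split(runif(6), n_bins = 10), "random split")
  expect_error(stratified_split(runif(3)), "at least five")
})

test_that("the default grids match the benchmark design", {
  g <- model_grid("glm")
  expect_equal(nrow(g), 21 * 41)
  expect_equal(range(g$alpha), c(0, 1))
  expect_equal(range(g$lambda), c(0, 2))
  rf <- model_grid("rf", p = 120)
  expect_equal(unique(rf$num_trees), 1000)
  expect_equal(sort(unique(rf$mtry)), ceiling(120 * (1:6) / 6))
  expect_setequal(unique(rf$min_node_size), c(3, 5, 7, 10, 15))
  sp <- model_grid("svr_poly")
  expect_equal(nrow(sp), 6 * 5)
  expect_setequal(unique(sp$degree), 1:5)
  expect_equal(unique(sp$scale), 1)
  sr <- model_grid("svr_rbf")
  expect_equal(nrow(sr), 9 * 12)
  expect_equal(sort(unique(sr$sigma)),
               c(1e-6, 2.5e-6, 6.25e-6, 1e-5, 2e-5, 5e-5, 2.5e-4, 5e-4,
                 1e-3, 1e-2, 1e-1, 1))
  expect_error(model_grid("rf"), "`p`")
})

test_that("grid search picks an unregularized model for a noise-free linear signal", {
  pb <- linear_problem()
  grid <- tidyr::expand_grid(alpha = c(0.5, 1), lambda = c(0, 0.5, 2))
  fit <- grid_search_cv(pb$X, pb$y, family = "glm", grid = grid,
                        k = 5, repeats = 2, seed = 3)
  expect_equal(fit$best$lambda, 0)
  expect_equal(nrow(fit$cv_results), nrow(grid))
  expect_true(all(is.finite(fit$cv_results$mean_rmse)))
  # refit model predicts the held-out-free training data almost exactly
  expect_lt(nrmse(sqrt(mean((pb$y - predict(fit, pb$X))^2)), pb$y), 1)
  # deterministic under the seed
  fit2 <- grid_search_cv(pb$X, pb$y, family = "glm", grid = grid,
                         k = 5, repeats = 2, seed = 3)
  expect_equal(fit$cv_results, fit2$cv_results)
})

test_that("exact cross-validation ties break toward the stronger regularization", {
  pb <- linear_problem(seed = 9)
  # both lambdas zero out every coefficient, so their CV scores tie exactly
  grid <- tibble::tibble(alpha = 1, lambda = c(5, 10))
  fit <- grid_search_cv(pb$X, pb$y, family = "glm", grid = grid,
                        k = 4, repeats = 1, seed = 2)
  expect_equal(fit$best$lambda, 10)
  expect_equal(unname(fit$model$beta), rep(0, ncol(pb$X)))
})

test_that("test metrics are reported on the original fluorescence scale", {
  withr::with_seed(13, x <- runif(40, 0.01, 0.06))
  sc <- zscore_target(x)
  pb <- linear_problem(n = 40, seed = 13)
  fit <- fit_elastic_net(pb$X, sc$values, alpha = 0, lambda = 0.01)
  m <- evaluate_fit(fit, pb$X, sc$values, scaler = sc)
  rmse_z <- sqrt(mean((sc$values - predict(fit, pb$X))^2))
  expect_equal(m$rmse, rmse_z)
  expect_equal(m$nrmse, 100 * rmse_z * sc$sd / diff(range(x)))
  # an exact predictor scores zero error and unit R-squared
  perfect <- structure(list(), class = "dom_oracle")
  assign("predict.dom_oracle", function(object, newdata, ...) sc$values,
         envir = globalenv())
  on.exit(rm("predict.dom_oracle", envir = globalenv()), add = TRUE)
  mp <- evaluate_fit(perfect, pb$X, sc$values, scaler = sc)
  expect_equal(mp$rmse, 0)
  expect_equal(mp$r2, 1)
})

test_that("the benchmark produces one scored cell per combination and family", {
  sim <- small_sim()
  specs <- preprocess_specs()[c(5, 21), ]  # one per table format
  grids <- list(
    glm = tidyr::expand_grid(alpha = 1, lambda = c(0.01, 0.1)),
    svr_poly = tidyr::expand_grid(cost = 1, degree = 1:2, scale = 1)
  )
  bench <- run_benchmark(sim$long, sim$samples, specs = specs,
                         families = c("glm", "svr_poly"), seed = 4,
                         k = 3, repeats = 1, grids = grids)
  expect_equal(nrow(bench), 4)
  expect_true(all(is.na(bench$error)))
  expect_true(all(is.finite(bench$nrmse)))
  expect_setequal(bench$family, c("glm", "svr_poly"))
  split <- attr(bench, "split")
  expect_length(split$train, floor(0.8 * nrow(sim$samples)))
  # a trained model must beat the constant mean predictor on average
  expect_gt(max(bench$r2), 0)
})
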