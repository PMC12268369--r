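# Train/test split, grid search with repeated stratified CV, benchmark grid.

#' Stratified train/test split on the target
#'
#' Splits samples into a training and test set whose target distributions
#' are similar: samples are binned by target quantiles and each bin
#' contributes proportionally to both sets (largest-remainder allocation;
#' the training set receives `floor(train_fraction * n)` samples, e.g.
#' 95 samples -> 76 train / 19 test).
#'
#' @param target Per-sample target values.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param n_bins Number of quantile bins (default 5). With fewer samples
#'   than bins, a plain random split is used with a warning.
#' @param seed Integer seed.
#' @return A list with sorted integer index vectors `train` and `test`.
#' @export
stratified_split <- function(target, train_fraction = 0.8, n_bins = 5,
                             seed = 1L) {
  n <- length(target)
  if (n < 5) abort("Need at least five samples to split.")
  n_train <- floor(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    abort("`train_fraction` leaves an empty training or test set.")
  }
  withr::with_seed(seed, {
    if (n < n_bins) {
      warn("Fewer samples than strata; falling back to a random split.")
      train <- sort(sample.int(n, n_train))
      return(list(train = train, test = setdiff(seq_len(n), train)))
    }
    breaks <- unique(quantile(target, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- cut(target, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    sizes <- tabulate(bins, nbins = max(bins))
    quota <- n_train * sizes / n
    base <- floor(quota)
    rem <- n_train - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    train <- integer(0)
    for (b in seq_along(sizes)) {
      idx <- which(bins == b)
      take <- min(base[b], length(idx))
      if (take > 0) train <- c(train, sample(idx, take))
    }
    # top up if some bin was too small for its quota
    short <- n_train - length(train)
    if (short > 0) {
      pool <- setdiff(seq_len(n), train)
      train <- c(train, sample(pool, short))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

# Stratified k-fold assignment: rank the target, then shuffle fold labels
# within consecutive rank groups of size k so each fold spans the target
# range.
.stratified_folds <- function(y, k) {
  n <- length(y)
  k <- min(k, n)
  ord <- order(y, sample.int(n))  # random tie-break
  folds <- integer(n)
  fold_seq <- rep(seq_len(k), length.out = n)
  for (start in seq(1, n, by = k)) {
    idx <- ord[start:min(start + k - 1, n)]
    folds[idx] <- sample(fold_seq[seq_along(idx)])
  }
  folds
}

#' Grid search with repeated stratified cross-validation
#'
#' Evaluates every row of a hyperparameter grid by k-fold cross-validation
#' repeated `repeats` times (folds re-randomized per repeat, stratified by
#' target quantile), scores grid points by their mean validation RMSE, and
#' refits the best point on the full training data. Exact score ties are
#' broken toward the more strongly regularized candidate (larger lambda,
#' smaller polynomial degree, smaller mtry / larger node size, smaller
#' cost/sigma).
#'
#' @param X Training feature matrix or `dom_features` table (training
#'   samples only; the test set must not enter here).
#' @param y Training target.
#' @param family One of `"glm"`, `"rf"`, `"svr_poly"`, `"svr_rbf"`.
#' @param grid Hyperparameter grid (default [model_grid()] for the
#'   family).
#' @param k Folds (default 10).
#' @param repeats CV repeats (default 10).
#' @param seed Integer seed controlling fold assignment and forests.
#' @param epsilon SVR tube half-width (default 0.1).
#' @return An object of class `"dom_fit"`: the refitted `$model`, the
#'   chosen `$best` grid row, and `$cv_results` (grid with `mean_rmse`,
#'   `sd_rmse`, `n_folds`).
#' @export
grid_search_cv <- function(X, y, family = .families, grid = NULL, k = 10,
                           repeats = 10, seed = 1L, epsilon = 0.1) {
  family <- match.arg(family)
  X <- .as_X(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (sd(y) == 0) abort("Cross-validation target is constant.")
  if (is.null(grid)) grid <- model_grid(family, p = ncol(X))
  if (nrow(grid) == 0) abort("Empty hyperparameter grid.")

  err_sum <- numeric(nrow(grid))
  err_sq <- numeric(nrow(grid))
  n_folds_used <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      folds <- .stratified_folds(y, k)
      for (f in sort(unique(folds))) {
        hold <- folds == f
        if (sum(hold) == 0 || sum(!hold) < 2 || sd(y[!hold]) == 0) next
        rmse_f <- .cv_fold_rmse(family, grid, X[!hold, , drop = FALSE],
                                y[!hold], X[hold, , drop = FALSE], y[hold],
                                seed = seed + r, epsilon = epsilon)
        err_sum <- err_sum + rmse_f
        err_sq <- err_sq + rmse_f^2
        n_folds_used <- n_folds_used + 1L
      }
    }
  })
  if (n_folds_used == 0L) abort("Cross-validation produced no usable folds.")
  mean_rmse <- err_sum / n_folds_used
  sd_rmse <- sqrt(pmax(err_sq / n_folds_used - mean_rmse^2, 0))

  pref <- .tie_break_order(grid, family)
  best_score <- min(mean_rmse)
  tied <- which(mean_rmse <= best_score + 1e-12)
  best_idx <- pref[pref %in% tied][1]
  best <- grid[best_idx, , drop = FALSE]

  model <- .fit_family(family, X, y, as.list(best), seed = seed,
                       epsilon = epsilon)
  structure(
    list(
      family = family,
      best = best,
      cv_results = dplyr::mutate(grid, mean_rmse = mean_rmse,
                                 sd_rmse = sd_rmse, n_folds = n_folds_used),
      model = model,
      features = colnames(X),
      seed = seed
    ),
    class = "dom_fit"
  )
}

# Validation RMSE of every grid row for one fold. The elastic net is
# evaluated path-wise (one glmnet fit per alpha covering all lambdas).
.cv_fold_rmse <- function(family, grid, X_tr, y_tr, X_va, y_va, seed,
                          epsilon) {
  out <- numeric(nrow(grid))
  if (family == "glm") {
    lambdas <- sort(unique(grid$lambda), decreasing = TRUE)
    for (a in unique(grid$alpha)) {
      fit <- glmnet::glmnet(X_tr, y_tr, alpha = a, lambda = lambdas,
                            intercept = FALSE, standardize = FALSE,
                            thresh = 1e-9, maxit = 1e7)
      pred <- predict(fit, newx = X_va, s = lambdas, exact = FALSE)
      rmse_l <- sqrt(colMeans((y_va - pred)^2))
      rows <- which(grid$alpha == a)
      out[rows] <- rmse_l[match(grid$lambda[rows], lambdas)]
    }
  } else {
    for (i in seq_len(nrow(grid))) {
      model <- .fit_family(family, X_tr, y_tr, as.list(grid[i, ]),
                           seed = seed, epsilon = epsilon)
      pred <- predict(model, X_va)
      out[i] <- sqrt(mean((y_va - pred)^2))
    }
  }
  out
}

#' @export
predict.dom_fit <- function(object, newdata, ...) {
  predict(object$model, newdata)
}

#' @export
print.dom_fit <- function(x, ...) {
  cat(sprintf("<dom_fit> family=%s, best: %s\n", x$family,
              paste(names(x$best), unlist(x$best), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Test-set metrics for a fitted model
#'
#' Computes RMSE, NRMSE, R-squared and MAE on held-out data. When a target
#' scaler from [zscore_target()] is supplied (the usual case: models are
#' trained on the standardized target), the RMSE is mapped back to the
#' original fluorescence scale and the NRMSE uses the full dataset's
#' original target range.
#'
#' @param fit A `"dom_fit"` (or any model with a `predict` method).
#' @param X_test,y_test Held-out features and target (target on the model's
#'   training scale).
#' @param scaler Optional `"dom_scaler"`; without it, NRMSE uses the range
#'   of `y_test`.
#' @return One-row tibble: `rmse`, `nrmse`, `r2`, `mae` (rmse and mae on
#'   the model's target scale, `nrmse` in percent of the original range).
#' @export
evaluate_fit <- function(fit, X_test, y_test, scaler = NULL) {
  pred <- predict(fit, X_test)
  rmse <- sqrt(mean((y_test - pred)^2))
  mae <- mean(abs(y_test - pred))
  r2 <- 1 - sum((y_test - pred)^2) / sum((y_test - mean(y_test))^2)
  nr <- if (!is.null(scaler)) {
    nrmse(rmse * scaler$sd, scaler$range)
  } else {
    nrmse(rmse, y_test)
  }
  tibble::tibble(rmse = rmse, nrmse = nr, r2 = r2, mae = mae)
}

#' Benchmark model families over preprocessing combinations
#'
#' Runs the full comparison: standardize the target over all samples,
#' make one stratified train/test split, and for every requested
#' preprocessing combination build + filter + normalize the feature table,
#' grid-search each model family on the training samples and score it on
#' the held-out test samples. Failures in single cells are recorded, not
#' fatal.
#'
#' @param long Long table of intensities.
#' @param samples Per-sample metadata (`sample_id`, `c475`, `doc`).
#' @param specs Preprocessing combinations (default all 32 from
#'   [preprocess_specs()]).
#' @param families Model families to run (default all four).
#' @param seed Master seed (split, folds, forests).
#' @param k,repeats Cross-validation folds and repeats.
#' @param grids Optional named list of grid overrides per family (for
#'   reduced-size runs).
#' @param train_fraction Training fraction for the split.
#' @param epsilon SVR tube half-width.
#' @return A tibble of class `"dom_benchmark"`: one row per
#'   (combination, family) cell with the test metrics, the chosen
#'   hyperparameters (`best`, list-column) and an `error` column (NA on
#'   success). The target scaler and seed ride along as attributes.
#' @export
run_benchmark <- function(long, samples,
                          specs = preprocess_specs(),
                          families = .families,
                          seed = 1L, k = 10, repeats = 10,
                          grids = NULL, train_fraction = 0.8,
                          epsilon = 0.1) {
  families <- match.arg(families, .families, several.ok = TRUE)
  scaler <- zscore_target(samples$c475)
  y <- scaler$values
  split <- stratified_split(samples$c475, train_fraction = train_fraction,
                            seed = seed)
  cells <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    ft <- tryCatch(apply_preprocess(long, spec, samples),
                   error = function(e) e)
    for (fam in families) {
      row <- tibble::as_tibble(spec)
      row$family <- fam
      if (inherits(ft, "error")) {
        row$rmse <- NA_real_; row$nrmse <- NA_real_
        row$r2 <- NA_real_; row$mae <- NA_real_
        row$best <- list(NULL)
        row$error <- conditionMessage(ft)
      } else {
        res <- tryCatch({
          m <- ft_matrix(ft)
          m <- m[samples$sample_id, , drop = FALSE]
          fit <- grid_search_cv(
            m[split$train, , drop = FALSE], y[split$train],
            family = fam, grid = grids[[fam]], k = k, repeats = repeats,
            seed = seed, epsilon = epsilon
          )
          metrics <- evaluate_fit(fit, m[split$test, , drop = FALSE],
                                  y[split$test], scaler = scaler)
          list(metrics = metrics, best = fit$best)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          row$rmse <- NA_real_; row$nrmse <- NA_real_
          row$r2 <- NA_real_; row$mae <- NA_real_
          row$best <- list(NULL)
          row$error <- conditionMessage(res)
        } else {
          row <- dplyr::bind_cols(row, res$metrics)
          row$best <- list(res$best)
          row$error <- NA_character_
        }
      }
      cells[[length(cells) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(cells)
  structure(out, scaler = scaler, seed = seed, split = split,
            class = c("dom_benchmark", class(out)))
}
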