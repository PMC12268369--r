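# Feature importance, top-k stability, SHAP-weighted composition, and
# recursive feature elimination.

.new_importance <- function(feature, score, method) {
  structure(
    tibble::tibble(feature = feature, score = score, method = method),
    class = c("dom_importance", class(tibble::tibble()))
  )
}

#' Beta-weight importance of a zero-intercept elastic net
#'
#' For a linear model with the intercept fixed at zero, the fitted beta
#' weights both rank features and point them: on a standardized target, a
#' positive weight marks a terrestrial-leaning feature and a negative
#' weight a marine-leaning one. Features with exactly zero weight are
#' reported but excluded from top-k rankings.
#'
#' @param fit A `"dom_glm"` or a `"dom_fit"` wrapping one.
#' @return A `dom_importance` tibble (`feature`, `score`, `method =
#'   "beta"`).
#' @export
beta_importance <- function(fit) {
  model <- if (inherits(fit, "dom_fit")) fit$model else fit
  if (!inherits(model, "dom_glm")) {
    abort("Beta importance is defined for elastic-net fits only.")
  }
  if (!isTRUE(model$intercept == 0)) {
    abort("Beta importance requires a zero-intercept model.")
  }
  if (all(model$beta == 0)) {
    warn("All beta weights are zero (regularization too strong); ranking is empty.")
  }
  .new_importance(names(model$beta), unname(model$beta), "beta")
}

#' Out-of-bag permutation importance of a random forest
#'
#' The increase in out-of-bag prediction error when a feature's values are
#' shuffled among the out-of-bag samples, averaged over trees (computed by
#' ranger during fitting and seeded through the forest's seed).
#'
#' @param fit A `"dom_rf"` or a `"dom_fit"` wrapping one.
#' @return A `dom_importance` tibble (`method = "permutation"`).
#' @export
permutation_importance <- function(fit) {
  model <- if (inherits(fit, "dom_fit")) fit$model else fit
  if (!inherits(model, "dom_rf")) {
    abort("Permutation importance is defined for random-forest fits only.")
  }
  imp <- ranger::importance(model$model)
  .new_importance(unname(model$key_map[names(imp)]), unname(imp),
                  "permutation")
}

#' Mean-absolute-SHAP importance
#'
#' Summarizes a per-sample SHAP matrix into one score per feature (the
#' mean absolute SHAP value across samples), the ranking statistic used
#' for top-k feature sets.
#'
#' @param shap A `"dom_shap"` from [shap_values()].
#' @return A `dom_importance` tibble (`method = "shap_mean_abs"`).
#' @export
shap_importance <- function(shap) {
  stopifnot(inherits(shap, "dom_shap"))
  .new_importance(colnames(shap$shap), colMeans(abs(shap$shap)),
                  "shap_mean_abs")
}

# Descending ranking of an importance report; beta weights rank by
# magnitude, zero scores are excluded.
.rank_features <- function(report, k) {
  mag <- if (report$method[1] == "beta") abs(report$score) else report$score
  keep <- mag != 0
  feats <- report$feature[keep]
  mag <- mag[keep]
  ord <- order(-mag, feats)
  feats[ord][seq_len(min(k, length(feats)))]
}

#' Union of top-k features across importance reports
#'
#' Takes the k highest-scoring features from each report (magnitude for
#' beta weights; ties broken by feature key) and returns the set of all
#' distinct features, the stability construction used to ask how much
#' repeated forests agree on what matters.
#'
#' @param reports A `dom_importance` tibble or list of them.
#' @param k Features to take from each report (default 100; clamped with a
#'   warning if a report has fewer ranked features).
#' @return Character vector (a set) of feature keys.
#' @export
top_k_union <- function(reports, k = 100) {
  if (inherits(reports, "dom_importance")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  sets <- lapply(reports, function(r) {
    n_ranked <- sum(abs(r$score) != 0)
    if (k > n_ranked) {
      warn(sprintf("k = %d exceeds the %d ranked features; clamping.", k, n_ranked))
    }
    .rank_features(r, k)
  })
  sort(unique(unlist(sets)))
}

#' SHAP-weighted average elemental composition
#'
#' Characterizes the terrestrial-leaning side of one sample's SHAP
#' decomposition: the strictly positive SHAP values are min-max scaled to
#' `[0, 1]` and used as weights for an average CHNOS composition of the
#' contributing formulas; negative-SHAP (marine-leaning) features are
#' excluded. N/C and S/C ratios are recomputed from the weighted counts.
#'
#' @param shap_row Named numeric vector: one sample's SHAP value per
#'   feature (feature keys are formula labels, optionally with an
#'   `@segment` suffix for time-aware features).
#' @param scaling `"minmax"` (default): scale positive values to
#'   `[0, 1]` by `(s - min) / (max - min)`; `"max"`: divide by the
#'   maximum.
#' @return One-row tibble of class `"dom_composition"`: weighted mean
#'   `C`, `H`, `N`, `O`, `S` counts, `NC` and `SC` ratios, `n_features`
#'   (number of positive-SHAP features) and `scaling`.
#' @export
shap_composition <- function(shap_row, scaling = c("minmax", "max")) {
  scaling <- match.arg(scaling)
  if (is.null(names(shap_row))) {
    abort("`shap_row` must be named by feature key.")
  }
  pos <- shap_row[shap_row > 0]
  if (length(pos) == 0) {
    abort("No strictly positive SHAP values; terrestrial composition undefined.")
  }
  w <- if (scaling == "minmax") {
    rng <- range(pos)
    if (diff(rng) == 0) rep(1, length(pos)) else (pos - rng[1]) / diff(rng)
  } else {
    pos / max(pos)
  }
  labels <- sub("@.*$", "", names(pos))
  counts <- parse_formula(labels)
  if (sum(w) == 0) {
    # min-max scaling of a single tie group can zero out all weights
    w <- rep(1, length(w))
  }
  wm <- vapply(c("C", "H", "N", "O", "S"),
               function(el) sum(w * counts[[el]]) / sum(w), numeric(1))
  structure(
    tibble::tibble(
      C = wm[["C"]], H = wm[["H"]], N = wm[["N"]], O = wm[["O"]], S = wm[["S"]],
      NC = wm[["N"]] / wm[["C"]], SC = wm[["S"]] / wm[["C"]],
      n_features = length(pos), scaling = scaling
    ),
    class = c("dom_composition", class(tibble::tibble()))
  )
}

#' Recursive feature elimination with a random forest
#'
#' Iteratively fits a random forest, ranks features by out-of-bag
#' permutation importance, removes the least important 10% (at least one)
#' and records the k-fold cross-validated NRMSE of the current feature
#' set, until a single feature remains. Hyperparameters are held fixed
#' across iterations, with `mtry` re-derived as a fixed fraction of the
#' shrinking feature count; the reported error comes from the omitted CV
#' folds, not from a separate test set.
#'
#' @param X Feature matrix or `dom_features` table.
#' @param y Target (typically the standardized fluorescence proxy).
#' @param num_trees Trees per forest (default 500).
#' @param mtry_fraction Fraction of current features tried per split
#'   (default 1/3).
#' @param min_node_size Minimal node size (default 5).
#' @param step_fraction Fraction of remaining features removed per
#'   iteration (default 0.1).
#' @param k Cross-validation folds per step (default 10).
#' @param seed Integer seed (forests, folds).
#' @param scaler Optional `"dom_scaler"`; with it, NRMSE is expressed in
#'   percent of the original target range, otherwise of the range of `y`.
#' @return A tibble of class `"dom_rfe"`: one row per step with
#'   `n_features`, `cv_rmse`, `cv_nrmse` and the list-column `features`.
#' @export
recursive_feature_elimination <- function(X, y, num_trees = 500,
                                          mtry_fraction = 1 / 3,
                                          min_node_size = 5,
                                          step_fraction = 0.1, k = 10,
                                          seed = 1L, scaler = NULL) {
  X <- .as_X(X)
  if (ncol(X) < 2) abort("Recursive feature elimination needs at least two features.")
  target_range <- if (!is.null(scaler)) scaler$range else range(y)
  sd_scale <- if (!is.null(scaler)) scaler$sd else 1

  current <- colnames(X)
  rows <- list()
  step <- 0L
  withr::with_seed(seed, {
    repeat {
      step <- step + 1L
      Xc <- X[, current, drop = FALSE]
      mtry <- max(1L, ceiling(mtry_fraction * ncol(Xc)))
      # cross-validated error of the current feature set
      folds <- .stratified_folds(y, k)
      sq_err <- 0
      n_pred <- 0L
      for (f in sort(unique(folds))) {
        hold <- folds == f
        fit_f <- fit_random_forest(Xc[!hold, , drop = FALSE], y[!hold],
                                   num_trees = num_trees,
                                   mtry = min(mtry, ncol(Xc)),
                                   min_node_size = min_node_size,
                                   seed = seed + step)
        pred <- predict(fit_f, Xc[hold, , drop = FALSE])
        sq_err <- sq_err + sum((y[hold] - pred)^2)
        n_pred <- n_pred + sum(hold)
      }
      cv_rmse <- sqrt(sq_err / n_pred)
      rows[[step]] <- tibble::tibble(
        step = step, n_features = ncol(Xc), cv_rmse = cv_rmse,
        cv_nrmse = nrmse(cv_rmse * sd_scale, target_range),
        features = list(current)
      )
      if (ncol(Xc) == 1) break
      fit_all <- fit_random_forest(Xc, y, num_trees = num_trees,
                                   mtry = min(mtry, ncol(Xc)),
                                   min_node_size = min_node_size,
                                   seed = seed + step)
      imp <- permutation_importance(fit_all)
      n_drop <- max(1L, floor(step_fraction * ncol(Xc)))
      ord <- order(imp$score, imp$feature)  # least important first
      drop <- imp$feature[ord][seq_len(n_drop)]
      current <- setdiff(current, drop)
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("dom_rfe", class(out)))
}
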