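# broom-style tidiers for fitted objects.

#' Tidy a fitted model
#'
#' Returns the per-feature view of a `"dom_fit"`: beta weights for the
#' elastic net, out-of-bag permutation importance for random forests, and
#' the feature list (scores `NA`) for support vector regressions, whose
#' attribution is obtained via [shap_values()] instead.
#'
#' @param x A `"dom_fit"`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `score`, `method`.
#' @export
tidy.dom_fit <- function(x, ...) {
  switch(x$family,
    glm = tibble::as_tibble(beta_importance(x)),
    rf = tibble::as_tibble(permutation_importance(x)),
    tibble::tibble(feature = x$features, score = NA_real_,
                   method = "none")
  )
}

#' One-row summary of a fitted model
#'
#' @param x A `"dom_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: the model family, the selected
#'   hyperparameters and the best mean cross-validation RMSE.
#' @export
glance.dom_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(family = x$family),
    x$best,
    tibble::tibble(cv_rmse = min(x$cv_results$mean_rmse),
                   n_folds = x$cv_results$n_folds[1])
  )
}

#' Tidy a benchmark result grid
#'
#' @param x A `"dom_benchmark"`.
#' @param ... Unused.
#' @return The underlying tibble of per-cell results (one row per
#'   preprocessing combination and model family).
#' @export
tidy.dom_benchmark <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a recursive-feature-elimination curve
#'
#' @param x A `"dom_rfe"`.
#' @param ... Unused.
#' @return A tibble with `step`, `n_features`, `cv_rmse`, `cv_nrmse`.
#' @export
tidy.dom_rfe <- function(x, ...) {
  tibble::as_tibble(x)[, c("step", "n_features", "cv_rmse", "cv_nrmse")]
}
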