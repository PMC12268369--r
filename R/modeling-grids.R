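# Hyperparameter grids for the four model families.

.families <- c("glm", "rf", "svr_poly", "svr_rbf")

# Sigma ladder for the RBF kernel: 1e-6 up to 1e-5 in factor-2.5 steps,
# 2e-5, a coarser run 5e-5 to 5e-4 in factor-5 steps, then decades to 1.
.rbf_sigma_ladder <- c(1e-6, 2.5e-6, 6.25e-6, 1e-5, 2e-5,
                       5e-5, 2.5e-4, 5e-4,
                       1e-3, 1e-2, 1e-1, 1)

#' Default hyperparameter grid for a model family
#'
#' Returns the full tuning grid used in the benchmark for one of the four
#' model families:
#'
#' * `"glm"` — elastic-net linear model with zero intercept: mixing
#'   `alpha` from 0 (ridge) to 1 (lasso) in 0.05 steps crossed with
#'   regularization strength `lambda` from 0 to 2 in 0.05 steps.
#' * `"rf"` — random forest regression: 1000 trees, variance split rule,
#'   `mtry` in one-sixth increments of the feature count up to all
#'   features, and minimum node sizes 3, 5, 7, 10, 15.
#' * `"svr_poly"` — polynomial-kernel support vector regression: cost in
#'   \{0.01, 0.1, 0.25, 0.5, 0.75, 1\}, degrees one to five, fixed kernel
#'   scale 1.
#' * `"svr_rbf"` — radial-basis-kernel SVR: cost in \{0.001, 0.01, 0.1,
#'   0.25, 0.5, 0.75, 0.9, 0.99, 1\} crossed with a sigma ladder from
#'   1e-6 to 1 (factor 2.5 steps up to 1e-5, 2e-5, factor 5 steps from
#'   5e-5 to 5e-4, then decades).
#'
#' @param family One of `"glm"`, `"rf"`, `"svr_poly"`, `"svr_rbf"`.
#' @param p Number of features (required for `"rf"` to derive `mtry`).
#' @return A tibble with one row per grid point.
#' @export
model_grid <- function(family = .families, p = NULL) {
  family <- match.arg(family)
  switch(family,
    glm = tidyr::expand_grid(
      alpha = seq(0, 1, by = 0.05),
      lambda = seq(0, 2, by = 0.05)
    ),
    rf = {
      if (is.null(p)) abort("`p` (number of features) is required for the RF grid.")
      tidyr::expand_grid(
        num_trees = 1000,
        mtry = unique(ceiling(p * (1:6) / 6)),
        min_node_size = c(3, 5, 7, 10, 15)
      )
    },
    svr_poly = tidyr::expand_grid(
      cost = c(0.01, 0.1, 0.25, 0.5, 0.75, 1),
      degree = 1:5,
      scale = 1
    ),
    svr_rbf = tidyr::expand_grid(
      cost = c(0.001, 0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99, 1),
      sigma = .rbf_sigma_ladder
    )
  )
}

# Order grid rows so that, among tied cross-validation scores, the more
# strongly regularized (smoother) candidate wins: larger lambda for the
# elastic net, smaller mtry / larger node size for forests, smaller degree
# and cost for polynomial SVR, smaller cost and sigma for RBF SVR.
.tie_break_order <- function(grid, family) {
  switch(family,
    glm = order(-grid$lambda, -grid$alpha),
    rf = order(grid$mtry, -grid$min_node_size),
    svr_poly = order(grid$degree, grid$cost),
    svr_rbf = order(grid$cost, grid$sigma)
  )
}
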