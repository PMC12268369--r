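# Model-family fit wrappers with a common predict() surface.

.as_X <- function(X) {
  m <- as.matrix(if (is.data.frame(X) && "sample_id" %in% names(X)) {
    X[, setdiff(names(X), "sample_id"), drop = FALSE]
  } else {
    X
  })
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort("Feature matrix contains non-finite values.")
  m
}

#' Fit a zero-intercept elastic-net linear model
#'
#' Minimizes `(1/2n) * sum((y - X beta)^2) + lambda * ((1 - alpha)/2 *
#' ||beta||_2^2 + alpha * ||beta||_1)` with no intercept term: `alpha = 1`
#' is the lasso (one of two duplicated features is driven to zero),
#' `alpha = 0` is ridge. The intercept is fixed at zero so that the fitted
#' beta weights are directly interpretable as directional feature
#' importances (positive = terrestrial-leaning on a standardized target).
#' Features are not rescaled before fitting unless `standardize = TRUE`.
#'
#' @param X Feature matrix or `dom_features` table (samples x features).
#' @param y Numeric target (typically the Z-scored fluorescence proxy).
#' @param alpha Elastic-net mixing parameter in `[0, 1]`.
#' @param lambda Regularization strength (>= 0).
#' @param standardize Rescale features internally? Default `FALSE`.
#' @return An object of class `"dom_glm"` with the coefficient vector in
#'   `$beta`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda, standardize = FALSE) {
  X <- .as_X(X)
  if (any(!is.finite(y))) abort("Target contains non-finite values.")
  fit <- NULL
  if (lambda == 0 && !standardize) {
    # the unpenalized case is plain least squares: solve it exactly
    # (minimum-norm solution when the system is underdetermined)
    beta <- .lstsq_min_norm(X, y)
  } else {
    path <- .glmnet_path(lambda)
    fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = path,
                          intercept = FALSE, standardize = standardize,
                          thresh = 1e-10, maxit = 1e7)
    beta <- as.numeric(coef(fit, s = lambda, exact = FALSE))[-1]
  }
  structure(
    list(beta = setNames(beta, colnames(X)), alpha = alpha, lambda = lambda,
         intercept = 0, glmnet = fit, features = colnames(X)),
    class = "dom_glm"
  )
}

# Exact least squares via the singular value decomposition; small singular
# values are dropped, giving the minimum-norm solution for rank-deficient
# or underdetermined systems.
.lstsq_min_norm <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * max(dim(X)) * .Machine$double.eps
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep]))
}

# glmnet discourages single-lambda fits; embed the requested lambda in a
# short descending path so the coefficients at that exact path point are
# returned.
.glmnet_path <- function(lambda) {
  sort(unique(c(lambda, lambda * 2 + 0.5, lambda * 5 + 2)), decreasing = TRUE)
}

#' @export
predict.dom_glm <- function(object, newdata, ...) {
  X <- .as_X(newdata)[, object$features, drop = FALSE]
  as.numeric(X %*% object$beta)
}

#' Fit a random forest regression
#'
#' Wraps [ranger::ranger()] with the variance split rule, out-of-bag
#' permutation importance and retained in-bag counts (needed for the
#' tree-exact SHAP computation). Predictions are the mean over trees.
#'
#' @param X Feature matrix or `dom_features` table.
#' @param y Numeric target.
#' @param num_trees Number of trees (default 1000).
#' @param mtry Split candidates per node (default: all features divided by
#'   3, the ranger regression default).
#' @param min_node_size Minimal node size (default 5).
#' @param seed Integer seed; forests are deterministic given it.
#' @return An object of class `"dom_rf"`; `$model` is the ranger fit,
#'   `$oob_predictions` the out-of-bag predictions.
#' @export
fit_random_forest <- function(X, y, num_trees = 1000, mtry = NULL,
                              min_node_size = 5, seed = 1L) {
  X <- .as_X(X)
  if (!is.null(mtry) && mtry > ncol(X)) {
    abort("`mtry` cannot exceed the number of features.")
  }
  df <- as.data.frame(X)
  # syntactic names for ranger; original keys kept for reporting
  key_map <- setNames(colnames(X), make.names(colnames(X), unique = TRUE))
  names(df) <- names(key_map)
  fit <- ranger::ranger(
    y = y, x = df,
    num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
    splitrule = "variance", importance = "permutation",
    keep.inbag = TRUE, oob.error = TRUE, seed = seed, num.threads = 1
  )
  structure(
    list(model = fit, oob_predictions = fit$predictions,
         features = colnames(X), key_map = key_map,
         X_train = X, y_train = y, seed = seed,
         num_trees = num_trees, mtry = mtry %||% fit$mtry,
         min_node_size = min_node_size),
    class = "dom_rf"
  )
}

#' @export
predict.dom_rf <- function(object, newdata, ...) {
  X <- .as_X(newdata)[, object$features, drop = FALSE]
  df <- as.data.frame(X)
  names(df) <- names(object$key_map)
  as.numeric(predict(object$model, data = df, num.threads = 1)$predictions)
}

#' Fit an epsilon-insensitive support vector regression
#'
#' Wraps [kernlab::ksvm()] (type `"eps-svr"`) with either the polynomial
#' kernel (fixed scale 1, offset 1) or the Gaussian radial basis kernel
#' `exp(-sigma * |x - x'|^2)`. Errors smaller than the `epsilon` tube are
#' not penalized; larger deviations are penalized linearly with weight
#' `cost`. Features are used as-is (no internal rescaling), consistent
#' with the rest of the pipeline.
#'
#' @param X Feature matrix or `dom_features` table.
#' @param y Numeric target.
#' @param kernel `"poly"` or `"rbf"`.
#' @param cost Cost of tube violations.
#' @param degree Polynomial degree (poly kernel).
#' @param sigma Inverse kernel width (rbf kernel).
#' @param scale Polynomial kernel scale (default 1).
#' @param epsilon Tube half-width on the (standardized) target scale
#'   (default 0.1).
#' @return An object of class `"dom_svr"`.
#' @export
fit_svr <- function(X, y, kernel = c("poly", "rbf"), cost = 1,
                    degree = NULL, sigma = NULL, scale = 1, epsilon = 0.1) {
  kernel <- match.arg(kernel)
  X <- .as_X(X)
  if (kernel == "poly") {
    if (is.null(degree)) abort("Polynomial SVR needs `degree`.")
    kern <- kernlab::polydot(degree = degree, scale = scale, offset = 1)
  } else {
    if (is.null(sigma)) abort("RBF SVR needs `sigma`.")
    if (sigma <= 0) abort("RBF `sigma` must be positive.")
    kern <- kernlab::rbfdot(sigma = sigma)
  }
  fit <- kernlab::ksvm(x = X, y = y, type = "eps-svr", kernel = kern,
                       C = cost, epsilon = epsilon, scaled = FALSE)
  structure(
    list(model = fit, kernel = kernel, cost = cost, degree = degree,
         sigma = sigma, epsilon = epsilon, features = colnames(X)),
    class = "dom_svr"
  )
}

#' @export
predict.dom_svr <- function(object, newdata, ...) {
  X <- .as_X(newdata)[, object$features, drop = FALSE]
  as.numeric(kernlab::predict(object$model, X))
}

# Fit one grid row for a family; used by CV and by the final refit.
.fit_family <- function(family, X, y, params, seed = 1L, epsilon = 0.1) {
  switch(family,
    glm = fit_elastic_net(X, y, alpha = params$alpha, lambda = params$lambda),
    rf = fit_random_forest(X, y, num_trees = params$num_trees,
                           mtry = min(params$mtry, ncol(.as_X(X))),
                           min_node_size = params$min_node_size, seed = seed),
    svr_poly = fit_svr(X, y, kernel = "poly", cost = params$cost,
                       degree = params$degree, scale = params$scale,
                       epsilon = epsilon),
    svr_rbf = fit_svr(X, y, kernel = "rbf", cost = params$cost,
                      sigma = params$sigma, epsilon = epsilon)
  )
}
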