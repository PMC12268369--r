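# SHAP values: tree-exact for random forests, seeded coalition sampling for
# the other model families.

# Extract one ranger tree as flat arrays (0-based ids) plus per-node covers
# computed by routing the in-bag training samples down the tree.
.rf_tree_structure <- function(rf, tree) {
  ti <- ranger::treeInfo(rf$model, tree)
  nn <- nrow(ti)
  left <- ifelse(is.na(ti$leftChild), -1L, ti$leftChild)
  right <- ifelse(is.na(ti$rightChild), -1L, ti$rightChild)
  feature <- ifelse(is.na(ti$splitvarID), -1L, ti$splitvarID)
  threshold <- ifelse(is.na(ti$splitval), 0, ti$splitval)
  value <- ifelse(is.na(ti$prediction), 0, ti$prediction)

  inbag <- rf$model$inbag.counts[[tree]]
  X <- rf$X_train
  cover <- numeric(nn)
  for (s in seq_len(nrow(X))) {
    w <- inbag[s]
    if (w == 0) next
    nd <- 0L
    repeat {
      cover[nd + 1L] <- cover[nd + 1L] + w
      if (left[nd + 1L] < 0L) break
      nd <- if (X[s, feature[nd + 1L] + 1L] <= threshold[nd + 1L]) {
        left[nd + 1L]
      } else {
        right[nd + 1L]
      }
    }
  }
  list(left = as.integer(left), right = as.integer(right),
       feature = as.integer(feature), threshold = as.numeric(threshold),
       value = as.numeric(value), cover = cover)
}

# Cover-weighted mean leaf value of one tree (its baseline prediction).
.tree_expected_value <- function(tr) {
  leaves <- tr$left < 0L
  sum(tr$value[leaves] * tr$cover[leaves]) / tr$cover[1]
}

#' SHAP values of a fitted model
#'
#' Per-sample, per-feature Shapley attributions of the model's
#' predictions. For random forests the values are computed tree-exactly
#' with the polynomial-time path-dependent tree algorithm (averaged over
#' trees), so the additivity identity `rowSums(shap) + expected_value ==
#' prediction` holds to numerical precision. For the other model families
#' a seeded coalition-sampling estimator is used (random feature orderings
#' against a background dataset), for which additivity holds within Monte
#' Carlo error.
#'
#' @param fit A `"dom_fit"`, `"dom_rf"`, `"dom_glm"` or `"dom_svr"`.
#' @param X Samples to explain (matrix or `dom_features`); columns must
#'   match the model's features.
#' @param background Background data for the sampling estimator (defaults
#'   to `X`).
#' @param nsim Number of sampled feature orderings per sample (sampling
#'   estimator only; default 100).
#' @param seed Seed for the sampling estimator.
#' @return A list of class `"dom_shap"`: `shap` (samples x features
#'   matrix), `expected_value` (baseline prediction), `method`
#'   (`"tree"` or `"sampling"`).
#' @export
shap_values <- function(fit, X, background = NULL, nsim = 100, seed = 1L) {
  model <- if (inherits(fit, "dom_fit")) fit$model else fit
  X <- .as_X(X)
  if (!setequal(colnames(X), model$features) ||
      !all(colnames(X) == model$features)) {
    X <- tryCatch(X[, model$features, drop = FALSE],
                  error = function(e) abort(
                    "Feature mismatch between model and `X`."))
  }
  if (inherits(model, "dom_rf")) {
    .shap_tree(model, X)
  } else {
    .shap_sampling(model, X, background = background, nsim = nsim,
                   seed = seed)
  }
}

.shap_tree <- function(model, X) {
  nt <- model$model$num.trees
  phi <- matrix(0, nrow = nrow(X), ncol = ncol(X),
                dimnames = list(rownames(X), colnames(X)))
  ev <- 0
  for (t in seq_len(nt)) {
    tr <- .rf_tree_structure(model, t)
    phi <- phi + treeshap_tree_cpp(tr$left, tr$right, tr$feature,
                                   tr$threshold, tr$value, tr$cover, X)
    ev <- ev + .tree_expected_value(tr)
  }
  structure(
    list(shap = phi / nt, expected_value = ev / nt, method = "tree"),
    class = "dom_shap"
  )
}

.shap_sampling <- function(model, X, background = NULL, nsim = 100,
                           seed = 1L) {
  background <- if (is.null(background)) X else .as_X(background)
  background <- background[, colnames(X), drop = FALSE]
  p <- ncol(X)
  phi <- matrix(0, nrow = nrow(X), ncol = p,
                dimnames = list(rownames(X), colnames(X)))
  withr::with_seed(seed, {
    for (s in seq_len(nrow(X))) {
      x <- X[s, ]
      acc <- numeric(p)
      for (r in seq_len(nsim)) {
        perm <- sample.int(p)
        b <- background[sample.int(nrow(background), 1L), ]
        # walk the permutation, switching features from background to x
        steps <- matrix(rep(b, p + 1L), nrow = p + 1L, byrow = TRUE,
                        dimnames = list(NULL, colnames(X)))
        for (j in seq_len(p)) {
          steps[(j + 1L):(p + 1L), perm[j]] <- x[perm[j]]
        }
        preds <- predict(model, steps)
        acc[perm] <- acc[perm] + diff(preds)
      }
      phi[s, ] <- acc / nsim
    }
  })
  structure(
    list(shap = phi,
         expected_value = mean(predict(model, background)),
         method = "sampling"),
    class = "dom_shap"
  )
}

#' @export
print.dom_shap <- function(x, ...) {
  cat(sprintf("<dom_shap> %d samples x %d features (%s), baseline %.4g\n",
              nrow(x$shap), ncol(x$shap), x$method, x$expected_value))
  invisible(x)
}
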