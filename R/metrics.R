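# Evaluation metrics and set-similarity helpers.

#' Normalized root-mean-square error (NRMSE)
#'
#' Expresses an RMSE as a percentage of the target's full range:
#' `100 * rmse / (max(target) - min(target))`. Reported in percent of the
#' original target scale throughout the package.
#'
#' @param rmse Root-mean-square error on the target's original scale.
#' @param target The target values whose range defines the scale (the full
#'   dataset's values, not only the test set), or a length-2 range.
#' @return NRMSE in percent.
#' @examples
#' nrmse(0.3, c(-27.7, -21.9))
#' @export
nrmse <- function(rmse, target) {
  rng <- range(target)
  if (diff(rng) <= 0) abort("NRMSE undefined: target has zero range.")
  100 * rmse / diff(rng)
}

#' Standard error of the mean
#'
#' `sd(values) / sqrt(length(values))`, used to judge whether an error
#' estimate from repeated model trainings is an outlier.
#'
#' @param values Numeric vector of repeated measurements (n >= 2).
#' @return The standard error of the mean.
#' @export
sem <- function(values) {
  if (length(values) < 2) abort("SEM needs at least two values.")
  sd(values) / sqrt(length(values))
}

#' Two-sided Wilcoxon rank test with continuity correction
#'
#' Compares two metric vectors with the two-sided Wilcoxon test using the
#' normal approximation with continuity correction (average ranks for
#' ties). For paired comparisons, zero differences are dropped first, the
#' standard signed-rank convention.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Use the signed-rank test on paired differences?
#' @return The two-sided p-value.
#' @export
wilcoxon_compare <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b)) {
      abort("Paired comparison needs vectors of equal length.")
    }
    keep <- (a - b) != 0
    if (!any(keep)) {
      abort("All paired differences are zero; the signed-rank test is undefined.")
    }
    a <- a[keep]
    b <- b[keep]
  }
  res <- suppressWarnings(
    wilcox.test(a, b, paired = paired, alternative = "two.sided",
                correct = TRUE, exact = FALSE)
  )
  unname(res$p.value)
}

#' Jaccard similarity of two feature sets
#'
#' `|A intersect B| / |A union B|`, ranging from 0 (disjoint) to 1 (equal
#' sets). Two empty sets are treated as identical (similarity 1, with a
#' message).
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return Similarity in `[0, 1]`.
#' @examples
#' # two terrestrial-marker sets sharing 759 of 3546 + 1450 formulas:
#' a <- paste0("f", seq_len(3546)); b <- c(a[seq_len(759)], paste0("g", seq_len(691)))
#' jaccard(a, b)
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    inform("Jaccard similarity of two empty sets defined as 1.")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}
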