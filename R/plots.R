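# ggplot2 displays for benchmark grids, RFE curves and importance reports.

#' Heatmap of benchmark NRMSE values
#'
#' Mirrors the standard presentation of the model comparison: model
#' families across, normalizations down, one panel per table format and
#' feature-elimination choice, tiles colored and labeled by test-set
#' NRMSE in percent of the original target range.
#'
#' @param object A `"dom_benchmark"` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dom_benchmark <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$normalization,
                                   fill = .data$nrmse)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$nrmse)),
                       size = 3) +
    ggplot2::facet_grid(table_format ~ elimination) +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "NRMSE [%]") +
    ggplot2::labs(x = "model family", y = "normalization",
                  title = "Test-set NRMSE by preprocessing and model family")
}

#' Recursive feature elimination curve
#'
#' Cross-validated NRMSE against the number of remaining features, on a
#' reversed log axis so the elimination reads left to right.
#'
#' @param object A `"dom_rfe"` from [recursive_feature_elimination()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dom_rfe <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_features, y = .data$cv_nrmse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "remaining features", y = "CV NRMSE [%]",
                  title = "Recursive feature elimination")
}

#' Top features of an importance report
#'
#' @param object A `dom_importance` tibble.
#' @param k Number of features to display (default 20).
#' @param ... Unused.
#' @return A ggplot object (horizontal bars, strongest on top; beta
#'   weights keep their sign).
#' @export
autoplot.dom_importance <- function(object, k = 20, ...) {
  top <- .rank_features(object, k)
  df <- tibble::as_tibble(object)[match(top, object$feature), ]
  df$feature <- factor(df$feature, levels = rev(top))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = paste0("score (", df$method[1], ")"), y = NULL,
                  title = sprintf("Top %d features", nrow(df)))
}
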