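#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object a `roc_result`.
#' @param ... unused.
#' @return a ggplot: the empirical ROC with the chance diagonal and the
#'   optimal cutoff marked.
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- object$curve
  cut <- tibble::tibble(fpr = 1 - object$specificity,
                        sensitivity = object$sensitivity)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cut, colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc),
                  subtitle = sprintf("optimal cutoff %.3g: sens %.0f%%, spec %.0f%%",
                                     object$optimal_cutoff,
                                     100 * object$sensitivity,
                                     100 * object$specificity)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a scintigram pair
#'
#' @param object a `scintigram_pair`.
#' @param ... unused.
#' @return a ggplot raster of the two views (square-root intensity scale, the
#'   usual display transform for count images).
#' @export
autoplot.scintigram_pair <- function(object, ...) {
  df <- purrr::map_dfr(c("anterior", "posterior"), function(v) {
    M <- object[[v]]
    tibble::tibble(view = v,
                   row = rep(seq_len(nrow(M)), ncol(M)),
                   col = rep(seq_len(ncol(M)), each = nrow(M)),
                   counts = as.numeric(M))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = sqrt(.data$counts))) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~view) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = expression(sqrt(counts))) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a reclassification table
#'
#' @param object a `reclass_table`.
#' @param ... unused.
#' @return a ggplot tile heatmap of old vs new categories with counts.
#' @export
autoplot.reclass_table <- function(object, ...) {
  labs <- object$labels %||% as.character(1:4)
  df <- tidyr::expand_grid(old = 1:4, new = 1:4)
  df$count <- as.numeric(object$counts)[cbind(df$old, df$new)]
  df$count <- object$counts[cbind(df$old, df$new)]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$new, labels = labs),
                                   y = factor(.data$old, labels = labs),
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(labs)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "new method", y = "old method",
                  title = sprintf("%s stratum (n = %d), net gain %+.1f%%",
                                  object$stratum, object$n,
                                  100 * net_gain(object))) +
    ggplot2::theme_minimal()
}
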