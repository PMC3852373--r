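#' Plot methods
#'
#' `autoplot()` methods render the package's result objects with ggplot2:
#' residual field maps as heat maps (the classic per-model residual panel of
#' a spatial-adjustment analysis), PCoA scatter plots, and cross-validation
#' accuracy distributions.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name spatgs-plots
NULL

#' @rdname spatgs-plots
#' @method autoplot field_map
#' @export
autoplot.field_map <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$residual)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "column", y = "row", fill = "residual",
      title = if (!is.null(object$model)) {
        sprintf("Plot residuals (%s), Moran's I = %.3f (p = %.3f)",
                object$model, object$moran$I, object$moran$p_value)
      } else {
        sprintf("Plot residuals, Moran's I = %.3f (p = %.3f)",
                object$moran$I, object$moran$p_value)
      })
}

#' @rdname spatgs-plots
#' @method autoplot spatial_fit
#' @export
autoplot.spatial_fit <- function(object, ...) {
  autoplot.field_map(residual_field_map(object, n_perm = 199L))
}

#' @rdname spatgs-plots
#' @param groups Optional data frame with `line_id` and a grouping column
#'   (e.g. the `subpops` tibble of [simulate_genotypes()]).
#' @method autoplot spatgs_pcoa
#' @export
autoplot.spatgs_pcoa <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  if (!is.null(groups)) df <- dplyr::left_join(df, groups, by = "line_id")
  grp <- if (!is.null(groups)) names(groups)[2] else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", object$pct_variance[1]),
      y = sprintf("PCo2 (%.1f%%)", object$pct_variance[2]))
  if (is.null(grp)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[grp]]))
  }
}

#' @rdname spatgs-plots
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::labs(x = "replicate accuracy (Pearson r)", y = "count")
}

#' @rdname spatgs-plots
#' @method autoplot adjustment_comparison
#' @export
autoplot.adjustment_comparison <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$model, y = .data$accuracy,
                               fill = .data$kernel)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "adjustment model", y = "accuracy (Pearson r)")
}
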