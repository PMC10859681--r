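#' Plot a stability report
#'
#' Stacked bars of reproducibility-group percentages per segmentation arm,
#' mirroring the usual Poor/Fair/Good/Excellent summary table.
#'
#' @param object A [stability_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  df <- dplyr::mutate(object$bin_counts,
                      group = factor(.data$group, levels = rev(icc_bins())))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$pct,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      Excellent = "#1b7837", Good = "#a6dba0", Fair = "#fdb863", Poor = "#b2182b"
    )) +
    ggplot2::labs(x = "segmentation arm", y = "% of features",
                  fill = "reproducibility",
                  title = sprintf("Feature reproducibility by arm  [ICC(%s)]",
                                  sub("1", ",1", object$model))) +
    ggplot2::theme_minimal()
}

#' Per-feature ICC comparison across arms
#'
#' @param report A [stability_report()].
#' @return A ggplot object: one point per (feature, arm), features ordered by
#'   the first arm's ICC.
#' @export
plot_icc_comparison <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  first_arm <- report$summary$arm[1]
  ord <- report$icc |>
    dplyr::filter(.data$arm == first_arm) |>
    dplyr::arrange(.data$icc)
  df <- dplyr::mutate(report$icc,
                      feature = factor(.data$feature, levels = ord$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc, y = .data$feature,
                                   colour = .data$arm)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(0.4, 0.6, 0.75), linetype = "dotted") +
    ggplot2::labs(x = "ICC", y = NULL, colour = "arm") +
    ggplot2::theme_minimal()
}

#' Display an image with an optional mask contour
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param mask Optional logical matrix drawn as a contour overlay.
#' @return A ggplot object.
#' @export
plot_gray_image <- function(image, mask = NULL) {
  assert_image(image)
  df <- tidyr::expand_grid(row = seq_len(nrow(image)), col = seq_len(ncol(image)))
  df$value <- image[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
  if (!is.null(mask)) {
    assert_mask(mask, allow_empty = TRUE)
    df$mask <- as.numeric(mask[cbind(df$row, df$col)])
    p <- p + ggplot2::geom_contour(data = df,
                                   ggplot2::aes(z = .data$mask),
                                   breaks = 0.5, colour = "red", linewidth = 0.4)
  }
  p
}
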