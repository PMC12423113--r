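#' Plot PC scores, optionally colored by morphotype cluster
#'
#' @param object A `morpho_pca`.
#' @param assignments Optional cluster labels, one per specimen.
#' @param pcs Which two components to plot (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.morpho_pca <- function(object, assignments = NULL, pcs = c(1, 2), ...) {
  d <- object$scores
  xs <- paste0("PC", pcs[1])
  ys <- paste0("PC", pcs[2])
  lab <- function(i) {
    sprintf("PC%d (%.1f%%)", pcs[i], object$percent_variance[pcs[i]])
  }
  p <- if (is.null(assignments)) {
    ggplot2::ggplot(d, ggplot2::aes(.data[[xs]], .data[[ys]]))
  } else {
    d$cluster <- factor(assignments)
    ggplot2::ggplot(
      d, ggplot2::aes(.data[[xs]], .data[[ys]], colour = .data$cluster)
    ) +
      ggplot2::stat_ellipse(level = 0.95, na.rm = TRUE)
  }
  p +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Plot aligned landmark configurations with the mean shape
#'
#' @param object A `gpa_alignment`.
#' @param ... Unused.
#' @return A ggplot of aligned landmarks (grey) over the mean shape (black).
#' @export
autoplot.gpa_alignment <- function(object, ...) {
  pts <- tidy(object)
  mean_df <- tibble::tibble(
    landmark = seq_len(nrow(object$mean_shape)),
    x = object$mean_shape[, 1],
    y = object$mean_shape[, 2]
  )
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8, colour = "grey40") +
    ggplot2::geom_point(data = mean_df, colour = "black", size = 2) +
    ggplot2::geom_text(
      data = mean_df, ggplot2::aes(label = .data$landmark),
      nudge_y = 0.012, size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot WIC/BIC stacked niche components with IS labels
#'
#' @param object A `niche_decomposition_tbl` from [decompose_niche()].
#' @param ... Unused.
#' @return A ggplot: stacked WIC + BIC (= TNW) bars per group, faceted by
#'   isotope, annotated with IS = WIC/TNW.
#' @export
autoplot.niche_decomposition_tbl <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "isotope", "group", "WIC", "BIC"),
    c("WIC", "BIC"),
    names_to = "component", values_to = "variance"
  )
  labels <- dplyr::mutate(
    object,
    label = sprintf("IS = %.2f", .data$IS)
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$group, .data$variance, fill = .data$component)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      data = labels,
      ggplot2::aes(.data$group, .data$TNW, label = .data$label),
      inherit.aes = FALSE, vjust = -0.4, size = 3
    ) +
    ggplot2::facet_wrap(~isotope) +
    ggplot2::labs(
      x = NULL,
      y = "Variance (‰²)",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
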