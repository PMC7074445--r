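#' @exportS3Method ggplot2::autoplot
autoplot.gpa_fit <- function(object, ...) {
  ggplot2::ggplot(object$aligned, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6, colour = "grey40") +
    ggplot2::geom_point(
      data = object$consensus,
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "firebrick", size = 2
    ) +
    ggplot2::geom_text(
      data = object$consensus,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$lm),
      vjust = -0.8, size = 3, colour = "firebrick"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "Procrustes-aligned configurations and consensus",
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.wing_cva <- function(object, axes = c(1L, 2L), ...) {
  ax <- paste0("CV", axes)
  if (!all(ax %in% names(object$scores))) {
    abort("requested canonical axes not present")
  }
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]], colour = .data$site_id)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = "Canonical variate scores", colour = "site") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.spca_fit <- function(object, axis = 1L, ...) {
  if (is.null(object$network)) {
    abort("sPCA fit carries no network coordinates to map")
  }
  dat <- dplyr::bind_cols(object$network$coords, object$scores)
  col <- paste0("Axis", axis)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data[[col]]),
                                     fill = .data[[col]] > 0),
                        shape = 22, alpha = 0.8) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white"),
                               guide = "none") +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(
      title = sprintf("sPCA scores (axis %d): square size = |score|, fill = sign", axis),
      x = "longitude", y = "latitude", size = "|score|"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.structure_test <- function(object, ...) {
  ggplot2::ggplot(
    tibble(max_t = object$permuted_max_t),
    ggplot2::aes(x = .data$max_t)
  ) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_max_t,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      title = sprintf("%s structure test: observed max(t) vs %d permutations (p = %.4g)",
                      object$kind, object$nperm, object$p_value),
      x = "max(t)", y = "permutation count"
    ) +
    ggplot2::theme_minimal()
}

#' Map an interpolated score surface
#'
#' @param grid Tibble `lat`, `lon`, `value` from [interpolate_scores()].
#' @param coords Optional sample locations to overlay.
#' @return A ggplot.
#' @export
plot_score_surface <- function(grid, coords = NULL) {
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient2(low = "white", mid = "grey60", high = "black",
                                  na.value = "transparent") +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "score") +
    ggplot2::theme_minimal()
  if (!is.null(coords)) {
    p <- p + ggplot2::geom_point(data = coords, size = 0.4, colour = "red")
  }
  p
}
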