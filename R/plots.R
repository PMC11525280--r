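# Plot helpers for the main result types.

#' Plot a wrist speed profile with its segmentation
#'
#' @param profile Tibble from [speed_profile()].
#' @param segments Optional tibble from [segment_movements()]; segment
#'   bounds are drawn as vertical dashed lines.
#' @return A ggplot.
#' @export
plot_speed_profile <- function(profile, segments = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$time_s, y = .data$v)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "wrist speed (m/s)") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0L) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(segments$t_start, segments$t_end),
                          linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot a center-of-pressure trajectory
#'
#' @param plate Force-plate tibble (`cop_ml_cm`, `cop_ap_cm`).
#' @return A ggplot of the sway path with equal axis scaling.
#' @export
plot_cop <- function(plate) {
  ggplot2::ggplot(plate, ggplot2::aes(x = .data$cop_ml_cm,
                                      y = .data$cop_ap_cm)) +
    ggplot2::geom_path(colour = "steelblue", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "medio-lateral CoP (cm)", y = "antero-posterior CoP (cm)") +
    ggplot2::theme_minimal()
}

#' Plot a t-SNE + K-means clustering
#'
#' @param object Tibble returned by [tsne_kmeans()].
#' @param ... Unused.
#' @return A ggplot of the embedding colored by cluster.
#' @export
plot_tsne_clusters <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tsne_1, y = .data$tsne_2,
                                       colour = factor(.data$cluster))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "cluster") +
    ggplot2::theme_minimal()
}
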