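#' Plot the effect of group averaging on screening metrics
#'
#' Line plot of mean Z', robust Z' and SSMD* against the number of larvae
#' averaged per group, from [bootstrap_group_averaging()].
#'
#' @param averaging tibble from [bootstrap_group_averaging()].
#' @return a ggplot object.
#' @export
plot_group_averaging <- function(averaging) {
  long <- tidyr::pivot_longer(averaging,
                              c("z_prime", "robust_z_prime", "ssmd_star"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group_size, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "larvae averaged per group", y = "metric value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-condition score distributions
#'
#' Jittered per-larva scores with median bars, e.g. for a dose-response
#' series.
#'
#' @param scores tidy score table.
#' @param score,condition column names.
#' @return a ggplot object.
#' @export
plot_scores <- function(scores, score = "bhs", condition = "condition") {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data[[condition]],
                                       y = .data[[score]])) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3, colour = "red") +
    ggplot2::labs(x = NULL, y = "Brain Health Score") +
    ggplot2::theme_minimal()
}

#' Display a brain template or crop as a raster
#'
#' @param object a `brain_template` or `brain_crop`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.brain_template <- function(object, ...) {
  raster_plot(object$M, "template intensity")
}

#' @rdname autoplot.brain_template
#' @export
autoplot.brain_crop <- function(object, ...) {
  raster_plot(object$image, "counts")
}

raster_plot <- function(m, legend) {
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = legend, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
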