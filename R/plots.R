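#' Low- vs high-SF activation scatter
#'
#' Each point is a placement; the dashed lines at 1 separate suppression
#' (< 1) from amplification (> 1).
#'
#' @param results A `pipeline_result`.
#' @return A ggplot object.
#' @export
plot_activation_scatter <- function(results) {
  df <- results$placements
  ggplot2::ggplot(df, ggplot2::aes(x = .data$activation_low,
                                   y = .data$activation_high,
                                   colour = factor(.data$group))) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::labs(x = "output/input activation (low SF)",
                  y = "output/input activation (high SF)",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Input- vs output-layer cutoff SF comparison
#'
#' @param results A `pipeline_result`.
#' @return A ggplot object.
#' @export
plot_cutoff_comparison <- function(results) {
  df <- results$placements
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff_in, y = .data$cutoff_out,
                                   colour = factor(.data$group))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "input-layer cutoff SF (c/deg)",
                  y = "output-layer cutoff SF (c/deg)",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Mechanism contributions across SF
#'
#' Mean normalized contribution of the M, P and recurrent mechanisms at each
#' SF condition, across placements.
#'
#' @param results A `pipeline_result`.
#' @return A ggplot object.
#' @export
plot_contribution_curves <- function(results) {
  df <- results$contributions
  summ <- df |>
    dplyr::group_by(.data$sf, .data$component) |>
    dplyr::summarise(contribution = mean(.data$contribution, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$sf, y = .data$contribution,
                                     colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "spatial frequency (c/deg)",
                  y = "normalized contribution", colour = "mechanism") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dynamic_response <- function(object, ...) {
  tb <- attr(object, "time")
  df <- tidyr::expand_grid(orientation = 0:(nrow(object) - 1),
                           delay_ms = tb)
  df$response <- as.vector(t(unclass(object)[, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delay_ms,
                                   y = factor(.data$orientation * 20),
                                   fill = .data$response)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "delay (ms)", y = "orientation (deg)",
                  fill = "spikes/s") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ffrec_fit <- function(object, ...) {
  df <- tidyr::expand_grid(sf = object$sf, t_ms = object$time)
  df$fitted <- as.vector(t(object$fitted))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$fitted)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~sf, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (ms)", y = "fitted response (spikes/s)",
                  title = sprintf("%s model, gof_raw = %.3f",
                                  toupper(object$variant), object$gof_raw)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sf_tuning_fit <- function(object, ...) {
  grid <- exp(seq(log(min(object$sf)), log(max(object$sf)),
                  length.out = 200))
  curve <- object$a1 * exp(-grid^2 / (2 * object$sigma1^2)) -
    object$a2 * exp(-grid^2 / (2 * object$sigma2^2))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = tibble::tibble(sf = grid, r = curve),
                       ggplot2::aes(x = .data$sf, y = .data$r)) +
    ggplot2::geom_point(data = tibble::tibble(sf = object$sf,
                                              r = object$data),
                        ggplot2::aes(x = .data$sf, y = .data$r)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "spatial frequency (c/deg)",
                  y = "response (spikes/s)") +
    ggplot2::theme_minimal()
}
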