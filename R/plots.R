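# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training history of a yield model
#'
#' Loss curves (MSE, heteroscedastic NLL, blended objective, all in
#' standardized units) against epoch on a free y scale.
#'
#' @param object A fitted [yieldnet()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yieldnet <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              cols = c("mse", "nll", "objective"),
                              names_to = "loss", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "loss (standardized units)",
                  title = "Training history")
}

#' Plot a selective-prediction coverage curve
#'
#' MAE and RMSE against prediction coverage; coverage decreases to the right,
#' mirroring how the curve is read (reject more, keep less).
#'
#' @param object A [coverage_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yieldnet_coverage <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("mae", "rmse"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$coverage, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "prediction coverage", y = "error (percent points)",
                  colour = NULL, title = "Selective prediction")
}

#' Parity plot of predicted versus observed yields
#'
#' Points are shaded by the uncertainty score so over-confident errors stand
#' out; the identity line marks perfect prediction.
#'
#' @param data A data frame (typically predictions joined to truth).
#' @param truth,estimate Observed and predicted yield columns (unquoted).
#' @param score Optional uncertainty score column (unquoted).
#' @return A ggplot object.
#' @export
plot_yield_parity <- function(data, truth, estimate, score = NULL) {
  tq <- rlang::enquo(truth); eq <- rlang::enquo(estimate)
  sq <- rlang::enquo(score)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = !!tq, y = !!eq))
  if (!rlang::quo_is_null(sq)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = !!sq), alpha = 0.6) +
      ggplot2::scale_colour_viridis_c()
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6)
  }
  p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "observed yield (%)", y = "predicted yield (%)")
}
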