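# ggplot2 visualisation: relaxation maps as rasters, fitted curves against
# the pixel samples, and modified Bland-Altman agreement plots
# (difference vs. reference with bias and 95 % limit-of-agreement lines).

#' @export
autoplot.relaxation_map <- function(object,
                                    which = c("tau", "residual"), ...) {
  which <- match.arg(which)
  df <- tidy(object)
  if (which == "tau") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$tau)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_viridis_c(name = "tau (ms)") +
      ggplot2::coord_fixed() +
      ggplot2::labs(title = sprintf("%s %s relaxation map",
                                    object$provenance$model_id,
                                    object$provenance$variant),
                    x = NULL, y = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$residual_pct)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_viridis_c(name = "residual (%)", option = "magma") +
      ggplot2::coord_fixed() +
      ggplot2::labs(title = "Curve-fit residual map", x = NULL, y = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot a fitted relaxation curve over the pixel samples
#'
#' @param fit A `relax_fit` from [fit_pixel()] or [fit_roi_mean()].
#' @param pixel The [pixel_series()] that was fitted.
#' @return A ggplot object.
#' @export
plot_fit_curve <- function(fit, pixel) {
  stopifnot(inherits(fit, "relax_fit"), inherits(pixel, "pixel_series"))
  model <- fit$model
  tt <- pixel$times
  tt[pixel$is_anchor] <- 0
  tgrid <- seq(0, max(tt), length.out = 200)
  curve <- predict_signal(model, list(A = fit$A, B = fit$B, tau = fit$tau),
                          tgrid)
  pts <- tibble(t = tt, signal = pixel$values, anchor = pixel$is_anchor)
  ggplot2::ggplot() +
    ggplot2::geom_line(data = tibble(t = tgrid, signal = curve),
                       ggplot2::aes(x = .data$t, y = .data$signal)) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$t, y = .data$signal,
                                     shape = .data$anchor), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                guide = "none") +
    ggplot2::labs(x = "preparation time (ms)", y = "signal",
                  title = sprintf("%s %s: tau = %.1f ms, residual = %.2f %%",
                                  model$model_id, model$variant, fit$tau,
                                  fit$residual_pct)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.agreement_stats <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$reference, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias_ms, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = c(object$loa_low_ms, object$loa_high_ms),
                        linetype = "dashed") +
    ggplot2::labs(x = "reference (ms)", y = "measured - reference (ms)",
                  title = sprintf("Bias %.2f ms, 95 %% LoA [%.2f, %.2f] ms",
                                  object$bias_ms, object$loa_low_ms,
                                  object$loa_high_ms)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
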