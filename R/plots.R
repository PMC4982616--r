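# ggplot2 displays for fits and validation reports.

#' Measured-vs-predicted scatter with the two-fold band
#'
#' Plots each validation pair on log10-log10 axes with the 1:1 line (solid)
#' and the two-fold prediction interval (dashed).
#'
#' @param object A `baf_validation` from [validate_transfer()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot baf_validation
#' @export
autoplot.baf_validation <- function(object, ...) {
  pairs <- object$pairs
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$predicted, y = .data$measured,
                                      colour = .data$cultivar)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = log10(2), linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = log10(0.5), linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Predicted BAF", y = "Measured BAF",
      title = sprintf("%.0f%% of %d pairs within 2-fold; R2 = %.3f (linear)",
                      100 * object$frac_within_twofold, object$n,
                      object$r2_linear)
    ) +
    ggplot2::theme_minimal()
}

#' Partial-relationship plot for a fitted transfer model
#'
#' Observed log10(BAF) against one predictor, with the model's fitted line
#' evaluated at the mean of the other predictors.
#'
#' @param records BAF record tibble.
#' @param soils Soil tibble.
#' @param model A [transfer_model()].
#' @param predictor One of the model's predictors, e.g. `"ph"` or
#'   `"log_oc"`.
#' @return A ggplot object.
#' @export
plot_transfer_fit <- function(records, soils, model, predictor = "ph") {
  stopifnot(predictor %in% model$predictors)
  joined <- join_soils(records, soils)
  x <- predictor_matrix(joined, model$predictors)
  df <- tibble::tibble(
    x = x[, predictor],
    log_baf = log10(joined$baf)
  )
  others <- setdiff(model$predictors, predictor)
  offset <- model$intercept +
    if (length(others)) sum(colMeans(x[, others, drop = FALSE]) *
                              model$coefficients[others]) else 0
  slope <- model$coefficients[[predictor]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$log_baf)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = slope, intercept = offset,
                         colour = "steelblue") +
    ggplot2::labs(x = predictor, y = "log10(BAF)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
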