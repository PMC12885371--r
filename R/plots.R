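#' Plot parameter recovery scatter
#'
#' True versus recovered values, one facet per parameter, with the identity
#' line and the pooled Pearson correlation in the facet label.
#'
#' @param object A `ca_recovery` from [run_parameter_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_recovery <- function(object, ...) {
  pooled <- object$summary[object$summary$condition == "pooled", ]
  lab <- setNames(sprintf("%s (r = %.2f)", pooled$term, pooled$r),
                  pooled$term)
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$true, y = .data$recovered,
                               colour = .data$condition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~term, scales = "free",
                        labeller = ggplot2::labeller(term = lab)) +
    ggplot2::labs(title = paste("Parameter recovery:", object$variant),
                  x = "generative value", y = "recovered value") +
    ggplot2::theme_minimal()
}

#' Plot a model-recovery confusion matrix
#'
#' @param object A `ca_confusion` from [run_model_recovery()].
#' @param criterion `"aic"` or `"bic"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_confusion <- function(object, criterion = c("aic", "bic"), ...) {
  criterion <- match.arg(criterion)
  m <- object$matrix[[criterion]]
  df <- tidyr::expand_grid(generator = rownames(m), winner = colnames(m))
  df$prop <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$winner, y = .data$generator,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prop))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(title = paste("Model recovery,", toupper(criterion)),
                  x = "selected model", y = "generating model",
                  fill = "proportion") +
    ggplot2::theme_minimal()
}

#' Plot stay/switch cell means
#'
#' Stay proportion per condition x time x reward-valence cell of the
#' stay/switch signature.
#'
#' @param x A `ca_signature` from [stay_signature_regression()].
#' @return A ggplot object.
#' @export
plot_stay_cells <- function(x) {
  stopifnot(inherits(x, "ca_signature"), !is.null(x$cells))
  ggplot2::ggplot(x$cells,
                  ggplot2::aes(x = .data$time, y = .data$p_stay,
                               fill = .data$reward)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "feedback time", y = "P(stay)",
                  fill = "reward valence") +
    ggplot2::theme_minimal()
}

#' Plot the credit-assignment gradient
#'
#' Mean one-step value credit applied to the options selected at lags 0-3,
#' split by prediction-error valence and condition.
#'
#' @param gradient Tibble from [credit_gradient()].
#' @return A ggplot object.
#' @export
plot_credit_gradient <- function(gradient) {
  ggplot2::ggplot(gradient,
                  ggplot2::aes(x = .data$lag, y = .data$mean_credit,
                               colour = .data$valence)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "selection lag (trials back)", y = "mean credit") +
    ggplot2::theme_minimal()
}
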