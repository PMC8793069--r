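#' Plot cross-validation ROC or precision-recall curves
#'
#' Draws one curve per balanced negative draw from the held-out
#' predictions stored in a [cross_validate()] result.
#'
#' @param object a `cv_result` fitted with `keep_predictions = TRUE`.
#' @param type `"roc"` or `"pr"`.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  if (is.null(object$predictions)) {
    abort("cv_result was built with keep_predictions = FALSE")
  }
  g <- glance(object)
  curves <- object$predictions |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::group_modify(~ if (type == "roc") {
      roc_points(.x$label, .x$score)
    } else {
      pr_points(.x$label, .x$score)
    }) |>
    dplyr::ungroup()
  if (type == "roc") {
    ggplot2::ggplot(curves,
                    ggplot2::aes(.data$fpr, .data$tpr,
                                 group = .data$repeat_id)) +
      ggplot2::geom_step(alpha = 0.5, colour = "steelblue") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC, %d-fold CV: mean AUC %.3f ± %.3f",
                        object$k, g$mean_auc, g$sd_auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(curves,
                    ggplot2::aes(.data$recall, .data$precision,
                                 group = .data$repeat_id)) +
      ggplot2::geom_step(alpha = 0.5, colour = "firebrick",
                         direction = "vh") +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("PR, %d-fold CV: mean AUPR %.3f ± %.3f",
                        object$k, g$mean_aupr, g$sd_aupr)) +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.cv_result
#' @param cv a `cv_result`.
#' @export
plot_roc <- function(cv) autoplot(cv, type = "roc")

#' @rdname autoplot.cv_result
#' @export
plot_pr <- function(cv) autoplot(cv, type = "pr")

#' @export
ggplot2::autoplot
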