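#' Plot per-ROI screening significance
#'
#' Manhattan-style display of `-log10(p)` per ROI, one line per measure set —
#' the usual way to eyeball where the fusion measure gains over single
#' modalities.
#'
#' @param object A `roi_screen` tibble from [screen_rois()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.roi_screen <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$roi, y = .data$neglog10p,
                               colour = .data$measure)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "ROI (AAL index)",
                  y = expression(-log[10](p)),
                  colour = "measure") +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of a cross-validated classifier
#'
#' @param object A `cv_report` from [nested_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot modality contribution ratios
#'
#' @param object A `contribution_result` from [contribution_ratios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.contribution_result <- function(object, ...) {
  df <- object[!is.na(object$ratio), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = expression(R^2 / R[fusion]^2)) +
    ggplot2::theme_minimal()
}
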