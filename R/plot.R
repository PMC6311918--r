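#' Plot a LOOCV ROC curve
#'
#' @param object An `lnc_loocv` result.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lnc_loocv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("LOOCV ROC (AUC = %.4f, %d folds)",
                                  object$auc, object$n_folds)) +
    ggplot2::theme_minimal()
}

#' Plot an alpha sweep
#'
#' @param object An `lnc_sweep` tibble from [lnc_alpha_sweep()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lnc_sweep <- function(object, ...) {
  best <- attr(object, "best_alpha")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha, y = .data$auc)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = "dotted") +
    ggplot2::labs(x = expression(alpha), y = "LOOCV AUC",
                  title = sprintf("Best alpha = %g", best)) +
    ggplot2::theme_minimal()
}

#' Heatmap of predicted association scores
#'
#' @param object An `lnc_scores` prediction tibble from [lnc_predict()].
#' @param ... Ignored.
#' @return A ggplot tile map with known associations outlined.
#' @exportS3Method ggplot2::autoplot
autoplot.lnc_scores <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lncrna, y = .data$disease,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$known == 1, ], fill = NA,
                       colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "lncRNA", y = "disease", fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
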