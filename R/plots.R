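# Report rendering: per-fold ROC curves with the mean curve and chance
# diagonal, confusion-matrix heatmap, and the agreement-threshold dual view.

#' ROC curves of a nested CV run
#'
#' One curve per outer fold plus the vertically averaged mean curve and the
#' chance diagonal; fold AUCs and the mean +/- sd AUC are shown in the
#' legend and subtitle.
#'
#' @param object A `nucleo_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nucleo_cv <- function(object, ...) {
  fold_pts <- dplyr::bind_rows(lapply(object$folds, function(f) {
    if (is.null(f$roc_points)) return(NULL)
    dplyr::mutate(f$roc_points,
                  fold = sprintf("fold %d (AUC %.2f)", f$fold_index, f$auc))
  }))
  grid_fpr <- seq(0, 1, by = 0.02)
  mean_tpr <- rowMeans(vapply(object$folds, function(f) {
    if (is.null(f$roc_points)) return(rep(NA_real_, length(grid_fpr)))
    approx(f$roc_points$fpr, f$roc_points$tpr, xout = grid_fpr,
           ties = "ordered", rule = 2)$y
  }, numeric(length(grid_fpr))), na.rm = TRUE)
  mean_df <- tibble::tibble(fpr = grid_fpr, tpr = mean_tpr)
  ggplot2::ggplot(fold_pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(ggplot2::aes(color = .data$fold), alpha = 0.7) +
    ggplot2::geom_line(data = mean_df, linewidth = 1.1, color = "black") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "red") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      color = NULL,
      title = "Nested cross-validation ROC (positive class: PTC-like)",
      subtitle = sprintf("mean AUC %.2f +/- %.2f", object$auc_mean, object$auc_sd)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of pooled nested CV predictions
#'
#' @param cv A `nucleo_cv`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cv) {
  df <- as.data.frame(cv$pooled_confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), color = "white",
                       size = 6) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$truth))) +
    ggplot2::scale_fill_gradient(low = "#4477aa", high = "#aa3344",
                                 guide = "none") +
    ggplot2::labs(title = "Pooled outer-fold confusion matrix",
                  x = "predicted", y = "truth") +
    ggplot2::theme_minimal()
}

#' Agreement-threshold curves (accuracy and subset size)
#'
#' Mirrors the minimal-pathologist-agreement analysis: the upper panel shows
#' classifier accuracy (when available), mean expert rating, and
#' distribution accuracy against the threshold; the lower panel the subset
#' composition.
#'
#' @param eval_tbl Output of [threshold_evaluation()].
#' @return A ggplot object (faceted dual panel).
#' @export
plot_agreement_curve <- function(eval_tbl) {
  acc_cols <- intersect(c("accuracy", "mean_c_i", "distribution_accuracy"),
                        names(eval_tbl))
  top <- tidyr::pivot_longer(eval_tbl[, c("threshold", acc_cols)],
                             -"threshold", names_to = "metric")
  top$panel <- "accuracy"
  bottom <- tidyr::pivot_longer(
    eval_tbl[, c("threshold", "n_ptc", "n_non_ptc")],
    -"threshold", names_to = "metric"
  )
  bottom$panel <- "subset size"
  df <- dplyr::bind_rows(top, bottom)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "minimal pathologist agreement level c_i",
                  y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
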