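#' Plot an evaluation report
#'
#' Confusion-matrix heat map (rows = truth, columns = predicted, counts
#' annotated), the orientation used in the package's reports.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- tidy(object$confusion)
  df$truth <- factor(df$truth, levels = rev(rownames(object$confusion)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "Predicted pathway", y = "True pathway",
      title = sprintf("BA = %.2f, MCC = %.2f", object$ba, object$mcc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a 2D embedding colored by a grouping
#'
#' @param embedding Tibble from [embed_2d()].
#' @param color Optional vector (e.g. labels or variants) to color points.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, color = NULL) {
  df <- as_tibble(embedding)
  if (!is.null(color)) df$group <- as.factor(color)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tsne1, y = .data$tsne2))
  if (!is.null(color)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 1.5)
  } else {
    p <- p + ggplot2::geom_point(size = 1.5)
  }
  p + ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot top feature importances
#'
#' @param model A tree-ensemble `path_model`.
#' @param top_n Number of residues to show; default 20.
#' @return A ggplot object.
#' @export
plot_importance <- function(model, top_n = 20) {
  imp <- head(feature_importance(model), top_n)
  imp$residue <- factor(imp$residue, levels = rev(imp$residue))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance, y = .data$residue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean decrease in impurity (normalized)", y = NULL) +
    ggplot2::theme_minimal()
}
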