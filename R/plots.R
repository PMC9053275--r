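#' Plot methods for result objects
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' the concordance histogram (agreement counts between two label sources),
#' the cohort sign-count histogram, the per-label metric forest with CIs,
#' and the embedding scatter colored by the 16-level anatomical color
#' index.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name radlabel-autoplot
NULL

# fixed 16-color legend for the 4-bit anatomical code
color_index_palette <- function() {
  setNames(grDevices::hcl.colors(16, "Spectral"), as.character(0:15))
}

#' @rdname radlabel-autoplot
#' @importFrom ggplot2 autoplot
#' @export
autoplot.concordance_result <- function(object, ...) {
  df <- mutate(object$histogram, pct = 100 * n / sum(n))
  ggplot2::ggplot(df, ggplot2::aes(x = n_agree, y = n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(
      xintercept = object$min_concordant - 0.5, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "concordant labels per subject", y = "subjects",
      title = sprintf(
        "%.1f%% of subjects concordant on ≥%d of %d labels",
        100 * object$fraction_at_least, object$min_concordant, object$n_labels
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname radlabel-autoplot
#' @export
autoplot.cohort_summary <- function(object, ...) {
  ggplot2::ggplot(object$sign_count_histogram, ggplot2::aes(x = n_signs, y = n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "abnormal signs per subject", y = "subjects") +
    ggplot2::theme_minimal()
}

#' @rdname radlabel-autoplot
#' @export
autoplot.metric_result <- function(object, ...) {
  df <- object %>%
    filter(!is.na(auc)) %>%
    mutate(label = stats::reorder(label, auc))
  ggplot2::ggplot(df, ggplot2::aes(x = auc, y = label)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$auc_low, xmax = .data$auc_high), height = 0.2
    ) +
    ggplot2::geom_point(color = "firebrick") +
    ggplot2::labs(x = "AUC (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname radlabel-autoplot
#' @export
autoplot.embedding_table <- function(object, ...) {
  if (all(is.na(object$x))) {
    abort("embedding table has no coordinates; supply them to export_embedding_table()")
  }
  df <- mutate(object, color_index = factor(color_index, levels = 0:15))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, color = color_index)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_color_manual(
      values = color_index_palette(), drop = FALSE, name = "color index"
    ) +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' Plot one label's empirical ROC curve
#'
#' @param scores Numeric scores for one label.
#' @param truth Binary truth (0/1).
#' @param label Optional title.
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, truth, label = NULL) {
  pts <- roc_curve_points(scores, truth)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = label,
      subtitle = sprintf("AUC = %.3f", suppressWarnings(auc_mann_whitney(scores, truth)))
    ) +
    ggplot2::theme_minimal()
}
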