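#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_abline geom_col
#'   geom_histogram geom_vline labs coord_equal theme_minimal
NULL

#' Plot a ROC curve
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_path(colour = "#2c7fb8", linewidth = 0.8) +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC curve (AUC = %.2f%%)", 100 * object$auc)) +
    theme_minimal()
}

#' Plot the out-of-fold ROC of a cross-validated consensus fit
#' @param object A `consensus_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot consensus_cv
#' @export
autoplot.consensus_cv <- function(object, ...) {
  autoplot(object$auc)
}

#' Plot the permutation-baseline AUC distribution
#' @param object A `permutation_baseline`.
#' @param real_auc Optional AUC of the real model, drawn as a second line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot permutation_baseline
#' @export
autoplot.permutation_baseline <- function(object, real_auc = NULL, ...) {
  p <- ggplot(tibble(auc = object$aucs), aes(x = .data$auc)) +
    geom_histogram(bins = 25, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$median_auc, colour = "#2c7fb8",
               linewidth = 0.8) +
    labs(x = "Permuted-label AUC", y = "Count",
         title = sprintf("Permutation baseline (median = %.2f%%)",
                         100 * object$median_auc)) +
    theme_minimal()
  if (!is.null(real_auc)) {
    p <- p + geom_vline(xintercept = real_auc, colour = "#d95f02",
                        linetype = "dashed", linewidth = 0.8)
  }
  p
}

#' Plot per-method consensus importances
#' @param object A `method_importance` tibble from [feature_importance()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot method_importance
#' @export
autoplot.method_importance <- function(object, ...) {
  df <- object[order(object$importance), ]
  df$method <- factor(df$method, levels = df$method)
  ggplot(df, aes(x = .data$importance, y = .data$method)) +
    geom_col(fill = "#2c7fb8") +
    labs(x = "Importance (0-100)", y = NULL,
         title = "Method importance in the consensus model") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
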