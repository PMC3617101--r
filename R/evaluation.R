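#' ROC curve and AUC against known-target labels
#'
#' Computes the receiver operating characteristic of a score vector against
#' binary labels. The AUC is the exact Mann-Whitney statistic,
#' `P(score_pos > score_neg) + 0.5 P(tie)`, and equals the trapezoidal area
#' under the returned curve; tied scores are collapsed into single curve
#' vertices so the trapezoids account for ties correctly.
#'
#' @param scores Numeric score vector (higher = more target-like).
#' @param labels 0/1 labels, same length; both classes must be present.
#' @return A `roc_result`: `$auc`, `$curve` (tibble `fpr`, `tpr` from (0,0)
#'   to (1,1)), `$n_pos`, `$n_neg`.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(scores) != length(y)) abort("scores/labels length mismatch.")
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC needs at least one positive and one negative.")
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  # one curve vertex per distinct threshold (tie group)
  grp_last <- !duplicated(ss, fromLast = TRUE)
  tpr <- c(0, cumsum(ys)[grp_last] / n_pos)
  fpr <- c(0, cumsum(1L - ys)[grp_last] / n_neg)
  auc <- auc_fast(scores, y)
  structure(
    list(auc = auc, curve = tibble(fpr = fpr, tpr = tpr),
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @method print roc_result
#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.2f%% (%d pos / %d neg)>\n",
              100 * x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

# trapezoidal area of the ROC polygon; equals the Mann-Whitney AUC
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1L) + curve$tpr[-1L]) / 2)
}

#' Bootstrap confidence interval for an AUC
#'
#' Percentile interval over node resamples (resamples with a single class
#' are redrawn).
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return A tibble with `auc`, `lower`, `upper`, `conf`.
#' @export
roc_auc_ci <- function(scores, labels, n_boot = 2000L, conf = 0.95,
                       seed = NULL) {
  y <- as.integer(labels)
  obs <- roc_auc(scores, y)$auc
  with_seed_(seed, {
    n <- length(y)
    boots <- vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
      }
      auc_fast(scores[idx], y[idx])
    }, numeric(1L))
    qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    tibble(auc = obs, lower = qs[1L], upper = qs[2L], conf = conf)
  })
}

#' Label-permutation baseline for the consensus model
#'
#' Estimates the imbalance-aware chance level of the full modeling
#' procedure: the known-target labels are randomly permuted (preserving the
#' number of positives), the complete stratified cross-validation is re-run,
#' and the out-of-fold AUC recorded, `n_perm` times. The median of these
#' AUCs is the baseline a real disease model must beat; in an unbalanced
#' setting it may differ from 50%.
#'
#' @param fm Feature tibble from [assemble_features()].
#' @param k Number of CV folds (default 5).
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param lambda_grid,n_boot Tuning settings, see [fit_logistic()].
#' @return A `permutation_baseline`: `$aucs` (length `n_perm`),
#'   `$median_auc`, `$n_perm`.
#' @export
permutation_baseline <- function(fm, k = 5L, n_perm = 100L, seed = NULL,
                                 lambda_grid = 10^seq(-4, 2), n_boot = 25L) {
  with_seed_(seed, {
    aucs <- vapply(seq_len(n_perm), function(p) {
      fm_perm <- fm
      fm_perm$label <- sample(fm$label)
      cross_validated_predict(fm_perm, k = k, seed = NULL,
                              lambda_grid = lambda_grid,
                              n_boot = n_boot)$auc$auc
    }, numeric(1L))
    structure(
      list(aucs = aucs, median_auc = median(aucs),
           n_perm = as.integer(n_perm)),
      class = "permutation_baseline"
    )
  })
}

#' @method print permutation_baseline
#' @export
print.permutation_baseline <- function(x, ...) {
  cat(sprintf("<permutation_baseline: median AUC %.2f%% over %d permutations>\n",
              100 * x$median_auc, x$n_perm))
  invisible(x)
}
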