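method_order <- c("propagation", "random_walk", "interconnectivity",
                  "neighborhood")

#' Assemble the node-by-method feature matrix for the consensus model
#'
#' Pivots the long score table into one row per network node with the four
#' method scores as columns (fixed order: propagation, random walk,
#' interconnectivity, neighborhood) and attaches the binary known-target
#' label. Nodes without a label entry default to 0 (negative). At least two
#' known targets are required as true positives for the regression model.
#'
#' @param scores Long tibble with columns `node`, `method`, `score` from
#'   [score_nodes()]; every method must cover the same node set.
#' @param labels A data frame with columns `node` and `label` (0/1), or a
#'   0/1 vector named by node.
#' @return A feature tibble: `node`, four score columns, `label`.
#' @export
assemble_features <- function(scores, labels) {
  methods <- unique(scores$method)
  missing <- setdiff(method_order, methods)
  if (length(missing) > 0L) {
    abort(sprintf("Missing score vectors for: %s",
                  paste(missing, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(scores, id_cols = "node",
                             names_from = "method", values_from = "score")
  if (anyNA(wide[method_order])) {
    abort("Score vectors cover different node sets.")
  }
  if (!all(vapply(wide[method_order], function(x) all(is.finite(x)), TRUE))) {
    abort("All scores must be finite.")
  }
  if (is.data.frame(labels)) {
    lab <- setNames(as.integer(labels$label), as.character(labels$node))
  } else {
    lab <- setNames(as.integer(labels), names(labels))
  }
  y <- unname(lab[wide$node])
  y[is.na(y)] <- 0L
  if (sum(y) < 2L) {
    abort("At least two known targets are required as true positives.")
  }
  out <- wide[, c("node", method_order)]
  out$label <- y
  out
}

#' Stratified fold assignment
#'
#' Randomly partitions nodes into `k` folds so that every node appears in
#' exactly one test fold and each fold's positive count differs from the
#' others by at most one, keeping the class proportions of each fold as close
#' as possible to those of the whole data set.
#'
#' @param labels 0/1 label vector.
#' @param k Number of folds (default 5).
#' @param seed Optional integer seed for reproducible assignment; `NULL`
#'   draws from the current RNG state.
#' @return Integer vector of fold indices in `1..k`, same length as
#'   `labels`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = NULL) {
  y <- as.integer(labels)
  n <- length(y)
  if (k < 2L) abort("`k` must be at least 2.")
  if (k > n) abort("`k` exceeds the number of nodes.")
  if (sum(y == 1L) < k) {
    warn("Fewer positives than folds; some folds will hold no positive.")
  }
  with_seed_(seed, {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
    fold
  })
}

standardize_features <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2L, sd)
  }
  usable <- scale > 0
  xs <- sweep(x, 2L, center, "-")
  xs[, usable] <- sweep(xs[, usable, drop = FALSE], 2L, scale[usable], "/")
  xs[, !usable] <- 0 # constant features carry no information; drop to 0
  list(x = xs, center = center, scale = scale, usable = usable)
}

# L2-penalized logistic regression over a decreasing lambda path (see
# src/ridge_logistic.cpp). Objective matches the standard scaling
# (1/n) * negloglik + lambda/2 * ||beta||^2, intercept unpenalized;
# x must already be standardized.
ridge_logistic_path <- function(x, y, lambdas) {
  .ridge_logistic_path_cpp(as.matrix(x), as.numeric(y), as.numeric(lambdas))
}

# rank-based Mann-Whitney AUC; midranks handle ties
auc_fast <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit one consensus logistic-regression model
#'
#' Fits an L2-penalized logistic regression of the known-target label on the
#' four standardized method scores. The penalty strength is selected from
#' `lambda_grid` by maximizing mean out-of-bag AUC over `n_boot` bootstrap
#' resamples of the training data; the final model is refit on all training
#' rows at the selected penalty. Coefficient z-statistics (for the
#' importance summary) come from an unpenalized refit on the same
#' standardized features.
#'
#' @param train A feature tibble (see [assemble_features()]) containing both
#'   classes.
#' @param lambda_grid Candidate L2 penalty strengths; default
#'   `10^(-4:2)`.
#' @param n_boot Number of bootstrap resamples for tuning (default 25).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A `consensus_model` with intercept, coefficients, standardization
#'   parameters, selected `lambda`, and per-feature z-statistics.
#' @export
fit_logistic <- function(train, lambda_grid = 10^seq(-4, 2),
                         n_boot = 25L, seed = NULL) {
  x <- as.matrix(train[, method_order])
  y <- as.integer(train$label)
  if (length(unique(y)) < 2L) {
    abort("Training fold contains a single class; cannot fit the model.")
  }
  with_seed_(seed, {
    std <- standardize_features(x)
    xs <- std$x
    grid <- sort(unique(lambda_grid), decreasing = TRUE)
    oob_auc <- matrix(NA_real_, nrow = n_boot, ncol = length(grid))
    n <- nrow(xs)
    for (b in seq_len(n_boot)) {
      for (try in 1:20) {
        in_bag <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), in_bag)
        if (length(unique(y[in_bag])) == 2L && length(oob) > 0L &&
            length(unique(y[oob])) == 2L) break
      }
      path <- ridge_logistic_path(xs[in_bag, , drop = FALSE], y[in_bag],
                                  grid)
      eta <- cbind(1, xs[oob, , drop = FALSE]) %*% path
      for (li in seq_along(grid)) {
        oob_auc[b, li] <- auc_fast(eta[, li], y[oob])
      }
    }
    mean_auc <- colMeans(oob_auc, na.rm = TRUE)
    best <- which.max(mean_auc) # ties resolve to the strongest penalty
    lambda <- grid[best]
    beta <- ridge_logistic_path(xs, y, grid)[, best]
    names(beta) <- c("(Intercept)", method_order)
    zstats <- glm_zstats(xs, y)
    structure(
      list(intercept = beta[[1L]], coefficients = beta[-1L],
           lambda = lambda, center = std$center, scale = std$scale,
           usable = std$usable, zstats = zstats,
           tuning = tibble(lambda = grid, mean_oob_auc = mean_auc)),
      class = "consensus_model"
    )
  })
}

glm_zstats <- function(xs, y) {
  df <- data.frame(y = y, xs)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = "binomial"))
  sm <- summary(fit)$coefficients
  z <- setNames(numeric(ncol(xs)), colnames(xs))
  rows <- intersect(rownames(sm), colnames(xs))
  z[rows] <- sm[rows, "z value"]
  z[!is.finite(z)] <- 0
  z
}

#' @method print consensus_model
#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("<consensus_model: lambda = %g>\n", x$lambda))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted target probability for new nodes
#' @param object A `consensus_model`.
#' @param newdata A feature tibble with the four method-score columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @method predict consensus_model
#' @export
predict.consensus_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, method_order])
  xs <- standardize_features(x, object$center, object$scale)$x
  eta <- object$intercept + as.numeric(xs %*% object$coefficients)
  1 / (1 + exp(-eta))
}

#' Cross-validated consensus prediction
#'
#' Runs stratified k-fold cross-validation: for each fold, a consensus model
#' is tuned and fitted on the other k-1 folds and predicts the held-out
#' nodes, so every node receives exactly one out-of-fold probability. The
#' aggregated predictions are ranked by descending probability with a
#' deterministic tie-break on node id.
#'
#' @param fm Feature tibble from [assemble_features()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed driving fold assignment and bootstrap tuning;
#'   `NULL` uses the current RNG state.
#' @param lambda_grid,n_boot Tuning settings, see [fit_logistic()].
#' @return A `consensus_cv` object: `$predictions` (tibble `node`,
#'   `probability`, `rank`, `known_target`, `fold`), `$models` (per-fold
#'   `consensus_model`s), `$auc` (out-of-fold [roc_auc()]), `$folds`.
#' @export
cross_validated_predict <- function(fm, k = 5L, seed = NULL,
                                    lambda_grid = 10^seq(-4, 2),
                                    n_boot = 25L) {
  with_seed_(seed, {
    fold <- stratified_folds(fm$label, k = k, seed = NULL)
    prob <- numeric(nrow(fm))
    models <- vector("list", k)
    for (f in seq_len(k)) {
      test <- fold == f
      models[[f]] <- fit_logistic(fm[!test, , drop = FALSE],
                                  lambda_grid = lambda_grid,
                                  n_boot = n_boot, seed = NULL)
      prob[test] <- predict(models[[f]], fm[test, , drop = FALSE])
    }
    ord <- order(-prob, fm$node)
    rank <- integer(nrow(fm))
    rank[ord] <- seq_len(nrow(fm))
    preds <- tibble(node = fm$node, probability = prob, rank = rank,
                    known_target = as.integer(fm$label), fold = fold)
    preds <- preds[ord, , drop = FALSE]
    structure(
      list(predictions = preds, models = models,
           auc = roc_auc(prob, fm$label), k = k),
      class = "consensus_cv"
    )
  })
}

#' @method print consensus_cv
#' @export
print.consensus_cv <- function(x, ...) {
  cat(sprintf("<consensus_cv: %d nodes, %d folds, out-of-fold AUC %.4f>\n",
              nrow(x$predictions), x$k, x$auc$auc))
  invisible(x)
}

#' Median out-of-fold AUC over repeated cross-validation
#'
#' Repeats the full stratified CV with independent fold assignments and
#' reports the per-repeat out-of-fold AUCs and their median, the headline
#' performance number for a disease.
#'
#' @inheritParams cross_validated_predict
#' @param repeats Number of CV repetitions (default 11).
#' @return A list with `aucs` (length `repeats`) and `median_auc`.
#' @export
repeated_cv_auc <- function(fm, k = 5L, repeats = 11L, seed = NULL,
                            lambda_grid = 10^seq(-4, 2), n_boot = 25L) {
  with_seed_(seed, {
    aucs <- vapply(seq_len(repeats), function(r) {
      cross_validated_predict(fm, k = k, seed = NULL,
                              lambda_grid = lambda_grid,
                              n_boot = n_boot)$auc$auc
    }, numeric(1L))
    list(aucs = aucs, median_auc = median(aucs))
  })
}

#' Per-method importance in the consensus model
#'
#' Summarizes how much each scoring method contributes to the fused
#' prediction: the mean absolute coefficient z-statistic across the
#' cross-validation folds, affinely rescaled so the most important method
#' reads 100 and the least important 0. If all methods tie, all read 100.
#'
#' @param x A `consensus_cv` object or a list of `consensus_model`s.
#' @return A `method_importance` tibble with columns `method`, `importance`
#'   (in `[0, 100]`).
#' @export
feature_importance <- function(x) {
  models <- if (inherits(x, "consensus_cv")) x$models else x
  stopifnot(length(models) >= 1L)
  z <- vapply(models, function(m) abs(m$zstats), numeric(length(method_order)))
  raw <- rowMeans(matrix(z, nrow = length(method_order),
                         dimnames = list(method_order, NULL)))
  rng <- range(raw)
  imp <- if (diff(rng) == 0) rep(100, length(raw)) else
    (raw - rng[1L]) / diff(rng) * 100
  out <- tibble(method = method_order, importance = unname(imp))
  class(out) <- c("method_importance", class(out))
  out
}

#' Tidy the per-fold consensus coefficients
#' @param x A `consensus_cv` object.
#' @param ... Unused.
#' @return A tibble with columns `fold`, `term`, `estimate`, `z`.
#' @method tidy consensus_cv
#' @export
tidy.consensus_cv <- function(x, ...) {
  purrr::map_dfr(seq_along(x$models), function(f) {
    m <- x$models[[f]]
    tibble(fold = f,
           term = c("(Intercept)", method_order),
           estimate = c(m$intercept, unname(m$coefficients)),
           z = c(NA_real_, unname(m$zstats)))
  })
}

#' One-row summary of a cross-validated consensus fit
#' @param x A `consensus_cv` object.
#' @param ... Unused.
#' @return A tibble with `n`, `n_pos`, `k`, `auc`, `median_lambda`.
#' @method glance consensus_cv
#' @export
glance.consensus_cv <- function(x, ...) {
  tibble(n = nrow(x$predictions),
         n_pos = sum(x$predictions$known_target),
         k = x$k,
         auc = x$auc$auc,
         median_lambda = median(vapply(x$models, `[[`, 1, "lambda")))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
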