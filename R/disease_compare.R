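#' Jaccard distance between two gene sets
#'
#' `1 - |a n b| / |a u b|`; 0 for identical sets, 1 for disjoint ones.
#' Errors when both sets are empty (the overlap is undefined).
#'
#' @param a,b Character vectors (treated as sets).
#' @return A number in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) abort("Jaccard distance is undefined for two empty sets.")
  1 - length(intersect(a, b)) / u
}

#' Pairwise Jaccard distance matrix over diseases
#'
#' Builds the disease-by-disease distance matrix from per-disease gene sets
#' (differentially expressed genes, or the top-k predicted targets from
#' [top_k_nodes()]).
#'
#' @param sets Named list of character vectors, one per disease; every set
#'   must be non-empty and at least two diseases are required.
#' @return A symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = disease names.
#' @export
build_distance_matrix <- function(sets) {
  if (length(sets) < 2L) abort("Need at least two diseases.")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list.")
  }
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty)) {
    abort(sprintf("Empty gene set for disease(s): %s",
                  paste(names(sets)[empty], collapse = ", ")))
  }
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- jaccard_distance(sets[[i]], sets[[j]])
    }
  }
  d
}

#' Top-k predicted nodes of a ranked prediction list
#'
#' @param predictions A prediction tibble (from
#'   [cross_validated_predict()]`$predictions`) with columns `node`, `rank`.
#' @param k Number of top-ranked nodes to keep (default 100, the convention
#'   for disease-similarity comparison of predicted targets).
#' @return Character vector of the k best-ranked node ids.
#' @export
top_k_nodes <- function(predictions, k = 100L) {
  predictions$node[predictions$rank <= k]
}

#' Complete-linkage hierarchical clustering of diseases
#'
#' Agglomerative clustering of the distance matrix with complete linkage
#' (cluster distance = maximum pairwise distance). Input order of the labels
#' breaks ties deterministically.
#'
#' @param d A symmetric distance matrix (see [build_distance_matrix()]).
#' @param linkage Linkage method, default `"complete"`.
#' @return An [stats::hclust] merge tree.
#' @export
hierarchical_cluster <- function(d, linkage = "complete") {
  check_distance_matrix(d)
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Write a merge tree in Newick format
#' @param hc An [stats::hclust] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("write_newick requires the ape package.")
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

check_distance_matrix <- function(d, name = "d") {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0)) {
    abort(sprintf("`%s` must be symmetric with zero diagonal.", name))
  }
  invisible(d)
}

#' Mantel test between two disease distance matrices
#'
#' Pearson correlation between the strictly-upper-triangle entries of the
#' two matrices, with significance from jointly permuting the rows and
#' columns of the second matrix. The test is one-sided (greater), matching
#' the hypothesis that similarity at one level (e.g. expression signatures)
#' predicts similarity at the other (e.g. predicted targets); the p-value
#' uses the add-one convention `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`
#' so it can never be exactly zero.
#'
#' @param d1,d2 Symmetric distance matrices with identical dimnames in the
#'   same order.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed for reproducible permutations.
#' @return A `mantel_result`: `$r`, `$p`, `$n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 1000L, seed = NULL) {
  check_distance_matrix(d1, "d1")
  check_distance_matrix(d2, "d2")
  if (!identical(dim(d1), dim(d2)) ||
      !identical(rownames(d1), rownames(d2))) {
    abort("`d1` and `d2` must share the same labels in the same order.")
  }
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  v2 <- d2[ut]
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("Zero variance in a distance matrix; correlation undefined.")
  }
  r_obs <- stats::cor(v1, v2)
  n <- nrow(d1)
  r_perm <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(n)
      stats::cor(v1, d2[idx, idx][ut])
    }, numeric(1L))
  })
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  structure(
    list(r = r_obs, p = p, n_perm = as.integer(n_perm)),
    class = "mantel_result"
  )
}

#' @method print mantel_result
#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result: r = %.4f, p = %.4g (%d permutations)>\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}
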