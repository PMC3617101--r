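#' Neighborhood scoring
#'
#' Local guilt-by-association score: a node's score depends equally on its own
#' fold-change weight and on the average weight of its direct neighbors,
#' `s(i) = 0.5 FC(i) + 0.5 mean_{n in N(i)} FC(n)`. Nodes that are not
#' differentially expressed and have no differentially expressed neighbor
#' score exactly 0; an empty neighborhood contributes 0 for the second term.
#'
#' @param net An `interaction_network`.
#' @param signal A seed-signal tibble from [map_signature_to_network()]
#'   (columns `node`, `weight`, `is_deg`) covering every network node.
#' @return A tibble with columns `node`, `score`.
#' @export
neighborhood_score <- function(net, signal) {
  w <- signal_weights(net, signal)
  adj <- build_adjacency(net)
  deg <- Matrix::colSums(adj)
  nb_mean <- as.numeric(adj %*% w)
  nb_mean[deg > 0] <- nb_mean[deg > 0] / deg[deg > 0]
  nb_mean[deg == 0] <- 0
  tibble(node = net$nodes, score = 0.5 * w + 0.5 * nb_mean)
}

#' Pairwise interconnectivity score
#'
#' Combines the direct edge indicator and the size of the shared neighborhood
#' of two nodes, normalized by their degrees:
#' `ICN(i,j) = (e(i,j) + |N(i) \eqn{\cap}{ & } N(j)|) / sqrt(deg(i) deg(j))`
#' under the default geometric normalization, or with denominator
#' `(deg(i) + deg(j)) / 2` under `normalization = "mean_degree"`. Pairs
#' involving a degree-0 node score 0.
#'
#' @param net An `interaction_network`.
#' @param i,j Distinct node identifiers.
#' @param normalization `"geometric"` (default) or `"mean_degree"`.
#' @return A single numeric score.
#' @export
interconnectivity_pair <- function(net, i, j,
                                   normalization = c("geometric",
                                                     "mean_degree")) {
  normalization <- match.arg(normalization)
  if (identical(i, j)) abort("interconnectivity_pair requires i != j.")
  ni <- network_neighbors(net, i)
  nj <- network_neighbors(net, j)
  if (length(ni) == 0L || length(nj) == 0L) return(0)
  num <- as.numeric(j %in% ni) + length(intersect(ni, nj))
  den <- switch(normalization,
    geometric = sqrt(length(ni) * length(nj)),
    mean_degree = (length(ni) + length(nj)) / 2
  )
  num / den
}

#' Interconnectivity scores against the DEG set
#'
#' Each node's score is the sum of its pairwise interconnectivity to every
#' differentially expressed node (excluding itself when it is a DEG). Shared
#' neighbor counts are the entries of the squared adjacency, so the whole
#' vector comes from two sparse products restricted to the DEG columns.
#'
#' @param net An `interaction_network`.
#' @param deg_nodes Character vector of differentially expressed node ids
#'   (non-empty).
#' @inheritParams interconnectivity_pair
#' @return A tibble with columns `node`, `score`.
#' @export
interconnectivity_score <- function(net, deg_nodes,
                                    normalization = c("geometric",
                                                      "mean_degree")) {
  normalization <- match.arg(normalization)
  deg_nodes <- check_seeds(net, deg_nodes)
  adj <- build_adjacency(net)
  deg <- Matrix::colSums(adj)
  d_idx <- match(deg_nodes, net$nodes)
  # e(i,d) + |N(i) & N(d)| for all i at once; diag(A^2) = deg supplies the
  # excluded d == i term, which normalizes to exactly 1 under both schemes
  m <- adj[, d_idx, drop = FALSE] + adj %*% adj[, d_idx, drop = FALSE]
  if (normalization == "geometric") {
    inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    scaled <- Matrix::Diagonal(x = inv_sqrt) %*% m %*%
      Matrix::Diagonal(x = inv_sqrt[d_idx])
    score <- as.numeric(Matrix::rowSums(scaled))
  } else {
    trip <- Matrix::summary(as(m, "TsparseMatrix"))
    di <- deg[trip$i]
    dj <- deg[d_idx[trip$j]]
    val <- ifelse(di > 0 & dj > 0, trip$x * 2 / (di + dj), 0)
    score <- as.numeric(tapply(val, factor(trip$i, levels = seq_along(deg)),
                               sum, default = 0))
  }
  is_seed <- net$nodes %in% deg_nodes
  score[is_seed & deg > 0] <- score[is_seed & deg > 0] - 1
  score[deg == 0] <- 0
  tibble(node = net$nodes, score = score)
}

#' Diffusion configuration helper
#'
#' @param alpha Restart/smoothing weight in (0,1); default 0.5.
#' @param tol L1 convergence tolerance; default 1e-6.
#' @param max_iter Iteration cap; default 10000.
#' @return A list with the validated fields.
#' @export
diffusion_config <- function(alpha = 0.5, tol = 1e-6, max_iter = 10000L) {
  stopifnot_scalar_prob(alpha, "alpha")
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be > 0.")
  if (!is.numeric(max_iter) || max_iter < 1) abort("`max_iter` must be >= 1.")
  list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter))
}

signal_weights <- function(net, signal) {
  if (!all(c("node", "weight") %in% names(signal))) {
    abort("`signal` must have columns node, weight (see map_signature_to_network).")
  }
  idx <- match(net$nodes, signal$node)
  if (anyNA(idx)) abort("`signal` must cover every network node.")
  signal$weight[idx]
}

check_seeds <- function(net, seeds) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) {
    abort("At least one differentially expressed node is required as seed.")
  }
  missing <- setdiff(seeds, net$nodes)
  if (length(missing) > 0L) {
    abort(sprintf("Seed node(s) not in network: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  seeds
}

seed_vector <- function(net, seeds, value) {
  v <- numeric(length(net$nodes))
  v[match(seeds, net$nodes)] <- value
  v
}

#' Random walk with restart
#'
#' Iterates the visitation probabilities
#' `P_{t+1} = (1 - alpha) A' P_t + alpha P_0` on the column-stochastic
#' adjacency `A'`, starting from the uniform distribution over the seed
#' (differentially expressed) nodes. Mass sitting on dangling (degree-0)
#' nodes is redirected to the restart vector each iteration so the update
#' stays stochastic; the iteration stops when the L1 change drops below
#' `tol`. The returned scores are a probability vector (sum 1).
#'
#' @param net An `interaction_network`.
#' @param seeds Character vector of seed node ids (non-empty).
#' @param alpha Restart probability in (0,1).
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   last residual.
#' @param trace If `TRUE`, the per-iteration total probability mass is
#'   attached to the result as attribute `"mass"`.
#' @return A tibble with columns `node`, `score`.
#' @export
random_walk <- function(net, seeds, alpha = 0.5, tol = 1e-6,
                        max_iter = 10000L, trace = FALSE) {
  cfg <- diffusion_config(alpha, tol, max_iter)
  seeds <- check_seeds(net, seeds)
  norm <- normalize_stochastic(build_adjacency(net))
  p0 <- seed_vector(net, seeds, 1 / length(seeds))
  dangling <- unname(norm$dangling)
  p <- p0
  mass <- if (trace) numeric(0)
  for (it in seq_len(cfg$max_iter)) {
    dangling_mass <- sum(p[dangling])
    p_new <- (1 - cfg$alpha) * (as.numeric(norm$matrix %*% p) +
                                  dangling_mass * p0) + cfg$alpha * p0
    resid <- sum(abs(p_new - p))
    p <- p_new
    if (trace) mass <- c(mass, sum(p))
    if (resid < cfg$tol) {
      out <- tibble(node = net$nodes, score = p)
      if (trace) attr(out, "mass") <- mass
      return(out)
    }
  }
  abort(sprintf("Random walk did not converge in %d iterations (L1 = %.3g).",
                cfg$max_iter, resid))
}

#' Network propagation
#'
#' Smooths the binary DEG prior over the network:
#' `F_{t+1} = alpha A' F_t + (1 - alpha) F_0` with `A'` the symmetric
#' degree-normalized adjacency and `F_0(i) = 1` for seed nodes, 0 elsewhere.
#' Terminates when the L1 norm of the change drops below `tol` (default
#' 1e-6).
#'
#' @inheritParams random_walk
#' @return A tibble with columns `node`, `score`.
#' @export
network_propagation <- function(net, seeds, alpha = 0.5, tol = 1e-6,
                                max_iter = 10000L) {
  cfg <- diffusion_config(alpha, tol, max_iter)
  seeds <- check_seeds(net, seeds)
  norm <- normalize_symmetric(build_adjacency(net))
  f0 <- seed_vector(net, seeds, 1)
  f <- f0
  for (it in seq_len(cfg$max_iter)) {
    f_new <- cfg$alpha * as.numeric(norm$matrix %*% f) + (1 - cfg$alpha) * f0
    resid <- sum(abs(f_new - f))
    f <- f_new
    if (resid < cfg$tol) {
      return(tibble(node = net$nodes, score = f))
    }
  }
  abort(sprintf("Propagation did not converge in %d iterations (L1 = %.3g).",
                cfg$max_iter, resid))
}

#' Exact fixed points of the diffusion methods
#'
#' Solves the linear systems whose fixed points the iterative methods
#' approximate: `P* = alpha (I - (1-alpha) A')^{-1} P_0` for the random walk
#' (with dangling mass folded into the restart term) and
#' `F* = (1-alpha) (I - alpha A')^{-1} F_0` for propagation. Intended as a
#' dense-solve oracle for small networks.
#'
#' @inheritParams random_walk
#' @param method `"random_walk"` or `"propagation"`.
#' @return A tibble with columns `node`, `score`.
#' @export
diffusion_exact <- function(net, seeds, alpha = 0.5,
                            method = c("random_walk", "propagation")) {
  method <- match.arg(method)
  stopifnot_scalar_prob(alpha, "alpha")
  seeds <- check_seeds(net, seeds)
  n <- length(net$nodes)
  if (n > 5000L) abort("diffusion_exact is guarded to networks <= 5000 nodes.")
  adj <- build_adjacency(net)
  if (method == "random_walk") {
    norm <- normalize_stochastic(adj)
    p0 <- seed_vector(net, seeds, 1 / length(seeds))
    a <- as.matrix(norm$matrix)
    # dangling columns restart: effective transition A' + p0 %*% t(1_dangling)
    if (any(norm$dangling)) {
      a <- a + p0 %*% t(as.numeric(norm$dangling))
    }
    lhs <- diag(n) - (1 - alpha) * a
    score <- alpha * solve(lhs, p0)
  } else {
    norm <- normalize_symmetric(adj)
    f0 <- seed_vector(net, seeds, 1)
    lhs <- diag(n) - alpha * as.matrix(norm$matrix)
    score <- (1 - alpha) * solve(lhs, f0)
  }
  tibble(node = net$nodes, score = as.numeric(score))
}

#' Score every network node with the four prioritization methods
#'
#' Runs neighborhood scoring, interconnectivity, random walk with restart,
#' and network propagation from one seed signal and returns the scores in
#' long form, ready for [assemble_features()].
#'
#' @param net An `interaction_network`.
#' @param signal Seed-signal tibble from [map_signature_to_network()].
#' @param methods Subset of
#'   `c("neighborhood", "interconnectivity", "random_walk", "propagation")`.
#' @param alpha,tol,max_iter Diffusion settings, see [random_walk()].
#' @param normalization Interconnectivity normalization, see
#'   [interconnectivity_pair()].
#' @return A tibble with columns `node`, `method`, `score`.
#' @export
score_nodes <- function(net, signal,
                        methods = c("neighborhood", "interconnectivity",
                                    "random_walk", "propagation"),
                        alpha = 0.5, tol = 1e-6, max_iter = 10000L,
                        normalization = "geometric") {
  methods <- match.arg(methods, several.ok = TRUE)
  seeds <- signal$node[signal$is_deg]
  one <- function(m) {
    s <- switch(m,
      neighborhood = neighborhood_score(net, signal),
      interconnectivity = interconnectivity_score(net, seeds, normalization),
      random_walk = random_walk(net, seeds, alpha, tol, max_iter),
      propagation = network_propagation(net, seeds, alpha, tol, max_iter)
    )
    tibble(node = s$node, method = m, score = s$score)
  }
  dplyr::bind_rows(lapply(methods, one))
}
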