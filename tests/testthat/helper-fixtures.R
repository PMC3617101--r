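# Small graphs used across tests
path_net <- function() {
  as_interaction_network(data.frame(from = c("A", "B"), to = c("B", "C")))
}

star_net <- function() {
  # center "c" with leaves l1..l3
  as_interaction_network(data.frame(from = "c", to = c("l1", "l2", "l3")))
}

# uniformly random simple graph; optionally guarantees >= 1 edge
random_net <- function(n, p_edge = 0.3, isolated = 0L) {
  pairs <- t(combn(n, 2))
  repeat {
    keep <- runif(nrow(pairs)) < p_edge
    if (any(keep)) break
  }
  ids <- sprintf("v%02d", seq_len(n + isolated))
  as_interaction_network(
    data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]]),
    nodes = ids
  )
}

make_signal <- function(net, deg_nodes, weight = 1) {
  tibble::tibble(
    node = network_nodes(net),
    weight = ifelse(network_nodes(net) %in% deg_nodes, weight, 0),
    is_deg = network_nodes(net) %in% deg_nodes
  )
}

# Independent oracles, deliberately naive -----------------------------------

# per-node loop over explicit neighbor sets
brute_neighborhood <- function(net, signal) {
  w <- setNames(signal$weight, signal$node)
  vapply(network_nodes(net), function(i) {
    nb <- network_neighbors(net, i)
    second <- if (length(nb) == 0) 0 else mean(w[nb])
    0.5 * w[[i]] + 0.5 * second
  }, numeric(1))
}

# set-arithmetic pairwise score, double loop over DEGs
brute_interconnectivity <- function(net, deg_nodes,
                                    normalization = "geometric") {
  nodes <- network_nodes(net)
  nb <- lapply(nodes, function(i) network_neighbors(net, i))
  names(nb) <- nodes
  vapply(nodes, function(i) {
    s <- 0
    for (d in setdiff(deg_nodes, i)) {
      di <- length(nb[[i]]); dd <- length(nb[[d]])
      if (di == 0 || dd == 0) next
      num <- as.numeric(d %in% nb[[i]]) + length(intersect(nb[[i]], nb[[d]]))
      den <- if (normalization == "geometric") sqrt(di * dd) else
        (di + dd) / 2
      s <- s + num / den
    }
    s
  }, numeric(1))
}

# toy expression with planted log2 shifts (cases minus controls)
planted_expression <- function(n_genes = 20, planted = 1:5, shift = 2,
                               sd = 0.1, n_per_group = 10) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- c(sprintf("case_%02d", seq_len(n_per_group)),
               sprintf("ctrl_%02d", seq_len(n_per_group)))
  mu <- matrix(7, n_genes, 2 * n_per_group)
  mu[planted, seq_len(n_per_group)] <- 7 + shift
  vals <- mu + matrix(rnorm(n_genes * 2 * n_per_group, 0, sd), n_genes)
  colnames(vals) <- samples
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes),
                           tibble::as_tibble(vals))
  groups <- tibble::tibble(sample = samples,
                           group = rep(c("case", "control"),
                                       each = n_per_group))
  list(expression = expr, groups = groups, planted = genes[planted])
}

# a feature matrix with one informative feature and noise features
toy_feature_matrix <- function(n = 200, n_pos = 20, informative = "propagation",
                               strength = 2) {
  nodes <- sprintf("n%03d", seq_len(n))
  y <- as.integer(seq_len(n) <= n_pos)
  fm <- tibble::tibble(node = nodes)
  for (m in c("propagation", "random_walk", "interconnectivity",
              "neighborhood")) {
    fm[[m]] <- rnorm(n) + if (m == informative) strength * y else 0
  }
  fm$label <- y
  fm[sample.int(n), ]
}
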