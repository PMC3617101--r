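#' Define a synthetic benchmark scenario
#'
#' Bundles the parameters of the synthetic study conditions: a scale-free
#' interaction network, a planted set of true targets, and case/control
#' expression in which the differential signal is concentrated in the
#' network neighborhood of the targets. The defaults are the benchmark
#' conditions used throughout the package: a 2000-node preferential-
#' attachment network (m = 2), 20 planted targets, a 2.0 log2-unit effect
#' decaying over 2 hops, per-sample noise sd 0.25, and 10 case vs 10
#' control samples. Targets themselves are shifted only with probability
#' 0.3, reflecting that most known drug targets are not differentially
#' expressed in the disease they treat.
#'
#' @param n_nodes Number of network nodes.
#' @param m Preferential-attachment parameter (edges added per new node).
#' @param n_targets Number of planted targets (at least 2, matching the
#'   minimum positive count the consensus model needs).
#' @param n_case,n_control Samples per group.
#' @param effect_size Log2 expression shift at the targets' neighbors
#'   (decays as `effect_size * 2^-hops`).
#' @param noise_sd Per-sample Gaussian noise sd on the log2 scale.
#' @param hops Diffusion depth of the planted signal (>= 1).
#' @param target_deg_prob Probability that a target itself receives the
#'   full shift (default 0.3).
#' @param seed Integer seed; all generators are bit-reproducible under it.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_nodes = 2000L, m = 2L, n_targets = 20L,
                               n_case = 10L, n_control = 10L,
                               effect_size = 2, noise_sd = 0.25,
                               hops = 2L, target_deg_prob = 0.3,
                               seed = 1L) {
  if (n_targets < 2L) abort("`n_targets` must be at least 2.")
  if (effect_size < 0 || noise_sd <= 0) {
    abort("`effect_size` must be >= 0 and `noise_sd` > 0.")
  }
  if (hops < 1L) abort("`hops` must be >= 1.")
  if (n_nodes <= m || m < 1L) abort("Require n_nodes > m >= 1.")
  structure(
    list(n_nodes = as.integer(n_nodes), m = as.integer(m),
         n_targets = as.integer(n_targets), n_case = as.integer(n_case),
         n_control = as.integer(n_control), effect_size = effect_size,
         noise_sd = noise_sd, hops = as.integer(hops),
         target_deg_prob = target_deg_prob, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' Generate a scale-free interaction network
#'
#' Preferential-attachment (Barabasi-Albert) graph: connected, simple, with
#' the heavy-tailed degree distribution typical of curated interaction
#' networks.
#'
#' @param scenario A [synthetic_scenario()].
#' @return An `interaction_network` with nodes named `g0001`, `g0002`, ...
#' @export
generate_network <- function(scenario) {
  with_seed_(scenario$seed, {
    g <- igraph::sample_pa(scenario$n_nodes, power = 1, m = scenario$m,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    width <- nchar(as.character(scenario$n_nodes))
    ids <- sprintf(paste0("g%0", width, "d"), seq_len(scenario$n_nodes))
    as_interaction_network(
      tibble(from = ids[el[, 1L]], to = ids[el[, 2L]]),
      nodes = ids
    )
  })
}

#' Plant the true-target set
#'
#' Uniform sample of `n_targets` nodes without replacement, excluding
#' degree-0 nodes (an unreachable target could never be recovered by any
#' network method).
#'
#' @param net An `interaction_network`.
#' @param scenario A [synthetic_scenario()].
#' @return Character vector of target node ids.
#' @export
plant_targets <- function(net, scenario) {
  deg <- network_degrees(net)
  eligible <- deg$node[deg$degree > 0L]
  if (scenario$n_targets > length(eligible)) {
    abort("More targets requested than connected nodes available.")
  }
  with_seed_(scenario$seed + 1L, {
    sort(sample(eligible, scenario$n_targets))
  })
}

#' Generate case/control expression around the planted targets
#'
#' One gene per network node. Baseline log2 expression is N(7, 1) per gene;
#' genes within `hops` of a target have their case-group mean shifted by
#' `effect_size * 2^-d` where `d` is the hop distance to the nearest
#' target. Targets themselves (d = 0) are shifted with probability
#' `target_deg_prob` only, so recovery must come from network proximity,
#' not from the targets' own expression. Gaussian noise of sd `noise_sd`
#' is added per sample.
#'
#' @param net An `interaction_network`.
#' @param targets Planted target ids from [plant_targets()].
#' @param scenario A [synthetic_scenario()].
#' @return A list with `expression` (tibble: `gene` + one column per
#'   sample), and `groups` (tibble: `sample`, `group`).
#' @export
generate_expression <- function(net, targets, scenario) {
  nodes <- net$nodes
  n <- length(nodes)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = nodes)
  hop <- suppressWarnings(
    apply(igraph::distances(g, v = targets), 2L, min)
  )[nodes]
  with_seed_(scenario$seed + 2L, {
    shift <- ifelse(is.finite(hop) & hop >= 1 & hop <= scenario$hops,
                    scenario$effect_size * 2^(-hop), 0)
    self_hit <- stats::runif(n) < scenario$target_deg_prob
    shift[hop == 0] <- ifelse(self_hit[hop == 0], scenario$effect_size, 0)
    samples <- c(sprintf("case_%02d", seq_len(scenario$n_case)),
                 sprintf("ctrl_%02d", seq_len(scenario$n_control)))
    group <- rep(c("case", "control"), c(scenario$n_case, scenario$n_control))
    baseline <- stats::rnorm(n, mean = 7, sd = 1)
    mu <- outer(baseline, rep(1, length(samples))) +
      outer(shift, as.numeric(group == "case"))
    vals <- mu + matrix(stats::rnorm(n * length(samples), 0, scenario$noise_sd),
                        nrow = n)
    colnames(vals) <- samples
    expr <- dplyr::bind_cols(tibble(gene = nodes), as_tibble(vals))
    list(expression = expr, groups = tibble(sample = samples, group = group))
  })
}

#' Simulate a complete synthetic disease data set
#'
#' Convenience wrapper chaining [generate_network()], [plant_targets()] and
#' [generate_expression()]; also returns the 0/1 target label table used to
#' train and evaluate the consensus model.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with `scenario`, `network`, `targets`, `expression`,
#'   `groups`, `labels` (tibble `node`, `label`).
#' @export
simulate_disease <- function(scenario = synthetic_scenario()) {
  net <- generate_network(scenario)
  targets <- plant_targets(net, scenario)
  ex <- generate_expression(net, targets, scenario)
  list(scenario = scenario, network = net, targets = targets,
       expression = ex$expression, groups = ex$groups,
       labels = tibble(node = net$nodes,
                       label = as.integer(net$nodes %in% targets)))
}
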