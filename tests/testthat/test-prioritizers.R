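test_that("neighborhood scoring matches its hand-evaluated cases", {
  net <- path_net()
  signal <- make_signal(net, "A", weight = 2)
  s <- neighborhood_score(net, signal)
  expect_equal(s$score[s$node == "B"], 0.5) # 0.5*0 + 0.5*(2+0)/2
  expect_equal(s$score[s$node == "A"], 1.0) # 0.5*2 + 0.5*0
  expect_equal(s$score[s$node == "C"], 0.0) # no DEG self or neighbor

  iso <- as_interaction_network(data.frame(from = "A", to = "B"),
                                nodes = c("A", "B", "Z"))
  s2 <- neighborhood_score(iso, make_signal(iso, "Z", weight = 3))
  expect_equal(s2$score[s2$node == "Z"], 1.5) # empty neighborhood term is 0
})

test_that("pairwise interconnectivity matches hand evaluation", {
  # square with diagonal: A-B adjacent, deg 2 each, one shared neighbor C
  net <- as_interaction_network(
    data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"))
  )
  expect_equal(interconnectivity_pair(net, "A", "B"), (1 + 1) / sqrt(2 * 2))

  st <- star_net()
  expect_equal(interconnectivity_pair(st, "c", "l1"), 1 / sqrt(3))
  expect_equal(interconnectivity_pair(st, "l1", "c",
                                      normalization = "mean_degree"),
               1 / 2)
  # non-adjacent, no shared neighbors
  two <- as_interaction_network(data.frame(from = c("A", "C"),
                                           to = c("B", "D")))
  expect_equal(interconnectivity_pair(two, "A", "C"), 0)
  expect_error(interconnectivity_pair(net, "A", "A"), "i != j")
})

test_that("interconnectivity score equals the brute-force DEG sum", {
  net <- as_interaction_network(
    data.frame(from = c("A", "A", "B", "C", "D"),
               to = c("B", "C", "C", "D", "E"))
  )
  degs <- c("A", "E")
  s <- interconnectivity_score(net, degs)
  expect_equal(s$score, unname(brute_interconnectivity(net, degs)))
  # single DEG adjacent to a node: score equals the pair score
  s1 <- interconnectivity_score(net, "A")
  expect_equal(s1$score[s1$node == "B"],
               interconnectivity_pair(net, "B", "A"))
  expect_error(interconnectivity_score(net, character(0)), "At least one")
})

test_that("both interconnectivity normalizations match brute force on random graphs", {
  withr::with_seed(5, {
    for (i in 1:15) {
      net <- random_net(sample(5:10, 1), p_edge = 0.35,
                        isolated = sample(0:1, 1))
      nodes <- network_nodes(net)
      degs <- sample(nodes, sample(1:3, 1))
      for (nrm in c("geometric", "mean_degree")) {
        expect_equal(interconnectivity_score(net, degs, nrm)$score,
                     unname(brute_interconnectivity(net, degs, nrm)),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("neighborhood scores match brute force on random graphs", {
  withr::with_seed(6, {
    for (i in 1:15) {
      net <- random_net(sample(5:10, 1), isolated = sample(0:1, 1))
      nodes <- network_nodes(net)
      signal <- make_signal(net, sample(nodes, 2), weight = runif(1, 1, 3))
      expect_equal(neighborhood_score(net, signal)$score,
                   unname(brute_neighborhood(net, signal)),
                   tolerance = 1e-12)
    }
  })
})

test_that("random walk agrees with symmetry, restart limit, and exact solve", {
  two <- as_interaction_network(data.frame(from = "X", to = "Y"))
  rw <- random_walk(two, c("X", "Y"), alpha = 0.37)
  expect_equal(rw$score, c(0.5, 0.5), tolerance = 1e-9)

  # restart-dominated limit returns the seed distribution
  st <- star_net()
  rw2 <- random_walk(st, "l1", alpha = 0.999)
  expect_equal(rw2$score[rw2$node == "l1"], 1, tolerance = 1e-2)

  withr::with_seed(8, {
    net <- random_net(6, p_edge = 0.5)
    seeds <- network_nodes(net)[1:2]
    it <- random_walk(net, seeds, alpha = 0.5)
    ex <- diffusion_exact(net, seeds, alpha = 0.5, method = "random_walk")
    expect_lt(sum(abs(it$score - ex$score)), 1e-6)
    expect_equal(sum(it$score), 1, tolerance = 1e-9)
  })
})

test_that("random walk redirects dangling mass and stays stochastic", {
  net <- as_interaction_network(data.frame(from = "A", to = "B"),
                                nodes = c("A", "B", "Z"))
  rw <- random_walk(net, c("A", "Z"), alpha = 0.4, trace = TRUE)
  expect_equal(sum(rw$score), 1, tolerance = 1e-9)
  expect_equal(attr(rw, "mass"), rep(1, length(attr(rw, "mass"))),
               tolerance = 1e-9)
  ex <- diffusion_exact(net, c("A", "Z"), alpha = 0.4,
                        method = "random_walk")
  expect_lt(sum(abs(rw$score - ex$score)), 1e-6)
})

test_that("propagation matches hand algebra, exact solve, and its limits", {
  # single edge, one seed, alpha = 0.5: F* = (2/3, 1/3) from the 2x2 system
  two <- as_interaction_network(data.frame(from = "X", to = "Y"))
  pr <- network_propagation(two, "X", alpha = 0.5)
  expect_equal(pr$score, c(2 / 3, 1 / 3), tolerance = 1e-6)
  ex <- diffusion_exact(two, "X", alpha = 0.5, method = "propagation")
  expect_equal(ex$score, c(2 / 3, 1 / 3), tolerance = 1e-12)

  # alpha -> 0 collapses to the prior
  pr0 <- network_propagation(two, "X", alpha = 1e-9)
  expect_equal(pr0$score, c(1, 0), tolerance = 1e-6)

  # symmetric seeds get identical scores
  pr2 <- network_propagation(two, c("X", "Y"), alpha = 0.6)
  expect_equal(pr2$score[1], pr2$score[2], tolerance = 1e-12)

  withr::with_seed(9, {
    net <- random_net(6, p_edge = 0.5)
    seeds <- network_nodes(net)[c(1, 4)]
    it <- network_propagation(net, seeds, alpha = 0.5)
    ex <- diffusion_exact(net, seeds, alpha = 0.5, method = "propagation")
    expect_lt(sum(abs(it$score - ex$score)), 1e-6)
  })
})

test_that("diffusion fixed point is initialization-independent", {
  # the iteration always starts from F0; re-running must reproduce exactly,
  # and the exact solve provides an initialization-free reference
  withr::with_seed(10, {
    net <- random_net(8, p_edge = 0.4)
    seeds <- network_nodes(net)[1:3]
    a <- network_propagation(net, seeds, alpha = 0.7)
    b <- network_propagation(net, seeds, alpha = 0.7)
    expect_identical(a, b)
    ex <- diffusion_exact(net, seeds, alpha = 0.7, method = "propagation")
    expect_lt(sum(abs(a$score - ex$score)), 1e-5)
  })
})

test_that("seed membership monotonicity: joining the seed set never lowers a node's score", {
  withr::with_seed(12, {
    for (i in 1:10) {
      net <- random_net(10, p_edge = 0.3)
      nodes <- network_nodes(net)
      seeds <- sample(nodes, 3)
      extra <- sample(setdiff(nodes, seeds), 1)
      for (fun in list(random_walk, network_propagation)) {
        before <- fun(net, seeds, alpha = 0.5)
        after <- fun(net, c(seeds, extra), alpha = 0.5)
        expect_gte(after$score[after$node == extra] + 1e-9,
                   before$score[before$node == extra])
      }
    }
  })
})

test_that("components without any DEG score zero under all four methods", {
  # two components: path A-B-C (seeded) and D-E (unseeded)
  net <- as_interaction_network(
    data.frame(from = c("A", "B", "D"), to = c("B", "C", "E"))
  )
  signal <- make_signal(net, "A", weight = 2)
  for (m in c("neighborhood", "interconnectivity", "random_walk",
              "propagation")) {
    sc <- score_nodes(net, signal, methods = m)
    expect_equal(sc$score[sc$node %in% c("D", "E")], c(0, 0),
                 tolerance = 1e-7)
  }
})

test_that("non-convergence and empty seed sets raise errors", {
  two <- as_interaction_network(data.frame(from = "X", to = "Y"))
  expect_error(random_walk(two, "X", alpha = 0.01, max_iter = 2L),
               "did not converge")
  expect_error(network_propagation(two, character(0)), "At least one")
  expect_error(random_walk(two, "nope"), "not in network")
})
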