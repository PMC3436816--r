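test_that("transition operator normalizes by weight and flags dangling nodes", {
  path <- xd_network(data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                                weight = c(0.5, 0.5)))
  tr <- build_transition_operator(path)
  expect_equal(as.numeric(tr$op["A", "B"]), 0.5)
  expect_equal(as.numeric(tr$op["C", "B"]), 0.5)
  expect_equal(as.numeric(Matrix::colSums(tr$op)), rep(1, 3))

  star <- xd_network(data.frame(node_a = c("H", "H"), node_b = c("X", "Y"),
                                weight = c(0.9, 0.1)))
  ts <- build_transition_operator(star)
  expect_equal(as.numeric(ts$op["X", "H"]), 0.9)
  expect_equal(as.numeric(ts$op["Y", "H"]), 0.1)

  iso <- xd_network(data.frame(node_a = "A", node_b = "B", weight = 1),
                    extra_nodes = "D")
  expect_true(build_transition_operator(iso)$dangling[["D"]])
  expect_error(build_transition_operator(
    structure(list(nodes = character(),
                   edges = data.frame(node_a = character(), node_b = character(),
                                      weight = numeric())),
              class = "xd_network")), "empty")
})

test_that("two-node closed form and single-node degenerate case are exact", {
  one <- xd_network(data.frame(node_a = character(), node_b = character(),
                               weight = numeric()), extra_nodes = "A")
  rv <- random_walk_with_restart(one, "A")
  expect_equal(unname(rv$scores[["A"]]), 1.0)

  two <- xd_network(data.frame(node_a = "A", node_b = "B", weight = 1))
  rv2 <- random_walk_with_restart(two, "A", restart_prob = 0.9, tol = 1e-14)
  # fixed point of p_A = 0.1 p_B + 0.9, p_B = 0.1 p_A
  expect_equal(unname(rv2$scores[["A"]]), 10 / 11, tolerance = 1e-12)
  expect_equal(unname(rv2$scores[["B"]]), 1 / 11, tolerance = 1e-12)
  expect_true(rv2$converged)
})

test_that("iterative RWR matches the dense linear-solve oracle", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(5:50, 1)
    net <- random_net(n, p = runif(1, 0.08, 0.3), seed = 200 + s)
    seeds <- sample(net$nodes, sample(1:4, 1))
    rv <- random_walk_with_restart(net, seeds)
    oracle <- rwr_linear_oracle(net, seeds)
    expect_lt(max(abs(rv$scores[net$nodes] - oracle[net$nodes])), 1e-8)
  }
})

test_that("probability is conserved, including with dangling nodes", {
  for (s in 1:10) {
    net <- random_net(15, p = 0.08, seed = 300 + s)  # sparse: isolates likely
    rv <- random_walk_with_restart(net, net$nodes[1:2])
    expect_equal(sum(rv$scores), 1, tolerance = 1e-9)
    expect_true(all(rv$scores >= 0))
  }
})

test_that("seed relevance dominates at high restart probability", {
  for (s in 1:10) {
    net <- random_net(20, seed = 400 + s)
    seeds <- sample(net$nodes, 3)
    rv <- random_walk_with_restart(net, seeds, restart_prob = 0.9)
    expect_gt(sum(rv$scores[seeds]), sum(rv$scores[setdiff(net$nodes, seeds)]))
  }
})

test_that("relevance on a cycle depends only on graph distance from the seed", {
  n <- 9
  ids <- sprintf("c%d", 1:n)
  net <- xd_network(data.frame(node_a = ids, node_b = ids[c(2:n, 1)],
                               weight = 1))
  rv <- random_walk_with_restart(net, "c1")
  dist <- pmin(abs(seq_len(n) - 1), n - abs(seq_len(n) - 1))
  sc <- rv$scores[ids]
  for (d in unique(dist)) {
    vals <- sc[dist == d]
    expect_lt(diff(range(vals)), 1e-12)
  }
})

test_that("seed handling: empty/unmapped seeds error, partial seeds warn", {
  net <- toy_net()
  expect_error(random_walk_with_restart(net, character()), "empty")
  expect_error(suppressWarnings(random_walk_with_restart(net, c("X", "Y"))),
               "no seed")
  expect_warning(rv <- random_walk_with_restart(net, c("A", "Z")), "dropped")
  expect_equal(sum(rv$scores), 1, tolerance = 1e-9)
  expect_error(random_walk_with_restart(net, "A", restart_prob = 1), "between")
})

test_that("distances are the 1-complement of relevance", {
  net <- toy_net()
  rv <- random_walk_with_restart(net, "A")
  dv <- to_distances(rv)
  expect_equal(unname(dv), unname(1 - rv$scores))
  expect_true(all(dv >= 0 & dv <= 1))

  one <- xd_network(data.frame(node_a = character(), node_b = character(),
                               weight = numeric()), extra_nodes = "A")
  expect_equal(unname(to_distances(random_walk_with_restart(one, "A"))[["A"]]), 0)

  two <- xd_network(data.frame(node_a = "A", node_b = "B", weight = 1))
  dv2 <- to_distances(random_walk_with_restart(two, "A"))
  expect_equal(unname(dv2[["A"]]), 1 / 11, tolerance = 1e-10)
  expect_equal(unname(dv2[["B"]]), 10 / 11, tolerance = 1e-10)
})
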