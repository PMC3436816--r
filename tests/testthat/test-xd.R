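test_that("quantile bin schemes give a near-uniform background that sums to 1", {
  pooled <- seq(0.0005, 0.9995, length.out = 1000)
  sc <- build_bin_scheme(pooled, n_bins = 10)
  expect_equal(sc$background_fractions, rep(0.1, 10))
  expect_equal(sum(sc$background_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(sc$edges) > 0))

  set.seed(5)
  for (i in 1:10) {
    sc2 <- build_bin_scheme(rbeta(500, 2, 5), n_bins = sample(2:15, 1))
    expect_equal(sum(sc2$background_fractions), 1, tolerance = 1e-9)
  }
})

test_that("degenerate pooled values fall back to equal-width binning", {
  expect_warning(sc <- build_bin_scheme(rep(0.7, 50), n_bins = 10), "equal-width")
  expect_equal(sc$method, "width")
  expect_equal(sum(sc$background_fractions > 0), 1L)  # single occupied bin
  expect_warning(build_bin_scheme(c(1, 1, 2, 2, 3), n_bins = 4), "equal-width")
  expect_error(build_bin_scheme(numeric()), "no pooled")
})

test_that("pathway profiles respect bins and tissue filters", {
  net <- random_net(30, seed = 9)
  ms <- map_set(gene_set("r", net$nodes[1:8]), net, min_mapped = 1L,
                role = "reference")
  dv <- to_distances(random_walk_with_restart(net, net$nodes[1:3]))
  sc <- build_bin_scheme(dv[net$nodes], n_bins = 5)

  p <- profile_pathway(dv, ms, sc)
  expect_equal(sum(p$fractions), 1, tolerance = 1e-9)
  expect_equal(p$n_scores, 8L)

  # filter covering everything is the identity
  p_all <- profile_pathway(dv, ms, sc, tissue_filter = net$nodes)
  expect_equal(p_all$fractions, p$fractions)

  # filter excluding every member: empty profile, Xd undefined (never 0)
  p_none <- profile_pathway(dv, ms, sc, tissue_filter = "nothing")
  expect_equal(p_none$n_scores, 0L)
  expect_true(is.na(xd_score(p_none, sc)))

  # all scores in the first bin
  lo <- make_scheme(rep(0.2, 5))
  p_lo <- profile_pathway(stats::setNames(rep(0.05, 8), ms$mapped), ms, lo)
  expect_equal(p_lo$fractions, c(1, 0, 0, 0, 0))
})

test_that("Xd hand values are exact", {
  bg <- make_scheme(rep(0.1, 10))
  expect_equal(xd_score(make_profile(rep(0.1, 10)), bg), 0, tolerance = 1e-9)

  H10 <- sum(1 / (1:10)); H9 <- sum(1 / (1:9))
  near <- xd_score(make_profile(c(1, rep(0, 9))), bg)
  expect_equal(near, 0.9 - 0.1 * (H10 - 1), tolerance = 1e-9)
  expect_equal(near, 0.7071032, tolerance = 1e-6)

  far <- xd_score(make_profile(c(rep(0, 9), 1)), bg)
  expect_equal(far, -0.1 * H9 + 0.09, tolerance = 1e-9)
  expect_equal(far, -0.1928968, tolerance = 1e-6)

  # optional 1/n normalization
  expect_equal(xd_score(make_profile(c(1, rep(0, 9))), bg, normalize = TRUE),
               near / 10, tolerance = 1e-12)
})

test_that("moving profile mass to a nearer bin strictly increases Xd", {
  set.seed(77)
  bg <- make_scheme(random_fractions(10))
  for (rep in 1:200) {
    fr <- random_fractions(10)
    j <- sample(2:10, 1)
    i <- sample(seq_len(j - 1), 1)
    shift <- fr[j] * runif(1, 0.1, 1)
    fr2 <- fr
    fr2[i] <- fr2[i] + shift
    fr2[j] <- fr2[j] - shift
    expect_gt(xd_score(make_profile(fr2), bg), xd_score(make_profile(fr), bg))
  }
})

test_that("|Xd| is bounded by the harmonic number of the bin count", {
  set.seed(78)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    H <- sum(1 / seq_len(n))
    xd <- xd_score(make_profile(random_fractions(n)),
                   make_scheme(random_fractions(n)))
    expect_lte(abs(xd), H)
  }
})

test_that("the pooled background scores 0 against itself", {
  net <- random_net(40, seed = 21)
  refs <- map_collection(gene_set_collection(list(
    gene_set("r1", net$nodes[1:10]), gene_set("r2", net$nodes[11:25]))), net)
  dv <- to_distances(random_walk_with_restart(net, net$nodes[1:3]))
  pooled <- unlist(lapply(refs, function(m) dv[m$mapped]), use.names = FALSE)
  sc <- build_bin_scheme(pooled, n_bins = 10)
  # a pseudo-set whose distance scores are exactly the pooled values
  counts <- xdnet:::bin_counts(pooled, sc$edges)
  xd <- sum((counts / sum(counts) - sc$background_fractions) / 1:10)
  expect_equal(xd, 0, tolerance = 1e-9)
})

test_that("score_collection is deterministic, order-invariant, and rewards proximity", {
  net <- random_net(40, p = 0.12, seed = 31)
  target <- map_set(gene_set("t", net$nodes[1:5]), net, min_mapped = 1L)
  col <- gene_set_collection(list(
    gene_set("same1", net$nodes[6:15]),
    gene_set("same2", net$nodes[6:15]),   # identical membership
    gene_set("other", net$nodes[26:35])))
  refs <- map_collection(col, net)
  res <- score_collection(net, target, refs)
  expect_equal(res$xd[res$set_id == "same1"], res$xd[res$set_id == "same2"])

  # permuting reference order changes nothing
  res2 <- score_collection(net, target, refs[c(3, 1, 2)])
  expect_equal(res2[order(res2$set_id), c("set_id", "xd")],
               res[order(res$set_id), c("set_id", "xd")],
               ignore_attr = TRUE)

  # planted structure: the target's own clique outranks a distractor set
  # placed >= 3 hops away
  chain <- data.frame(
    node_a = c("t1", "t2", "t1", "t2", "b1", "b2", "b3", "d1", "d2", "d1"),
    node_b = c("t2", "t3", "t3", "b1", "b2", "b3", "d1", "d2", "d3", "d3"),
    weight = 1)
  pn <- xd_network(chain)
  pt <- map_set(gene_set("t", c("t1", "t2", "t3")), pn, min_mapped = 1L)
  prefs <- map_collection(gene_set_collection(list(
    gene_set("self", c("t1", "t2", "t3")),
    gene_set("distant", c("d1", "d2", "d3")))), pn)
  pres <- suppressWarnings(
    score_collection(pn, pt, prefs, n_bins = 2))
  expect_gt(pres$xd[pres$set_id == "self"], pres$xd[pres$set_id == "distant"])
  expect_equal(pres$set_id[1], "self")
})
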