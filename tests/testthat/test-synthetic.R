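test_that("generation is deterministic and leaves the session RNG untouched", {
  spec <- synthetic_spec(seed = 5)
  set.seed(999)
  before <- .Random.seed
  b1 <- generate_bundle(spec)
  expect_identical(.Random.seed, before)  # RNG state restored
  b2 <- generate_bundle(spec)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(b1, d1); write_fixture(b2, d2)
  for (f in c("network.tsv", "target.txt", "pathways.gmt", "tissues.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the world
  b3 <- generate_bundle(synthetic_spec(seed = 6))
  expect_false(identical(b1$network$edges, b3$network$edges))
})

test_that("planted wiring follows p_conn", {
  # p_conn = 1: every target x planted-pathway pair is connected
  b <- generate_bundle(synthetic_spec(n_nodes = 100, target_size = 6,
                                      pathway_sizes = rep(10L, 3L),
                                      planted = c(P1 = 1),
                                      overlap_members = c(P2 = 3L),
                                      seed = 8))
  for (t in b$target$members) {
    for (p in setdiff(b$collection$P1$members, t)) {
      expect_false(is.na(edge_weight(b$network, t, p)),
                   label = sprintf("%s-%s", t, p))
    }
  }

  # p_conn = 0 adds nothing: network identical to the unplanted base model
  s0 <- synthetic_spec(seed = 8, planted = c(P1 = 0))
  b0 <- generate_bundle(s0)
  base <- generate_bundle(synthetic_spec(seed = 8, planted = c(P1 = 0.3)))
  expect_lt(nrow(b0$network$edges), nrow(base$network$edges))
  # planted weights come from the high-confidence range
  extra <- setdiff(paste(base$network$edges$node_a, base$network$edges$node_b),
                   paste(b0$network$edges$node_a, b0$network$edges$node_b))
  ww <- base$network$edges$weight[
    paste(base$network$edges$node_a, base$network$edges$node_b) %in% extra]
  expect_true(all(ww >= 0.5 & ww <= 1))
})

test_that("bundle structure matches the spec: disjoint pathways, overlaps, tissues", {
  b <- generate_bundle(synthetic_spec(seed = 12))
  members <- lapply(b$collection, `[[`, "members")
  expect_equal(length(unlist(members)), length(unique(unlist(members))))
  expect_length(b$collection, 8L)
  expect_length(b$target$members, 15L)
  # graded designed overlaps; planted pathway has exactly zero overlap
  ov <- vapply(members, function(m) length(intersect(m, b$target$members)),
               integer(1))
  expect_equal(unname(ov[c("P1", "P2", "P3", "P4", "P5")]), c(0L, 6L, 4L, 3L, 2L))
  # the planted tissue covers the planted pathway entirely
  expect_true(all(b$collection$P1$members %in% tissue_nodes(b$tissue, "brain")))
  expect_true(all(b$target$members %in% b$network$nodes))
})

test_that("fixtures round-trip through the package readers", {
  b <- generate_bundle(synthetic_spec(seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_fixture(b, dir)

  net <- read_edge_list(paths[["network"]])
  expect_equal(net$edges, b$network$edges)
  expect_equal(read_gene_list(paths[["target"]])$members, b$target$members)
  col <- read_gmt(paths[["gmt"]])
  expect_equal(names(col), names(b$collection))
  for (id in names(col)) {
    expect_setequal(col[[id]]$members, b$collection[[id]]$members)
  }
  ta <- read_tissue_annotations(paths[["tissue"]])
  for (lab in tissue_labels(b$tissue)) {
    expect_setequal(tissue_nodes(ta, lab), tissue_nodes(b$tissue, lab))
  }
  expect_equal(length(readLines(paths[["gmt"]])), length(b$collection))
  # every fixture id resolves against the network (or its unmapped report)
  m <- map_set(col$P1, net, min_mapped = 1L, role = "reference")
  expect_equal(length(m$mapped) + length(m$unmapped), length(col$P1$members))
})

test_that("the shipped extdata fixture is the seed-42 bundle", {
  dir <- system.file("extdata", "fixture", package = "xdnet")
  expect_true(nzchar(dir))
  b <- generate_bundle(synthetic_spec(seed = 42L))
  tmp <- withr::local_tempdir()
  write_fixture(b, tmp)
  for (f in c("network.tsv", "target.txt", "pathways.gmt", "tissues.tsv")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(tmp, f)), label = f)
  }
})

test_that("mean planted Xd is non-decreasing in the wiring probability", {
  # scaled-down sweep (15 seeds per level; the full 50-seed sweep at
  # p_conn = 0.3 runs in the acceptance suite)
  levels <- c(0, 0.1, 0.3, 0.6)
  means <- vapply(levels, function(pc) {
    mean(vapply(1:15, function(s) {
      b <- generate_bundle(synthetic_spec(seed = s, planted = c(P1 = pc)))
      tgt <- map_set(b$target, b$network, min_mapped = 1L)
      refs <- map_collection(b$collection, b$network)
      res <- score_collection(b$network, tgt, refs)
      res$xd[res$set_id == "P1"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_gt(means[4], means[1] + 0.2)  # strong signal at heavy wiring
})
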