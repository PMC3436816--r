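# In-code fixtures and independent oracles shared across the suite.

toy_net <- function() {
  xd_network(data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                        weight = c(0.9, 0.5)))
}

# Erdos-Renyi-style random weighted network; may contain isolated (dangling)
# nodes, which is intentional for probability-conservation checks.
random_net <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  ids <- sprintf("n%02d", seq_len(n))
  if (!any(keep)) keep[1] <- TRUE
  xd_network(data.frame(node_a = ids[pairs[keep, 1]],
                        node_b = ids[pairs[keep, 2]],
                        weight = runif(sum(keep), 0.1, 1)),
             extra_nodes = ids)
}

# Dense linear-solve oracle for RWR: fixed point of
#   p = (1 - r) * (T + p0 d^T) p + r * p0
# where d marks dangling nodes (mass redirected to the restart distribution).
# Independent of the iterative implementation path.
rwr_linear_oracle <- function(net, seeds, r = 0.9) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$node_a[i]; b <- net$edges$node_b[i]; w <- net$edges$weight[i]
    A[a, b] <- A[a, b] + w
    A[b, a] <- A[b, a] + w
  }
  cs <- colSums(A)
  Tm <- A
  for (j in seq_len(n)) if (cs[j] > 0) Tm[, j] <- Tm[, j] / cs[j]
  p0 <- numeric(n); names(p0) <- nodes
  p0[seeds] <- 1 / length(seeds)
  d <- as.numeric(cs == 0)
  M <- Tm + outer(p0, d)
  solve(diag(n) - (1 - r) * M, r * p0)
}

# Exhaustive enumeration oracle for the one-sided overlap test: probability,
# over all C(N, t) equally likely target draws from a universe {1..N} with
# reference set {1..m}, of an overlap >= k.
fisher_enum_oracle <- function(k, t, m, N) {
  draws <- combn(N, t)
  hits <- colSums(draws <= m)  # overlap with {1..m}
  mean(hits >= k)
}

# Brute-force step-up definition of the BH adjustment.
bh_brute <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  sapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(p[js] * m / rank(p, ties.method = "max")[js]))
  })
}

# Closed-form normal-equations OLS oracle.
ols_oracle <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  c(slope = sl, intercept = ic)
}

# random profile/background fraction pair for Xd property tests
random_fractions <- function(n_bins) {
  x <- runif(n_bins)
  x / sum(x)
}

make_profile <- function(fractions, set_id = "p", n_scores = 100L) {
  structure(list(set_id = set_id, fractions = fractions,
                 n_scores = as.integer(n_scores)),
            class = "pathway_profile")
}

make_scheme <- function(background, edges = seq(0, 1, length.out = length(background) + 1)) {
  structure(list(n_bins = length(background), edges = edges,
                 background_fractions = background, method = "quantile"),
            class = "bin_scheme")
}
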