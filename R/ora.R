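# Over-representation baseline: one-sided Fisher's exact test on the 2x2
# membership table, Benjamini-Hochberg step-up adjustment, and the gene
# universe the table is built over.

#' One-sided Fisher's exact test for over-representation
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of drawing at least `k`
#' reference-set members when `t` target genes are sampled without replacement
#' from a universe of `N` genes containing `m` reference-set members. Computed
#' by exact tail summation of log-densities (no normal approximation), so the
#' result is numerically safe at genome-scale `N`. `k = 0` gives exactly 1.
#'
#' @param k overlap count.
#' @param t target-set size within the universe.
#' @param m reference-set size within the universe.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
fisher_overrep <- function(k, t, m, N) {
  k <- as.integer(k); t <- as.integer(t); m <- as.integer(m); N <- as.integer(N)
  if (any(is.na(c(k, t, m, N)))) stop("overlap table entries must be integers")
  if (t > N || m > N) stop("set sizes cannot exceed the universe size")
  if (k < 0 || k > min(t, m)) stop("overlap k must satisfy 0 <= k <= min(t, m)")
  if (k + (N - m) < t) stop("overlap k too small: t - k genes must fit outside the reference set")
  if (k == 0L) return(1)
  xs <- k:min(t, m)
  lp <- stats::dhyper(xs, m, N - m, t, log = TRUE)
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j : p_(j) >= p_(i)} p_(j) * m / rank(j)`, capped at 1; output
#' order matches input order, ties in p map to equal q, and q >= p elementwise.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  p <- as.numeric(pvals)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)        # largest first
  ranks <- m:1L                           # rank of p in ascending order
  q <- pmin(1, cummin(p[o] * m / ranks))[order(o)]
  pmax(p, q)  # q >= p holds exactly; clamp away 1-ulp rounding dips
}

#' Gene universe for the contingency table
#'
#' The universe defines `N` and clips `t` and `m`. Default is the network's
#' node set, so the overlap statistic and the network statistic see the same
#' gene space (required for a meaningful Xd-vs-q regression); the union of
#' all reference-set members is available as an alternative.
#'
#' @param net an `xd_network`.
#' @param refs a `gene_set_collection`.
#' @param mode `"network_nodes"` (default) or `"union_of_refs"`.
#' @return character vector of gene ids.
#' @export
gene_universe <- function(net, refs, mode = c("network_nodes", "union_of_refs")) {
  mode <- match.arg(mode)
  u <- switch(mode,
              network_nodes = net$nodes,
              union_of_refs = sort(unique(unlist(lapply(refs, `[[`, "members"),
                                                 use.names = FALSE))))
  if (length(u) == 0L) stop("gene universe is empty")
  u
}

#' Fisher/BH over-representation analysis of a collection
#'
#' Builds one 2x2 table per reference set over the chosen universe and returns
#' one-sided Fisher p-values and BH q-values. Target genes outside the
#' universe are dropped from `t` (count reported via attribute
#' `n_target_dropped`).
#'
#' @param target a `gene_set` (the raw target set; clipping to the universe
#'   happens here).
#' @param refs a `gene_set_collection`.
#' @param universe character vector from [gene_universe()].
#' @return data.frame with columns `set_id`, `overlap`, `m`, `fisher_p`,
#'   `fisher_q`, in collection order.
#' @export
ora_analysis <- function(target, refs, universe) {
  stopifnot(inherits(target, "gene_set"))
  tset <- intersect(target$members, universe)
  dropped <- length(target$members) - length(tset)
  N <- length(universe)
  t <- length(tset)
  if (t == 0L) stop("no target gene lies in the universe")
  rows <- lapply(refs, function(s) {
    mem <- intersect(s$members, universe)
    k <- length(intersect(tset, mem))
    data.frame(set_id = s$set_id, overlap = k, m = length(mem),
               fisher_p = if (length(mem)) fisher_overrep(k, t, length(mem), N) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$fisher_p)
  out$fisher_q <- NA_real_
  out$fisher_q[ok] <- bh_adjust(out$fisher_p[ok])
  attr(out, "n_target_dropped") <- dropped
  attr(out, "universe_size") <- N
  out
}
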