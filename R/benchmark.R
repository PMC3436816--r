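# Benchmark evaluation machinery: consensus benchmark construction by top-k
# intersection and the normalized Kolmogorov-Smirnov running-sum enrichment
# score of benchmark members within a ranking, with permutation p-values.

#' Consensus benchmark by top-k intersection
#'
#' Intersects the top-`top_k` prefixes of two or more rankings; a ranking
#' shorter than `top_k` contributes its full list with a warning.
#'
#' @param rankings list of >= 2 character vectors (best first, no duplicates).
#' @param top_k prefix size (default 100).
#' @return character vector of ids present in every prefix.
#' @export
benchmark_intersection <- function(rankings, top_k = 100L) {
  stopifnot(is.list(rankings), length(rankings) >= 2L, top_k >= 1L)
  prefixes <- lapply(rankings, function(r) {
    r <- as.character(r)
    if (anyDuplicated(r)) stop("ranking contains duplicate ids")
    if (length(r) < top_k) {
      warning(sprintf("ranking has %d < top_k = %d items; using full list",
                      length(r), top_k))
      r
    } else r[seq_len(top_k)]
  })
  Reduce(intersect, prefixes)
}

# Running sum over a benchmark indicator: +sqrt((m-h)/h) on hits,
# -sqrt(h/(m-h)) on misses; weights balance so the final prefix sum is 0.
running_sum <- function(is_bench) {
  m <- length(is_bench)
  h <- sum(is_bench)
  if (h == 0L || h == m) stop("benchmark must be a proper non-empty subset of the ranking")
  step <- ifelse(is_bench, sqrt((m - h) / h), -sqrt(h / (m - h)))
  cumsum(step)
}

es_from_indicator <- function(is_bench, two_sided = FALSE) {
  rs <- running_sum(is_bench)
  if (two_sided) max(abs(c(0, rs))) else max(0, rs)
}

#' Normalized KS running-sum enrichment score
#'
#' Walks the ranking from best to worst, adding `sqrt((m - h) / h)` at each
#' benchmark member and subtracting `sqrt(h / (m - h))` otherwise (`m` = list
#' length, `h` = benchmark size), and returns the maximum prefix sum (the
#' empty prefix, value 0, included): a one-sided enrichment-at-the-top score.
#' `two_sided = TRUE` returns the maximum absolute deviation instead.
#'
#' @param ranking character vector, best first, no duplicates.
#' @param benchmark character vector, a proper non-empty subset of `ranking`.
#' @param two_sided use the maximum absolute running sum.
#' @return numeric enrichment score (>= 0).
#' @export
ks_running_sum <- function(ranking, benchmark, two_sided = FALSE) {
  ranking <- as.character(ranking)
  if (anyDuplicated(ranking)) stop("ranking contains duplicate ids")
  benchmark <- unique(as.character(benchmark))
  if (!all(benchmark %in% ranking)) stop("benchmark must be a subset of the ranking")
  es_from_indicator(ranking %in% benchmark, two_sided = two_sided)
}

#' Permutation p-value for the enrichment score
#'
#' Null distribution from random permutations of the input ranking; since the
#' score depends only on where the benchmark members fall, each permutation
#' draws the `h` benchmark positions uniformly among the `m` ranks (identical
#' in distribution, much cheaper). Add-one estimator
#' `p = (1 + #(es_perm >= es_obs)) / (n_perm + 1)`, so p is never exactly 0
#' and is floored at `1 / (n_perm + 1)` (0.001 at 1000 permutations).
#'
#' @inheritParams ks_running_sum
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed; RNG state is restored on exit.
#' @return object of class `es_result`: list with `es`, `p_value`,
#'   `n_permutations`.
#' @export
permutation_pvalue <- function(ranking, benchmark, n_perm = 1000L, seed = NULL,
                               two_sided = FALSE) {
  stopifnot(n_perm >= 1L)
  obs <- ks_running_sum(ranking, benchmark, two_sided = two_sided)
  m <- length(ranking)
  h <- length(unique(benchmark))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  perm <- vapply(seq_len(n_perm), function(i) {
    ind <- logical(m)
    ind[sample.int(m, h)] <- TRUE
    es_from_indicator(ind, two_sided = two_sided)
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  structure(list(es = obs, p_value = p, n_permutations = as.integer(n_perm)),
            class = "es_result")
}

#' @export
print.es_result <- function(x, ...) {
  cat(sprintf("<es_result> es = %.4g, p = %.4g (%d permutations)\n",
              x$es, x$p_value, x$n_permutations))
  invisible(x)
}
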