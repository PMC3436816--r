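# The Xd distance-bin statistic.
#
# Distance scores of each reference set's mapped nodes are discretized into
# n bins; the set's bin fractions P_ic are compared to the background
# fractions P_ia pooled over every reference set:
#
#   Xd = sum_{i=1..n} (P_ic - P_ia) / i
#
# The 1/i factor down-weights distant bins, so an excess of *short* distances
# (dense direct/indirect wiring to the seed set) dominates the score, and
# long-distance / high-degree outliers contribute little. Fractions live in
# [0, 1]; an optional extra 1/n normalization is available via `normalize`.

#' Build a bin scheme from pooled distance scores
#'
#' Default binning is equal-frequency: bin edges are quantiles of the pooled
#' distance distribution, making the background fractions near-uniform
#' (P_ia ~ 1/n up to ties) and profile deviations directly interpretable.
#' RWR relevance spans orders of magnitude, so equal-width bins over the raw
#' range would pile almost all mass into one bin; equal-width binning is still
#' available via `method = "width"` for sensitivity analysis. If the pooled
#' values carry fewer distinct values than bins, the scheme falls back to
#' equal-width edges over the observed range with a warning.
#'
#' Bins are left-closed/right-open; the last bin is closed on the right.
#'
#' @param pooled numeric vector of distance scores pooled over all reference
#'   sets (with multiplicity).
#' @param n_bins number of bins (>= 2); default 10.
#' @param method `"quantile"` (equal-frequency, default) or `"width"`.
#' @return object of class `bin_scheme`: list with `n_bins`, `edges`
#'   (length `n_bins + 1`, strictly increasing), `background_fractions`
#'   (sums to 1) and `method` actually used.
#' @export
build_bin_scheme <- function(pooled, n_bins = 10L, method = c("quantile", "width")) {
  method <- match.arg(method)
  pooled <- as.numeric(pooled)
  pooled <- pooled[is.finite(pooled)]
  if (length(pooled) == 0L) stop("no pooled distance scores to bin")
  stopifnot(n_bins >= 2L)
  used <- method
  edges <- NULL
  if (method == "quantile") {
    if (length(unique(pooled)) < n_bins) {
      warning("fewer distinct pooled values than bins; falling back to equal-width edges")
      used <- "width"
    } else {
      qs <- stats::quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE, type = 7)
      if (any(diff(qs) <= 0)) {
        warning("tied quantile edges; falling back to equal-width edges")
        used <- "width"
      } else {
        edges <- qs
      }
    }
  }
  if (is.null(edges)) {
    lo <- min(pooled); hi <- max(pooled)
    if (hi <= lo) hi <- lo + 1  # all values identical: single occupied bin
    edges <- seq(lo, hi, length.out = n_bins + 1)
    used <- "width"
  }
  counts <- bin_counts(pooled, edges)
  structure(list(n_bins = as.integer(n_bins), edges = edges,
                 background_fractions = counts / sum(counts), method = used),
            class = "bin_scheme")
}

# Histogram counts under the scheme's bin convention: left-closed/right-open,
# last bin right-closed; values outside the edge range are clamped into the
# first/last bin.
bin_counts <- function(x, edges) {
  n_bins <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = n_bins)
}

#' Profile a reference set's distances under a bin scheme
#'
#' Assigns the distance scores of the set's mapped nodes (optionally
#' restricted to a tissue's node filter) to the scheme's bins and normalizes
#' to fractions. A profile with no contributing scores is flagged empty; the
#' Xd score is then undefined (NA downstream), never silently 0.
#'
#' @param dv named numeric distance vector ([to_distances()]) over the same
#'   network the set was mapped against.
#' @param ref a `mapped_set`.
#' @param scheme a `bin_scheme`.
#' @param tissue_filter optional character vector of node ids; only reference
#'   nodes inside the filter contribute.
#' @return object of class `pathway_profile`: list with `set_id`, `fractions`
#'   (sums to 1 when non-empty), `n_scores`.
#' @export
profile_pathway <- function(dv, ref, scheme, tissue_filter = NULL) {
  stopifnot(inherits(ref, "mapped_set"), inherits(scheme, "bin_scheme"))
  nodes <- ref$mapped
  if (!is.null(tissue_filter)) nodes <- intersect(nodes, tissue_filter)
  vals <- dv[nodes]
  vals <- vals[!is.na(vals)]
  n <- length(vals)
  fr <- if (n > 0L) bin_counts(vals, scheme$edges) / n else rep(NA_real_, scheme$n_bins)
  structure(list(set_id = ref$origin$set_id, fractions = fr, n_scores = n),
            class = "pathway_profile")
}

#' Xd score of a profile against the background
#'
#' `Xd = sum_i (P_ic - P_ia) / i`, with profile fractions `P_ic` and
#' background fractions `P_ia` in \[0, 1\]. Returns `NA_real_` for an empty
#' profile (the "not scorable" sentinel — 0 is a meaningful score and is never
#' used as a placeholder).
#'
#' @param profile a `pathway_profile`.
#' @param scheme the `bin_scheme` the profile was built under.
#' @param normalize if `TRUE`, additionally divide by the number of bins.
#' @return numeric Xd score, or `NA_real_` when the profile is empty.
#' @export
xd_score <- function(profile, scheme, normalize = FALSE) {
  stopifnot(inherits(profile, "pathway_profile"), inherits(scheme, "bin_scheme"))
  if (profile$n_scores == 0L) return(NA_real_)
  n <- scheme$n_bins
  xd <- sum((profile$fractions - scheme$background_fractions) / seq_len(n))
  if (normalize) xd <- xd / n
  xd
}

#' Score a reference collection against a target set
#'
#' The full network statistic: one RWR from the target seeds, distances by
#' subtraction from 1, one pooled background over all scorable reference
#' sets, then one Xd score per reference set. When tissue annotations are
#' given, each tissue label additionally gets its own Xd column, computed by
#' restricting both the reference-node distances and the pooled background to
#' nodes annotated for that tissue (a matched background avoids scale
#' artifacts between tissues).
#'
#' @param net an `xd_network`.
#' @param target a `mapped_set` for the target gene set.
#' @param refs named list of `mapped_set` objects ([map_collection()]).
#' @param restart_prob RWR restart probability (default 0.9).
#' @param n_bins number of distance bins (default 10).
#' @param tissue optional `tissue_annotation`.
#' @param binning passed to [build_bin_scheme()] (`"quantile"` or `"width"`).
#' @param normalize passed to [xd_score()].
#' @return data.frame with columns `set_id`, `xd`, `n_scores`, `n_mapped`,
#'   `overlap` (and `xd_<label>` per tissue), sorted by `xd` descending with
#'   unscorable sets (NA) last. Attributes: `bin_scheme`, `relevance`.
#' @export
score_collection <- function(net, target, refs, restart_prob = 0.9,
                             n_bins = 10L, tissue = NULL,
                             binning = c("quantile", "width"),
                             normalize = FALSE) {
  binning <- match.arg(binning)
  stopifnot(inherits(target, "mapped_set"))
  if (target$n_mapped == 0L) stop("target set has no mapped members")
  scorable <- vapply(refs, function(m) !m$unscorable, logical(1))
  if (!any(scorable)) stop("no reference set is scorable on this network")

  rv <- random_walk_with_restart(net, target$mapped, restart_prob = restart_prob)
  dv <- to_distances(rv)

  pooled <- unlist(lapply(refs[scorable], function(m) dv[m$mapped]),
                   use.names = FALSE)
  scheme <- build_bin_scheme(pooled, n_bins = n_bins, method = binning)

  res <- data.frame(
    set_id = vapply(refs, function(m) m$origin$set_id, character(1)),
    stringsAsFactors = FALSE)
  profs <- lapply(refs, function(m) {
    if (m$unscorable) NULL else profile_pathway(dv, m, scheme)
  })
  res$xd <- vapply(profs, function(p) {
    if (is.null(p)) NA_real_ else xd_score(p, scheme, normalize = normalize)
  }, numeric(1))
  res$n_scores <- vapply(profs, function(p) {
    if (is.null(p)) 0L else p$n_scores
  }, integer(1))
  res$n_mapped <- vapply(refs, function(m) m$n_mapped, integer(1))
  res$overlap <- vapply(refs, function(m) {
    length(intersect(target$mapped, m$mapped))
  }, integer(1))

  if (!is.null(tissue)) {
    stopifnot(inherits(tissue, "tissue_annotation"))
    for (lab in tissue_labels(tissue)) {
      filt <- intersect(tissue_nodes(tissue, lab), net$nodes)
      col <- paste0("xd_", lab)
      if (length(filt) == 0L) { res[[col]] <- NA_real_; next }
      pooled_t <- unlist(lapply(refs[scorable], function(m) {
        dv[intersect(m$mapped, filt)]
      }), use.names = FALSE)
      if (length(pooled_t) == 0L) { res[[col]] <- NA_real_; next }
      scheme_t <- suppressWarnings(
        build_bin_scheme(pooled_t, n_bins = n_bins, method = binning))
      res[[col]] <- vapply(seq_along(refs), function(i) {
        m <- refs[[i]]
        if (m$unscorable) return(NA_real_)
        p <- profile_pathway(dv, m, scheme_t, tissue_filter = filt)
        xd_score(p, scheme_t, normalize = normalize)
      }, numeric(1))
    }
  }

  ord <- order(-res$xd, res$set_id, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "bin_scheme") <- scheme
  attr(res, "relevance") <- rv
  res
}
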