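# End-to-end analysis driver: map -> RWR -> Xd -> ORA -> calibrate -> flag.

#' Run the full network enrichment analysis on in-memory objects
#'
#' Maps the target and reference sets onto the network, runs the random walk
#' with restart from the target seeds, scores every reference set with the Xd
#' statistic against the pooled background (plus per-tissue columns when
#' annotations are given), computes the Fisher/BH over-representation
#' baseline over the chosen universe, fits the Xd-versus-q calibration and
#' flags significant rows. The default configuration needs no tuning; every
#' constant is an overridable argument.
#'
#' @param net an `xd_network`.
#' @param target a `gene_set` (the raw target list).
#' @param collection a `gene_set_collection` of reference sets.
#' @param tissue optional `tissue_annotation`.
#' @param restart_prob RWR restart probability (default 0.9).
#' @param n_bins number of distance bins (default 10).
#' @param q_cut adjusted-p cutoff the Xd threshold corresponds to
#'   (default 0.05).
#' @param min_mapped advisory minimum mapped target size (default 10; a
#'   smaller mapped target warns but proceeds).
#' @param universe_mode universe for the overlap test
#'   (`"network_nodes"` or `"union_of_refs"`).
#' @param binning bin-edge mode (`"quantile"` or `"width"`).
#' @param transform calibration x-axis (`"neglog10"` or `"raw"`).
#' @param band calibration band (`"confidence"` or `"prediction"`).
#' @param conf confidence level of the calibration band (default 0.95).
#' @param normalize divide Xd by the bin count (default `FALSE`).
#' @param fallback_threshold Xd threshold used when the calibration is
#'   unavailable (default 0.5).
#' @return object of class `xd_result`: list with `ranking` (data.frame with
#'   columns `set_id`, `xd_score`, `n_mapped`, `overlap`, `fisher_p`,
#'   `fisher_q`, `significant_flag`, then one `xd_<label>` column per
#'   tissue), `threshold`, `calibration`, `relevance`, `bin_scheme`,
#'   `mapped_target`, `mapped_refs`, `log` (character vector of processing
#'   notes).
#' @export
run_xd_analysis <- function(net, target, collection, tissue = NULL,
                            restart_prob = 0.9, n_bins = 10L, q_cut = 0.05,
                            min_mapped = 10L,
                            universe_mode = c("network_nodes", "union_of_refs"),
                            binning = c("quantile", "width"),
                            transform = c("neglog10", "raw"),
                            band = c("confidence", "prediction"),
                            conf = 0.95, normalize = FALSE,
                            fallback_threshold = 0.5) {
  universe_mode <- match.arg(universe_mode)
  binning <- match.arg(binning)
  transform <- match.arg(transform)
  band <- match.arg(band)
  stopifnot(inherits(net, "xd_network"), inherits(target, "gene_set"),
            inherits(collection, "gene_set_collection"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  mt <- withCallingHandlers(
    map_set(target, net, min_mapped = min_mapped, role = "target"),
    warning = function(w) { note("%s", conditionMessage(w)); invokeRestart("muffleWarning") })
  note("target: %d/%d members mapped", mt$n_mapped, length(target$members))
  if (mt$n_mapped == 0L) stop("no target gene maps to the network")
  mrefs <- map_collection(collection, net)
  n_unsc <- sum(vapply(mrefs, `[[`, logical(1), "unscorable"))
  note("references: %d sets, %d unscorable", length(mrefs), n_unsc)

  scored <- score_collection(net, mt, mrefs, restart_prob = restart_prob,
                             n_bins = n_bins, tissue = tissue,
                             binning = binning, normalize = normalize)
  rv <- attr(scored, "relevance")
  note("RWR converged in %d iterations (r = %g)", rv$iterations_used,
       restart_prob)

  uni <- gene_universe(net, collection, mode = universe_mode)
  ora <- ora_analysis(target, collection, uni)
  merged <- merge(scored, ora[, c("set_id", "fisher_p", "fisher_q")],
                  by = "set_id", sort = FALSE)
  merged <- merged[order(-merged$xd, merged$set_id, na.last = TRUE), ,
                   drop = FALSE]

  merged <- withCallingHandlers(
    calibrate_ranking(merged, q_cut = q_cut, conf = conf, band = band,
                      transform = transform, fallback = fallback_threshold),
    warning = function(w) { note("%s", conditionMessage(w)); invokeRestart("muffleWarning") })
  thr <- attr(merged, "threshold")
  fit <- attr(merged, "calibration")
  note("Xd significance threshold: %.6g (q_cut = %g)", thr, q_cut)

  ranking <- data.frame(set_id = merged$set_id, xd_score = merged$xd,
                        n_mapped = merged$n_mapped, overlap = merged$overlap,
                        fisher_p = merged$fisher_p, fisher_q = merged$fisher_q,
                        significant_flag = merged$significant_flag,
                        stringsAsFactors = FALSE)
  tis_cols <- grep("^xd_", names(merged), value = TRUE)
  for (cc in tis_cols) ranking[[cc]] <- merged[[cc]]
  rownames(ranking) <- NULL

  structure(list(ranking = ranking, threshold = thr, calibration = fit,
                 relevance = rv, bin_scheme = attr(scored, "bin_scheme"),
                 mapped_target = mt, mapped_refs = mrefs, log = log),
            class = "xd_result")
}

#' @export
print.xd_result <- function(x, ...) {
  cat(sprintf("<xd_result> %d reference sets, threshold %.4g, %d flagged significant\n",
              nrow(x$ranking), x$threshold,
              sum(x$ranking$significant_flag, na.rm = TRUE)))
  print(utils::head(x$ranking, 10L))
  invisible(x)
}

#' Write a ranking table to TSV
#'
#' Column names and order are stable: `set_id`, `xd_score`, `n_mapped`,
#' `overlap`, `fisher_p`, `fisher_q`, `significant_flag`, then tissue
#' columns.
#'
#' @param result an `xd_result` (or its `ranking` data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, path) {
  tab <- if (inherits(result, "xd_result")) result$ranking else result
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' File-level pipeline run
#'
#' Reads the input files, runs [run_xd_analysis()] and writes
#' `ranking.tsv`, `calibration.txt` and `run.log` into `out_dir`. Outputs are
#' only written after the whole computation succeeds, so a failing run leaves
#' no partial files.
#'
#' @param network_path weighted edge-list TSV.
#' @param target_path target gene list, one id per line.
#' @param gmt_path reference collection in GMT format.
#' @param tissue_path optional tissue-annotation TSV.
#' @param out_dir output directory (created if absent).
#' @param weight_scale optional divisor for raw confidence scores
#'   (e.g. 1000).
#' @param ... further arguments to [run_xd_analysis()].
#' @return the `xd_result`, invisibly.
#' @export
run_xd_files <- function(network_path, target_path, gmt_path,
                         tissue_path = NULL, out_dir = ".",
                         weight_scale = NULL, ...) {
  net <- read_edge_list(network_path, weight_scale = weight_scale)
  target <- read_gene_list(target_path)
  collection <- read_gmt(gmt_path)
  tissue <- if (!is.null(tissue_path)) read_tissue_annotations(tissue_path)
  res <- run_xd_analysis(net, target, collection, tissue = tissue, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_ranking(res, file.path(out_dir, "ranking.tsv"))
  cal <- res$calibration
  writeLines(c(
    sprintf("threshold\t%.10g", res$threshold),
    sprintf("calibration_valid\t%s", isTRUE(cal$valid)),
    sprintf("slope\t%.10g", cal$slope),
    sprintf("intercept\t%.10g", cal$intercept),
    sprintf("residual_std\t%.10g", cal$residual_std),
    sprintf("pearson_r\t%.10g", cal$pearson_r),
    sprintf("n_points\t%d", cal$n_points)),
    file.path(out_dir, "calibration.txt"))
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(res)
}

#' Mann-Whitney comparison of tissue-group Xd scores
#'
#' Convenience utility: given the tissue-specific Xd scores of one reference
#' set and a grouping of tissue labels, tests whether scores in the group of
#' interest are shifted upward (one-sided Wilcoxon rank-sum).
#'
#' @param tissue_scores named numeric vector (names = tissue labels).
#' @param group character vector of labels forming the group of interest.
#' @return `htest` object from [stats::wilcox.test()].
#' @export
compare_tissue_groups <- function(tissue_scores, group) {
  stopifnot(!is.null(names(tissue_scores)))
  inside <- names(tissue_scores) %in% group
  x <- tissue_scores[inside]; y <- tissue_scores[!inside]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both tissue groups need at least one finite score")
  }
  stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)
}
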