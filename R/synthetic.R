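# Synthetic-data generator with planted target<->pathway associations.
#
# The stated world: a heavy-tailed (preferential-attachment) base network with
# STRING-like confidence weights; disjoint reference pathways; a target set
# emulating a disease gene list — a graded overlap with a couple of "known"
# pathways (what makes the Xd-versus-q regression calibratable, mirroring the
# strong observed Xd/overlap-score correlation on real data) plus genes drawn
# uniformly from the network; and one or more planted pathways whose nodes
# gain extra high-confidence edges to the target nodes, emulating a dense
# sub-network of interactions that a network-aware statistic should detect
# even at low or zero overlap. Fully deterministic under the spec's seed.

#' Specification for a synthetic bundle
#'
#' @param n_nodes network size (default 300).
#' @param attachment edges added per node in the preferential-attachment
#'   model (default 2).
#' @param target_size target gene-set size (default 15).
#' @param pathway_sizes integer vector of reference-set sizes (default eight
#'   pathways of 30).
#' @param planted named numeric vector: wiring probability `p_conn` per
#'   planted pathway id (default `c(P1 = 0.3)`); each target x pathway node
#'   pair gains an edge with probability `p_conn`, weight U\[0.5, 1\].
#' @param overlap_members named integer vector: number of target members drawn
#'   from the given pathways' member lists
#'   (default `c(P2 = 6, P3 = 4, P4 = 3, P5 = 2)`), emulating a disease list
#'   whose genes hit a few known pathways with graded strength; any remaining
#'   target members are drawn uniformly from all nodes. The resulting spread
#'   of overlap q-values anchors the Xd-versus-q calibration, and with the
#'   default sizes the planted pathway keeps exactly zero overlap, so its
#'   association is purely network-driven.
#' @param topology `"preferential_attachment"` (default) or
#'   `"configuration"` (degree-sequence rewiring alternative).
#' @param planted_tissue label of the tissue covering the planted pathways'
#'   nodes (default `"brain"`).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 300L, attachment = 2L, target_size = 15L,
                           pathway_sizes = rep(30L, 8L),
                           planted = c(P1 = 0.3),
                           overlap_members = c(P2 = 6L, P3 = 4L, P4 = 3L, P5 = 2L),
                           topology = c("preferential_attachment", "configuration"),
                           planted_tissue = "brain", seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_nodes >= 2L, attachment >= 1L, target_size >= 1L,
            target_size <= n_nodes, all(pathway_sizes >= 1L),
            all(planted >= 0), all(planted <= 1), length(seed) == 1L)
  if (sum(pathway_sizes) > n_nodes) {
    stop("disjoint pathways cannot exceed the node count")
  }
  ids <- paste0("P", seq_along(pathway_sizes))
  if (!all(names(planted) %in% ids)) {
    stop("planted pathway ids must be among the generated pathway ids (P1, P2, ...)")
  }
  overlap_members <- overlap_members[names(overlap_members) %in% ids]
  storage.mode(overlap_members) <- "integer"
  if (sum(overlap_members) > target_size) {
    stop("overlap_members cannot exceed the target size")
  }
  if (any(overlap_members > pathway_sizes[match(names(overlap_members), ids)])) {
    stop("overlap_members cannot exceed the pathway sizes")
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 attachment = as.integer(attachment),
                 target_size = as.integer(target_size),
                 pathway_sizes = as.integer(pathway_sizes),
                 pathway_ids = ids,
                 planted = planted,
                 overlap_members = overlap_members,
                 topology = topology,
                 planted_tissue = planted_tissue,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic bundle
#'
#' Produces a weighted network, a target gene set, a reference collection and
#' tissue annotations. Base topology is scale-free (preferential attachment;
#' interactomes are heavy-tailed), base edge weights U\[0.15, 1\] echo a
#' STRING-like confidence spread, planted edges U\[0.5, 1\] mimic
#' high-confidence interactions. Tissue labels: the configured planted tissue
#' covers every planted pathway's nodes plus ~30% of the remaining nodes; a
#' second label `"generic"` covers an independent ~50% of all nodes. RNG
#' state is saved and restored, so generation is reproducible and
#' side-effect-free.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_bundle` with elements `network`
#'   (`xd_network`), `target` (`gene_set`), `collection`
#'   (`gene_set_collection`), `tissue` (`tissue_annotation`) and `spec`.
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_nodes
  node_ids <- sprintf("g%04d", seq_len(n))
  g <- igraph::sample_pa(n, power = 1, m = spec$attachment, directed = FALSE)
  if (spec$topology == "configuration") {
    g <- igraph::sample_degseq(igraph::degree(g), method = "fast.heur.simple")
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  base <- data.frame(node_a = node_ids[el[, 1L]], node_b = node_ids[el[, 2L]],
                     weight = stats::runif(nrow(el), 0.15, 1),
                     stringsAsFactors = FALSE)

  # disjoint pathways sampled from the node pool
  pool <- sample(node_ids)
  offsets <- cumsum(c(0L, spec$pathway_sizes))
  sets <- lapply(seq_along(spec$pathway_sizes), function(i) {
    gene_set(spec$pathway_ids[i],
             sort(pool[(offsets[i] + 1L):offsets[i + 1L]]),
             name = sprintf("synthetic pathway %d", i))
  })
  collection <- gene_set_collection(sets)

  # target = known-pathway members (graded overlap) + uniform novel genes
  from_pathways <- unlist(lapply(names(spec$overlap_members), function(pid) {
    sample(collection[[pid]]$members, spec$overlap_members[[pid]])
  }), use.names = FALSE)
  rest <- sample(setdiff(node_ids, from_pathways),
                 spec$target_size - length(from_pathways))
  target <- gene_set("target", sort(c(from_pathways, rest)))

  # planted wiring: dense high-confidence edges between target and pathway
  planted_edges <- list()
  for (pid in names(spec$planted)) {
    p_conn <- spec$planted[[pid]]
    if (p_conn <= 0) next
    pairs <- expand.grid(node_a = target$members,
                         node_b = collection[[pid]]$members,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$node_a != pairs$node_b, , drop = FALSE]
    hit <- stats::runif(nrow(pairs)) < p_conn
    if (any(hit)) {
      pe <- pairs[hit, , drop = FALSE]
      pe$weight <- stats::runif(nrow(pe), 0.5, 1)
      planted_edges[[pid]] <- pe
    }
  }
  edges <- rbind(base, do.call(rbind, planted_edges))
  network <- suppressWarnings(xd_network(edges, extra_nodes = node_ids))

  planted_nodes <- sort(unique(unlist(lapply(names(spec$planted), function(pid) {
    collection[[pid]]$members
  }))))
  others <- setdiff(node_ids, planted_nodes)
  tis_nodes <- sort(c(planted_nodes,
                      others[stats::runif(length(others)) < 0.3]))
  gen_nodes <- sort(node_ids[stats::runif(n) < 0.5])
  tissue <- tissue_annotation(data.frame(
    gene_id = c(tis_nodes, gen_nodes),
    tissue = c(rep(spec$planted_tissue, length(tis_nodes)),
               rep("generic", length(gen_nodes))),
    stringsAsFactors = FALSE))

  structure(list(network = network, target = target, collection = collection,
                 tissue = tissue, spec = spec),
            class = "synthetic_bundle")
}

#' Write a bundle as the plain-text fixture files the readers consume
#'
#' Writes `network.tsv` (edge list), `target.txt` (one id per line),
#' `pathways.gmt` and `tissues.tsv` into `dir`. Round-tripping these files
#' through the package readers reproduces the in-memory bundle.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if absent).
#' @return named character vector of the four paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             target = file.path(dir, "target.txt"),
             gmt = file.path(dir, "pathways.gmt"),
             tissue = file.path(dir, "tissues.tsv"))
  write_edge_list(bundle$network, paths[["network"]])
  writeLines(bundle$target$members, paths[["target"]])
  write_gmt(bundle$collection, paths[["gmt"]])
  utils::write.table(as.data.frame(bundle$tissue), paths[["tissue"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(paths)
}
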