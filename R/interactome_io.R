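# Network, gene-set and tissue-annotation I/O plus set-to-network mapping.
#
# Identifiers are opaque strings matched by exact, case-sensitive equality;
# identifier-space harmonization (symbol <-> Ensembl etc.) is out of scope and
# must be done upstream.

#' Construct an interaction network from an edge table
#'
#' Builds the weighted undirected network container used throughout the
#' package. Self-loops are dropped with a warning (public interactomes contain
#' them but they carry no propagation information), duplicate edges are
#' collapsed keeping the maximum weight (confidence scores: the conservative
#' choice toward connectivity), and all weights must lie in (0, 1].
#'
#' @param edges data.frame with columns `node_a`, `node_b` (character) and
#'   `weight` (numeric in (0, 1]).
#' @param extra_nodes optional character vector of node ids to include even if
#'   they touch no edge (isolated nodes).
#' @return An object of class `xd_network`: a list with `nodes` (sorted
#'   character vector) and `edges` (data.frame `node_a`, `node_b`, `weight`,
#'   canonicalized so `node_a < node_b`, sorted).
#' @export
xd_network <- function(edges, extra_nodes = character()) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L && length(extra_nodes) == 0L) {
    stop("network must contain at least one node")
  }
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  w <- as.numeric(edges$weight)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("node identifiers must be non-empty strings")
  }
  bad <- !is.finite(w) | w <= 0 | w > 1
  if (any(bad)) {
    stop(sprintf("%d edge weight(s) outside (0,1]: first offending value %s",
                 sum(bad), format(w[which(bad)[1L]])))
  }
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    a <- a[!loops]; b <- b[!loops]; w <- w[!loops]
  }
  # canonical order within each pair, then collapse duplicates by max weight
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  if (length(lo)) {
    key <- paste(lo, hi, sep = "\r")
    w <- vapply(split(w, key), max, numeric(1))
    first <- !duplicated(key)
    ed <- data.frame(node_a = lo[first], node_b = hi[first],
                     stringsAsFactors = FALSE)
    ed$weight <- as.numeric(w[paste(ed$node_a, ed$node_b, sep = "\r")])
    ed <- ed[order(ed$node_a, ed$node_b), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(node_a = character(), node_b = character(),
                     weight = numeric(), stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(ed$node_a, ed$node_b, as.character(extra_nodes))))
  structure(list(nodes = nodes, edges = ed), class = "xd_network")
}

#' @export
print.xd_network <- function(x, ...) {
  cat(sprintf("<xd_network> %d nodes, %d edges, weights in [%.3g, %.3g]\n",
              length(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) min(x$edges$weight) else NA,
              if (nrow(x$edges)) max(x$edges$weight) else NA))
  invisible(x)
}

#' Number of nodes / edge lookup helpers
#'
#' `edge_weight()` returns the weight of the undirected edge `(u, v)` or `NA`
#' if absent; lookup is symmetric in its arguments.
#'
#' @param net an `xd_network`.
#' @param u,v node identifiers.
#' @return numeric weight or `NA_real_`.
#' @export
edge_weight <- function(net, u, v) {
  lo <- pmin(u, v); hi <- pmax(u, v)
  i <- match(paste(lo, hi, sep = "\r"),
             paste(net$edges$node_a, net$edges$node_b, sep = "\r"))
  net$edges$weight[i]
}

#' Read a weighted edge list
#'
#' Parses a tab-separated edge list with two (node_a, node_b; weight defaults
#' to 1.0) or three (node_a, node_b, weight) columns. Lines starting with `#`
#' and blank lines are ignored. Raw STRING-style combined scores can be
#' rescaled into (0, 1] via `weight_scale` (e.g. 1000).
#'
#' @param path file path.
#' @param weight_scale optional positive divisor applied to all weights before
#'   validation.
#' @return an `xd_network`.
#' @export
read_edge_list <- function(path, weight_scale = NULL) {
  if (!file.exists(path)) stop(sprintf("edge list file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("edge list contains no data lines")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop(sprintf("malformed edge list line %d: expected 2 or 3 tab-separated fields, got %d",
                 keep[bad[1L]], nf[bad[1L]]))
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  w <- vapply(seq_along(parts), function(i) {
    if (nf[i] == 3L) {
      wi <- suppressWarnings(as.numeric(parts[[i]][3L]))
      if (is.na(wi)) stop(sprintf("malformed weight on edge list line %d: '%s'",
                                  keep[i], parts[[i]][3L]))
      wi
    } else 1.0
  }, numeric(1))
  if (!is.null(weight_scale)) {
    stopifnot(is.numeric(weight_scale), weight_scale > 0)
    w <- w / weight_scale
  }
  xd_network(data.frame(node_a = a, node_b = b, weight = w,
                        stringsAsFactors = FALSE))
}

#' Write a network back to an edge-list TSV
#'
#' Inverse of [read_edge_list()]: re-reading the written file yields an
#' identical network.
#'
#' @param net an `xd_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene set constructor
#'
#' @param set_id unique identifier within a collection.
#' @param members character vector of gene identifiers (deduplicated).
#' @param name human-readable description (defaults to `set_id`).
#' @return object of class `gene_set`.
#' @export
gene_set <- function(set_id, members, name = set_id) {
  stopifnot(is.character(set_id), length(set_id) == 1L, nzchar(set_id))
  members <- unique(as.character(members))
  if (length(members) == 0L) stop(sprintf("gene set '%s' has no members", set_id))
  structure(list(set_id = set_id, name = name, members = members),
            class = "gene_set")
}

#' Gene set collection constructor
#'
#' @param sets list of [gene_set()] objects; ids must be pairwise distinct.
#' @return object of class `gene_set_collection` (a named list of gene sets,
#'   order preserved).
#' @export
gene_set_collection <- function(sets = list()) {
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate set_id in collection: %s",
                 ids[duplicated(ids)][1L]))
  }
  names(sets) <- ids
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets\n", length(x)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `set_id TAB description TAB member...`.
#' Members are deduplicated within a set; file order is preserved. An empty
#' file yields an empty collection.
#'
#' @param path file path.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(f)))
    }
    gene_set(f[1L], f[-(1:2)], name = f[2L])
  })
  gene_set_collection(sets)
}

#' Write a collection to GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(s) {
    paste(c(s$set_id, s$name, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a target gene list (one identifier per line)
#'
#' `#` comments and blank lines are ignored; duplicates dropped.
#'
#' @param path file path.
#' @param set_id id for the resulting set.
#' @return a `gene_set`.
#' @export
read_gene_list <- function(path, set_id = "target") {
  if (!file.exists(path)) stop(sprintf("gene list file not found: %s", path))
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (length(ids) == 0L) stop("gene list is empty")
  gene_set(set_id, ids)
}

#' Read tissue annotations
#'
#' TSV with two columns, `gene_id` and `tissue_label`, one pair per row;
#' repeated gene ids accumulate labels.
#'
#' @param path file path.
#' @return object of class `tissue_annotation`: a data.frame with columns
#'   `gene_id`, `tissue`.
#' @export
read_tissue_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("tissue annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed tissue annotation line %d: expected 2 tab-separated fields",
                 keep[bad[1L]]))
  }
  tissue_annotation(data.frame(
    gene_id = vapply(parts, `[[`, character(1), 1L),
    tissue  = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE))
}

#' Tissue annotation constructor
#'
#' @param df data.frame with character columns `gene_id` and `tissue`.
#' @return object of class `tissue_annotation`.
#' @export
tissue_annotation <- function(df) {
  stopifnot(is.data.frame(df), all(c("gene_id", "tissue") %in% names(df)))
  if (any(!nzchar(df$gene_id)) || any(!nzchar(df$tissue))) {
    stop("tissue annotations require non-empty gene ids and labels")
  }
  df <- unique(df[, c("gene_id", "tissue")])
  rownames(df) <- NULL
  structure(df, class = c("tissue_annotation", "data.frame"))
}

#' Nodes annotated to a tissue
#'
#' @param ta a `tissue_annotation`.
#' @param label tissue label.
#' @return character vector of gene ids carrying `label`.
#' @export
tissue_nodes <- function(ta, label) {
  unique(ta$gene_id[ta$tissue == label])
}

#' Tissue labels present in an annotation
#' @param ta a `tissue_annotation`.
#' @return sorted character vector of labels.
#' @export
tissue_labels <- function(ta) sort(unique(ta$tissue))

#' Map a gene set onto a network
#'
#' Partitions the set's members into those present in the network (`mapped`)
#' and those absent (`unmapped`). A mapped size below `min_mapped` attaches a
#' warning for a target set (computation proceeds; the recommended minimum of
#' 10 identifiers is advisory) or flags the set unscorable for a reference
#' set. Degenerate cases are signalled via flags, never exceptions.
#'
#' @param gs a `gene_set`.
#' @param net an `xd_network`.
#' @param min_mapped minimum mapped size before flagging (>= 1).
#' @param role `"target"` (emit a warning when under-mapped) or `"reference"`
#'   (mark `unscorable`).
#' @return object of class `mapped_set`: list with `origin`, `mapped`,
#'   `unmapped`, `n_mapped`, `below_min`, `unscorable`.
#' @export
map_set <- function(gs, net, min_mapped = 10L, role = c("target", "reference")) {
  role <- match.arg(role)
  stopifnot(inherits(gs, "gene_set"), inherits(net, "xd_network"),
            min_mapped >= 1L)
  inside <- gs$members %in% net$nodes
  mapped <- gs$members[inside]
  unmapped <- gs$members[!inside]
  below <- length(mapped) < min_mapped
  unscorable <- if (role == "reference") length(mapped) == 0L || below else length(mapped) == 0L
  if (below && role == "target") {
    warning(sprintf("target set '%s': only %d of %d members map to the network (< %d recommended); proceeding",
                    gs$set_id, length(mapped), length(gs$members), min_mapped))
  }
  structure(list(origin = gs, mapped = mapped, unmapped = unmapped,
                 n_mapped = length(mapped), below_min = below,
                 unscorable = unscorable),
            class = "mapped_set")
}

#' Map every set of a collection onto a network
#'
#' Reference-set convenience wrapper around [map_set()]: a reference set is
#' scorable as soon as any member maps (`min_mapped = 1`).
#'
#' @param collection a `gene_set_collection`.
#' @param net an `xd_network`.
#' @param min_mapped minimum mapped members for a reference set to be scorable.
#' @return named list of `mapped_set` objects, collection order preserved.
#' @export
map_collection <- function(collection, net, min_mapped = 1L) {
  lapply(collection, map_set, net = net, min_mapped = min_mapped,
         role = "reference")
}
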