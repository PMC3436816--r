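# Annotated sub-network extraction and export: the static replacement for an
# interactive sub-network view. Nodes carry a role in
# {target, reference, shared, bridge}; exports are deterministic, layout is a
# downstream viewer's job.

#' Extract the annotated sub-network connecting a target and a reference set
#'
#' Induced subgraph on the union of the two mapped sets. With
#' `include_bridges = TRUE`, non-member nodes adjacent to at least one target
#' node and at least one reference node are added too, capturing the shared
#' network neighbourhood that drives high Xd scores at low overlap. Roles:
#' `shared` for nodes in both sets, `target`/`reference` for exclusive
#' members, `bridge` for added connectors.
#'
#' @param net an `xd_network`.
#' @param target,ref `mapped_set` objects mapped against `net`.
#' @param include_bridges add shared-neighbourhood connector nodes
#'   (default `FALSE`, matching minimal component views).
#' @return object of class `xd_subnetwork`: list with `nodes` (data.frame
#'   `node`, `role`, `component_id`) and `edges` (data.frame `node_a`,
#'   `node_b`, `weight`). Components are numbered by decreasing size, ties
#'   broken by lexicographically smallest member.
#' @export
extract_subnetwork <- function(net, target, ref, include_bridges = FALSE) {
  stopifnot(inherits(net, "xd_network"),
            inherits(target, "mapped_set"), inherits(ref, "mapped_set"))
  tset <- target$mapped
  rset <- ref$mapped
  members <- union(tset, rset)
  if (length(members) == 0L) stop("both sets are empty after mapping")
  keep <- members
  roles <- ifelse(keep %in% tset & keep %in% rset, "shared",
                  ifelse(keep %in% tset, "target", "reference"))
  names(roles) <- keep
  if (include_bridges) {
    ed <- net$edges
    touch_t <- union(ed$node_b[ed$node_a %in% tset], ed$node_a[ed$node_b %in% tset])
    touch_r <- union(ed$node_b[ed$node_a %in% rset], ed$node_a[ed$node_b %in% rset])
    bridges <- setdiff(intersect(touch_t, touch_r), members)
    if (length(bridges)) {
      roles <- c(roles, stats::setNames(rep("bridge", length(bridges)), bridges))
      keep <- c(keep, bridges)
    }
  }
  ed <- net$edges
  sub_e <- ed[ed$node_a %in% keep & ed$node_b %in% keep, , drop = FALSE]
  rownames(sub_e) <- NULL
  nodes <- sort(keep)
  comp <- component_ids(nodes, sub_e)
  nd <- data.frame(node = nodes, role = unname(roles[nodes]),
                   component_id = comp, stringsAsFactors = FALSE)
  structure(list(nodes = nd, edges = sub_e), class = "xd_subnetwork")
}

# Connected components numbered by decreasing size; ties by the
# lexicographically smallest member id.
component_ids <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = nodes))
  cm <- igraph::components(g)$membership[nodes]
  reps <- vapply(split(nodes, cm), min, character(1))
  sizes <- table(cm)
  ord <- order(-as.integer(sizes[names(reps)]), reps)
  relabel <- stats::setNames(seq_along(ord), names(reps)[ord])
  as.integer(relabel[as.character(cm)])
}

#' @export
print.xd_subnetwork <- function(x, ...) {
  cat(sprintf("<xd_subnetwork> %d nodes (%s), %d edges, %d component(s)\n",
              nrow(x$nodes),
              paste(sprintf("%s:%d", names(table(x$nodes$role)),
                            as.integer(table(x$nodes$role))), collapse = " "),
              nrow(x$edges), max(x$nodes$component_id)))
  invisible(x)
}

#' Restrict a sub-network to its largest connected component
#'
#' @param sub an `xd_subnetwork`.
#' @return the `xd_subnetwork` restricted to component 1 (largest; size ties
#'   resolved toward the component containing the lexicographically smallest
#'   node id).
#' @export
largest_component <- function(sub) {
  stopifnot(inherits(sub, "xd_subnetwork"), nrow(sub$nodes) > 0L)
  keep <- sub$nodes$node[sub$nodes$component_id == 1L]
  nd <- sub$nodes[sub$nodes$node %in% keep, , drop = FALSE]
  nd$component_id <- 1L
  ed <- sub$edges[sub$edges$node_a %in% keep & sub$edges$node_b %in% keep, ,
                  drop = FALSE]
  rownames(nd) <- rownames(ed) <- NULL
  structure(list(nodes = nd, edges = ed), class = "xd_subnetwork")
}

#' Write an annotated sub-network to disk
#'
#' `fmt = "graphml"` writes one GraphML file with node attributes `role` and
#' `component_id` and edge attribute `weight`. `fmt = "tsv"` writes a pair of
#' files `<path>_nodes.tsv` / `<path>_edges.tsv`. Both round-trip losslessly
#' through [read_subnetwork()].
#'
#' @param sub an `xd_subnetwork`.
#' @param path output path (for `"tsv"`, a prefix).
#' @param fmt `"graphml"` or `"tsv"`.
#' @return the path(s) written, invisibly.
#' @export
write_subnetwork <- function(sub, path, fmt = c("graphml", "tsv")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(sub, "xd_subnetwork"))
  if (fmt == "graphml") {
    g <- igraph::graph_from_data_frame(sub$edges, directed = FALSE,
                                       vertices = sub$nodes)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
  } else {
    paths <- paste0(path, c("_nodes.tsv", "_edges.tsv"))
    utils::write.table(sub$nodes, paths[1L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sub$edges, paths[2L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
  }
}

#' Read an annotated sub-network back from disk
#'
#' @param path path (or prefix for `"tsv"`) previously given to
#'   [write_subnetwork()].
#' @param fmt `"graphml"` or `"tsv"`.
#' @return an `xd_subnetwork`.
#' @export
read_subnetwork <- function(path, fmt = c("graphml", "tsv")) {
  fmt <- match.arg(fmt)
  if (fmt == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nd <- data.frame(node = igraph::V(g)$name,
                     role = igraph::V(g)$role,
                     component_id = as.integer(igraph::V(g)$component_id),
                     stringsAsFactors = FALSE)
    el <- igraph::as_data_frame(g, what = "edges")
    ed <- data.frame(node_a = pmin(el$from, el$to),
                     node_b = pmax(el$from, el$to),
                     weight = as.numeric(el$weight),
                     stringsAsFactors = FALSE)
  } else {
    nd <- utils::read.table(paste0(path, "_nodes.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "integer"))
    ed <- utils::read.table(paste0(path, "_edges.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "numeric"))
  }
  nd <- nd[order(nd$node), , drop = FALSE]
  ed <- ed[order(ed$node_a, ed$node_b), , drop = FALSE]
  rownames(nd) <- rownames(ed) <- NULL
  structure(list(nodes = nd, edges = ed), class = "xd_subnetwork")
}
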