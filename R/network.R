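#' Build the putative-target / disease-target interaction network
#'
#' Seeds the network with the union of putative and disease targets and
#' expands it over the merged PPI. Under the default `first_neighbor` rule
#' the node set is the seeds plus every direct PPI partner of a seed, and
#' the edges are all PPI edges with both endpoints in that node set — the
#' smallest rule that admits linker ("interactional") proteins. `seed_only`
#' keeps PPI edges among the seeds themselves; `full_ppi` keeps the whole
#' PPI plus any isolated seeds. Seeds absent from the PPI are retained as
#' degree-0 nodes so that target accounting stays exact.
#'
#' @param putative [TargetSet-class] of putative remedy targets.
#' @param disease [TargetSet-class] of known therapeutic targets.
#' @param ppi merged [EdgeTable-class].
#' @param expansionRule `"first_neighbor"` (default), `"seed_only"` or
#'   `"full_ppi"`.
#' @return An [InteractionNetwork-class] with node classes assigned by
#'   [classifyNodes()].
#' @export
buildInteractionNetwork <- function(putative, disease, ppi,
                                    expansionRule = c("first_neighbor",
                                                      "seed_only",
                                                      "full_ppi")) {
  expansionRule <- match.arg(expansionRule)
  seeds <- union(targetIds(putative), targetIds(disease))
  if (!length(seeds)) stop("empty seed union: no putative or disease targets")
  e <- ppi@edges
  nodes <- switch(expansionRule,
    seed_only = seeds,
    first_neighbor = {
      touch <- e$from %in% seeds | e$to %in% seeds
      union(seeds, unique(c(e$from[touch], e$to[touch])))
    },
    full_ppi = union(seeds, unique(c(e$from, e$to))))
  keep <- e$from %in% nodes & e$to %in% nodes
  g <- igraph::graph_from_data_frame(e[keep, c("from", "to"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  net <- new("InteractionNetwork", graph = .labelGraph(g, putative, disease))
  cl <- table(nodeClasses(net))
  message(sprintf("network: %d nodes, %d edges (%s)", igraph::vcount(g),
                  igraph::ecount(g),
                  paste(sprintf("%s=%d", names(cl), as.integer(cl)),
                        collapse = ", ")))
  net
}

.labelGraph <- function(g, putative, disease) {
  ids <- as.character(igraph::V(g)$name)
  p <- ids %in% targetIds(putative)
  d <- ids %in% targetIds(disease)
  igraph::set_vertex_attr(g, "nodeClass",
                          value = ifelse(p & d, "both",
                                  ifelse(p, "putative",
                                  ifelse(d, "disease", "linker"))))
}

#' (Re)assign node class labels
#'
#' Partitions the node set: ids in both target sets are `both`, ids in only
#' one are `putative` / `disease`, the remainder are `linker`. The partition
#' is total and exclusive.
#'
#' @param network an [InteractionNetwork-class].
#' @param putative,disease [TargetSet-class] objects.
#' @return The relabelled [InteractionNetwork-class].
#' @export
classifyNodes <- function(network, putative, disease) {
  new("InteractionNetwork",
      graph = .labelGraph(network@graph, putative, disease))
}

#' Construct an InteractionNetwork from raw pieces
#'
#' Convenience constructor used by the generators and the null model: builds
#' a simple undirected graph on `nodes` with the given edges and class
#' labels (default all `linker`).
#'
#' @param nodes character vector of node ids.
#' @param edges data.frame with columns `from`, `to` (subset of `nodes`).
#' @param classes named character of class labels (missing ids -> linker).
#' @return An [InteractionNetwork-class].
#' @export
interactionNetwork <- function(nodes, edges = data.frame(from = character(),
                                                         to = character()),
                               classes = NULL) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  lab <- rep("linker", length(nodes))
  names(lab) <- nodes
  if (!is.null(classes)) lab[names(classes)] <- classes
  g <- igraph::set_vertex_attr(g, "nodeClass",
                               value = unname(lab[as.character(igraph::V(g)$name)]))
  new("InteractionNetwork", graph = g)
}

#' Summarize an interaction network
#'
#' @param network an [InteractionNetwork-class].
#' @return list with `nNodes`, `nEdges`, `classCounts` (named integer over
#'   all four classes), `nComponents`, `medianDegree`.
#' @export
networkSummary <- function(network) {
  g <- network@graph
  n <- igraph::vcount(g)
  cl <- table(factor(igraph::V(g)$nodeClass, levels = .NODE_CLASSES))
  list(nNodes = as.integer(n),
       nEdges = as.integer(igraph::ecount(g)),
       classCounts = stats::setNames(as.integer(cl), names(cl)),
       nComponents = if (n) as.integer(igraph::count_components(g)) else 0L,
       medianDegree = if (n) as.numeric(stats::median(igraph::degree(g))) else 0)
}

#' Export a network for external viewers
#'
#' GraphML carries the `nodeClass` label as a node attribute and round-trips
#' node and edge sets exactly through [readNetwork()]; SIF is a plain
#' one-edge-per-line format (`a pp b`) in which isolated nodes appear as
#' single-field lines and attributes are not representable.
#'
#' @param network an [InteractionNetwork-class].
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  g <- network@graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character()
    iso <- setdiff(as.character(igraph::V(g)$name), unique(c(el)))
    writeLines(c(lines, iso), path)
  }
  invisible(path)
}

#' Re-import a GraphML network
#'
#' @param path GraphML file written by [writeNetwork()] (or any GraphML
#'   whose nodes carry `name`; a missing `nodeClass` attribute defaults to
#'   `linker`).
#' @return An [InteractionNetwork-class].
#' @export
readNetwork <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::V(g)$nodeClass))
    g <- igraph::set_vertex_attr(g, "nodeClass", value = "linker")
  new("InteractionNetwork", graph = g)
}
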