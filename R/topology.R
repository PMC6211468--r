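.asGraph <- function(x) {
  if (is(x, "InteractionNetwork")) x@graph
  else if (igraph::is_igraph(x)) x
  else stop("expected an InteractionNetwork or igraph object")
}

#' Node degree
#'
#' Number of links incident to each node.
#'
#' @param x an [InteractionNetwork-class] or igraph.
#' @return named integer vector.
#' @export
computeDegree <- function(x) {
  g <- .asGraph(x)
  d <- igraph::degree(g, loops = FALSE)
  stats::setNames(as.integer(d), as.character(igraph::V(g)$name))
}

#' Node betweenness
#'
#' Fraction-weighted count of shortest paths running through each node
#' (endpoints excluded): for each pair (s, t) a node i on their geodesics
#' contributes the fraction of s-t shortest paths passing through it.
#' Normalization divides by the pair count `(n-1)(n-2)/2`; graphs with fewer
#' than 3 nodes have no interior pairs and return zeros.
#'
#' @param x an [InteractionNetwork-class] or igraph.
#' @param normalized divide by `(n-1)(n-2)/2` (default `TRUE`).
#' @return named numeric vector.
#' @export
computeBetweenness <- function(x, normalized = TRUE) {
  g <- .asGraph(x)
  n <- igraph::vcount(g)
  b <- if (n) igraph::betweenness(g, directed = FALSE) else numeric()
  if (normalized) {
    b <- if (n < 3) rep(0, n) else b / ((n - 1) * (n - 2) / 2)
  }
  stats::setNames(as.numeric(b), as.character(igraph::V(g)$name))
}

#' Node closeness
#'
#' Inverse of the summed shortest-path distance from a node to the others.
#' Disconnected graphs use the component-restricted form with
#' Wasserman-Faust scaling by default: for node i in a component of size r,
#' `((r-1)/(n-1)) * ((r-1)/sum of distances within the component)`, which
#' reduces to ordinary normalized closeness on a connected graph, is bounded
#' in `[0, 1]`, and sends isolated nodes to 0. The `"harmonic"` rule
#' (`mean of 1/d(i,j)` over all other nodes, unreachable contributing 0) is
#' available as an alternative convention.
#'
#' @param x an [InteractionNetwork-class] or igraph.
#' @param rule `"component"` (Wasserman-Faust, default) or `"harmonic"`.
#' @return named numeric vector in `[0, 1]`.
#' @export
computeCloseness <- function(x, rule = c("component", "harmonic")) {
  rule <- match.arg(rule)
  g <- .asGraph(x)
  n <- igraph::vcount(g)
  out <- numeric(n)
  if (n > 1) {
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      idx <- which(comp$membership == ci)
      r <- length(idx)
      if (r == 1) next
      D <- igraph::distances(g, v = idx, to = idx)
      if (rule == "component") {
        out[idx] <- ((r - 1) / (n - 1)) * ((r - 1) / rowSums(D))
      } else {
        iD <- 1 / D; diag(iD) <- 0
        out[idx] <- rowSums(iD) / (n - 1)
      }
    }
  }
  stats::setNames(out, as.character(igraph::V(g)$name))
}

#' Node coreness (k-core shell index)
#'
#' The k-core of a graph is the maximal subgraph in which every node has at
#' least k neighbors within it, obtained by repeatedly deleting nodes of
#' degree below k; a node's coreness is the largest k for which it survives.
#'
#' @param x an [InteractionNetwork-class] or igraph.
#' @return named integer vector.
#' @export
computeCoreness <- function(x) {
  g <- .asGraph(x)
  stats::setNames(as.integer(igraph::coreness(g)),
                  as.character(igraph::V(g)$name))
}

#' Profile all four topological parameters on one graph
#'
#' Degree, normalized betweenness, closeness and coreness, evaluated on the
#' same graph; `scope` records which graph this was (the major-hub screen
#' profiles the hub-induced subnetwork).
#'
#' @param x an [InteractionNetwork-class] or igraph.
#' @param scope free-text label of the profiled graph.
#' @param closenessRule passed to [computeCloseness()].
#' @return A [TopologyProfile-class].
#' @export
profileTopology <- function(x, scope = "full", closenessRule = "component") {
  g <- .asGraph(x)
  ids <- as.character(igraph::V(g)$name)
  new("TopologyProfile",
      data = data.frame(id = ids,
                        degree = unname(computeDegree(g)),
                        betweenness = unname(computeBetweenness(g)),
                        closeness = unname(computeCloseness(g, closenessRule)),
                        coreness = unname(computeCoreness(g)),
                        stringsAsFactors = FALSE),
      scope = scope)
}
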