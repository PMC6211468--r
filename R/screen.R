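#' Select hubs by the twofold-median degree rule
#'
#' A node is a hub when its degree strictly exceeds `hubFactor` times the
#' median degree of ALL nodes of the network (default factor 2). With a
#' median degree of 1 — typical of sparse PPI unions — the cutoff is 2, i.e.
#' nodes of degree <= 2 are removed.
#'
#' @param x an [InteractionNetwork-class], igraph, or [TopologyProfile-class]
#'   computed over the full network.
#' @param hubFactor multiplier on the median degree (default 2).
#' @return character vector of hub ids.
#' @export
setGeneric("selectHubs", function(x, hubFactor = 2) standardGeneric("selectHubs"))

#' @rdname selectHubs
setMethod("selectHubs", "TopologyProfile", function(x, hubFactor = 2) {
  d <- stats::setNames(x@data$degree, x@data$id)
  .hubFilter(d, hubFactor)
})

#' @rdname selectHubs
setMethod("selectHubs", "InteractionNetwork", function(x, hubFactor = 2) {
  .hubFilter(computeDegree(x), hubFactor)
})

#' @rdname selectHubs
setMethod("selectHubs", "ANY", function(x, hubFactor = 2) {
  if (igraph::is_igraph(x)) return(.hubFilter(computeDegree(x), hubFactor))
  stop("selectHubs: unsupported input")
})

.hubFilter <- function(degrees, hubFactor) {
  if (!length(degrees)) return(character())
  cutoff <- hubFactor * stats::median(degrees)
  names(degrees)[degrees > cutoff]
}

#' Vertex-induced hub subnetwork
#'
#' The subgraph of direct interactions among the given hubs: all of their
#' pairwise edges, nothing else.
#'
#' @param network an [InteractionNetwork-class].
#' @param hubIds node ids (must be nodes of `network`).
#' @return An [InteractionNetwork-class].
#' @export
hubSubnetwork <- function(network, hubIds) {
  g <- network@graph
  miss <- setdiff(hubIds, as.character(igraph::V(g)$name))
  if (length(miss)) stop("hub ids not in network: ", paste(head(miss, 3),
                                                           collapse = ", "))
  new("InteractionNetwork",
      graph = igraph::induced_subgraph(g, hubIds))
}

#' Construct screening thresholds
#'
#' @param degreeMin,betweennessMin,closenessMin,corenessMin strict lower
#'   bounds on the four topological parameters.
#' @param hubFactor first-stage multiplier on the median degree.
#' @param mode `"explicit"` or `"median_derived"`.
#' @return A [ScreenThresholds-class].
#' @export
screenThresholds <- function(degreeMin, betweennessMin, closenessMin,
                             corenessMin, hubFactor = 2, mode = "explicit") {
  th <- as.numeric(c(degreeMin, betweennessMin, closenessMin, corenessMin))
  if (any(!is.finite(th))) stop("thresholds must be finite")
  new("ScreenThresholds", hubFactor = as.numeric(hubFactor),
      degreeMin = th[1], betweennessMin = th[2], closenessMin = th[3],
      corenessMin = th[4], mode = mode)
}

#' Reference thresholds of the ZJW-gastritis screen
#'
#' The explicit cutoffs used in the Zuojin Wan (ZJW) gastritis network
#' analysis: degree > 4, betweenness > 0.0002, closeness > 0.3919,
#' coreness > 5, with the twofold-median hub rule. Betweenness and closeness
#' are on the normalized `[0, 1]` scale of [profileTopology()]; since the
#' original normalization and disconnected-graph conventions were not
#' published, treat this preset as a convention, not ground truth.
#'
#' @return A [ScreenThresholds-class].
#' @export
zjwThresholds <- function() {
  screenThresholds(degreeMin = 4, betweennessMin = 0.0002,
                   closenessMin = 0.3919, corenessMin = 5,
                   hubFactor = 2, mode = "explicit")
}

#' Derive median thresholds from a profile
#'
#' Thresholds are the medians of the four metrics over the profiled graph
#' (even counts: mean of the two central order statistics); with the strict
#' `>` filter of [selectMajorHubs()] this keeps nodes above the median on
#' every parameter.
#'
#' @param profile a non-empty [TopologyProfile-class].
#' @param hubFactor carried into the result for bookkeeping.
#' @return A [ScreenThresholds-class] with `mode = "median_derived"`.
#' @export
deriveMedianThresholds <- function(profile, hubFactor = 2) {
  d <- profile@data
  if (!nrow(d)) stop("cannot derive thresholds from an empty profile")
  screenThresholds(degreeMin = stats::median(d$degree),
                   betweennessMin = stats::median(d$betweenness),
                   closenessMin = stats::median(d$closeness),
                   corenessMin = stats::median(d$coreness),
                   hubFactor = hubFactor, mode = "median_derived")
}

#' Select major hubs from a hub-subnetwork profile
#'
#' Keeps the nodes whose four topological parameters ALL strictly exceed
#' the thresholds.
#'
#' @param profile [TopologyProfile-class], normally over the hub subnetwork.
#' @param thresholds a [ScreenThresholds-class].
#' @param network optional [InteractionNetwork-class] supplying node class
#'   labels for the per-class counts.
#' @param hubNetwork optional hub subnetwork stored in the result (defaults
#'   to `network`).
#' @return A [HubScreenResult-class]; `hubIds` are the profiled nodes.
#' @export
selectMajorHubs <- function(profile, thresholds, network = NULL,
                            hubNetwork = NULL) {
  d <- profile@data
  keep <- d$degree > thresholds@degreeMin &
    d$betweenness > thresholds@betweennessMin &
    d$closeness > thresholds@closenessMin &
    d$coreness > thresholds@corenessMin
  major <- d$id[keep]
  counts <- integer(0)
  if (!is.null(network)) {
    cl <- nodeClasses(network)
    counts <- stats::setNames(
      as.integer(table(factor(cl[major], levels = .NODE_CLASSES))),
      .NODE_CLASSES)
  }
  if (is.null(hubNetwork))
    hubNetwork <- if (!is.null(network)) network else
      interactionNetwork(d$id)
  new("HubScreenResult", hubIds = d$id, majorHubIds = major,
      hubNetwork = hubNetwork, profile = profile, thresholds = thresholds,
      classCounts = counts)
}

#' Two-stage hub / major-hub screen
#'
#' Stage 1 keeps nodes whose degree strictly exceeds `hubFactor` times the
#' median degree of the full network; stage 2 profiles the hub-induced
#' subnetwork (degree, normalized betweenness, closeness, coreness) and
#' keeps the hubs strictly above all four thresholds — the medians of the
#' hub-subnetwork metrics by default, or explicit cutoffs such as
#' [zjwThresholds()].
#'
#' @param network an [InteractionNetwork-class].
#' @param hubFactor stage-1 multiplier on the median degree (default 2).
#' @param thresholds `NULL` (median-derived, default) or a
#'   [ScreenThresholds-class].
#' @param closenessRule passed to [profileTopology()].
#' @return A [HubScreenResult-class]. A network with no hubs yields an
#'   empty result whose thresholds are `+Inf` sentinels.
#' @export
screenHubs <- function(network, hubFactor = 2, thresholds = NULL,
                       closenessRule = "component") {
  hubs <- selectHubs(network, hubFactor)
  if (!length(hubs)) {
    empty <- new("ScreenThresholds", hubFactor = hubFactor, degreeMin = Inf,
                 betweennessMin = Inf, closenessMin = Inf, corenessMin = Inf,
                 mode = if (is.null(thresholds)) "median_derived" else
                   thresholds@mode)
    return(new("HubScreenResult", hubIds = character(),
               majorHubIds = character(),
               hubNetwork = interactionNetwork(character()),
               profile = profileTopology(igraph::make_empty_graph(0,
                 directed = FALSE), scope = "hub_subnetwork"),
               thresholds = empty, classCounts = integer(0)))
  }
  hubNet <- hubSubnetwork(network, hubs)
  prof <- profileTopology(hubNet, scope = "hub_subnetwork",
                          closenessRule = closenessRule)
  if (is.null(thresholds))
    thresholds <- deriveMedianThresholds(prof, hubFactor)
  selectMajorHubs(prof, thresholds, network = network, hubNetwork = hubNet)
}

#' Export a screen result as a per-node table
#'
#' @param result a [HubScreenResult-class].
#' @param network the screened [InteractionNetwork-class] (for class labels).
#' @return data.frame: id, class, the four metrics, `isHub`, `isMajorHub`.
#' @export
screenTable <- function(result, network) {
  cl <- nodeClasses(network)
  d <- result@profile@data
  data.frame(id = d$id, class = unname(cl[d$id]),
             degree = d$degree, betweenness = d$betweenness,
             closeness = d$closeness, coreness = d$coreness,
             isHub = d$id %in% result@hubIds,
             isMajorHub = d$id %in% result@majorHubIds,
             stringsAsFactors = FALSE)
}
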