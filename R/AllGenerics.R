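#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x the object.
#' @return `targetIds`: character vector of target ids. `targetEntries`: the
#'   underlying data.frame. `edgeTable`: the edge data.frame. `nodeIds`:
#'   vertex names. `nodeClasses`: named character of node class labels.
#'   `nodeCount` / `edgeCount`: integers. `asIgraph`: the underlying igraph.
#'   `pathwayList`: named list of member id vectors. `pathwayUniverse`:
#'   character. `profileTable` / `enrichmentTable`: the result data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))
#' @rdname accessors
#' @export
setGeneric("targetEntries", function(x) standardGeneric("targetEntries"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("nodeClasses", function(x) standardGeneric("nodeClasses"))
#' @rdname accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))
#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
#' @rdname accessors
#' @export
setGeneric("pathwayList", function(x) standardGeneric("pathwayList"))
#' @rdname accessors
#' @export
setGeneric("pathwayUniverse", function(x) standardGeneric("pathwayUniverse"))
#' @rdname accessors
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))
#' @rdname accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname accessors
setMethod("targetIds", "TargetSet", function(x) x@entries$id)
#' @rdname accessors
setMethod("targetEntries", "TargetSet", function(x) x@entries)
#' @rdname accessors
setMethod("edgeTable", "EdgeTable", function(x) x@edges)
#' @rdname accessors
setMethod("nodeIds", "InteractionNetwork",
          function(x) as.character(igraph::V(x@graph)$name))
#' @rdname accessors
setMethod("nodeClasses", "InteractionNetwork", function(x) {
  g <- x@graph
  stats::setNames(as.character(igraph::V(g)$nodeClass),
                  as.character(igraph::V(g)$name))
})
#' @rdname accessors
setMethod("nodeCount", "InteractionNetwork",
          function(x) as.integer(igraph::vcount(x@graph)))
#' @rdname accessors
setMethod("edgeCount", "InteractionNetwork",
          function(x) as.integer(igraph::ecount(x@graph)))
#' @rdname accessors
setMethod("asIgraph", "InteractionNetwork", function(x) x@graph)
#' @rdname accessors
setMethod("pathwayList", "PathwayAnnotation", function(x) x@sets)
#' @rdname accessors
setMethod("pathwayUniverse", "PathwayAnnotation", function(x) x@universe)
#' @rdname accessors
setMethod("profileTable", "TopologyProfile", function(x) x@data)
#' @rdname accessors
setMethod("enrichmentTable", "EnrichmentResult", function(x) x@table)

#' @rdname accessors
setMethod("length", "TargetSet", function(x) nrow(x@entries))
#' @rdname accessors
setMethod("length", "PathwayAnnotation", function(x) length(x@sets))

setMethod("show", "TargetSet", function(object) {
  cat(sprintf("TargetSet with %d targets (%d source labels)\n",
              nrow(object@entries),
              length(unique(unlist(strsplit(object@entries$source, ";"))))))
  if (nrow(object@entries))
    print(utils::head(object@entries, 5), row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "EdgeTable", function(object) {
  cat(sprintf("EdgeTable with %d undirected edges over %d ids\n",
              nrow(object@edges),
              length(unique(c(object@edges$from, object@edges$to)))))
  invisible(NULL)
})

setMethod("show", "PathwayAnnotation", function(object) {
  sz <- lengths(object@sets)
  cat(sprintf("PathwayAnnotation: %d pathways over %d ids", length(sz),
              length(object@universe)))
  if (length(sz)) cat(sprintf(" (sizes %d-%d)", min(sz), max(sz)))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "InteractionNetwork", function(object) {
  cl <- nodeClasses(object)
  cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
              nodeCount(object), edgeCount(object)))
  if (length(cl)) {
    tab <- table(factor(cl, levels = .NODE_CLASSES))
    cat("  node classes:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(NULL)
})

setMethod("show", "TopologyProfile", function(object) {
  cat(sprintf("TopologyProfile over %d nodes (scope: %s)\n",
              nrow(object@data), object@scope))
  if (nrow(object@data))
    print(utils::head(object@data, 5), row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "ScreenThresholds", function(object) {
  cat(sprintf(paste0("ScreenThresholds (%s): degree > %g, betweenness > %g, ",
                     "closeness > %g, coreness > %g; hub factor %g\n"),
              object@mode, object@degreeMin, object@betweennessMin,
              object@closenessMin, object@corenessMin, object@hubFactor))
  invisible(NULL)
})

setMethod("show", "HubScreenResult", function(object) {
  cat(sprintf("HubScreenResult: %d hubs -> %d major hubs\n",
              length(object@hubIds), length(object@majorHubIds)))
  if (length(object@classCounts))
    cat("  major hubs by class:",
        paste(sprintf("%s=%d", names(object@classCounts), object@classCounts),
              collapse = ", "), "\n")
  show(object@thresholds)
  invisible(NULL)
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %d pathways tested (universe %d, query %d)\n",
              nrow(object@table), object@universeSize, object@querySize))
  cat(sprintf("  %d with p < 0.05, %d with q < 0.05\n",
              sum(object@table$p < 0.05), sum(object@table$q < 0.05)))
  invisible(NULL)
})

setMethod("show", "NullModelReport", function(object) {
  cat(sprintf(paste0("NullModelReport: real major-hub count %d vs %d G(n,m) ",
                     "replicates\n  replicate counts: median %g, max %g; ",
                     "exceedance %.3f (thresholds: %s)\n"),
              object@realCount, object@nReplicates,
              stats::median(object@replicateCounts),
              max(object@replicateCounts, 0), object@exceedance,
              object@thresholdMode))
  invisible(NULL)
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0("SyntheticConfig: %d nodes / %d edges; herb targets ",
                     "%d + %d (overlap %d); %d disease targets; %d planted ",
                     "hubs (degree %d); %d pathways (%d planted); seed %d\n"),
              object@nNodes, object@nEdges, object@nTargetsHerbA,
              object@nTargetsHerbB, object@nOverlap, object@nDiseaseTargets,
              object@nPlantedHubs, object@plantedHubDegree, object@nPathways,
              object@nPlantedPathways, object@seed))
  invisible(NULL)
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset\n")
  show(object@ppi)
  cat(sprintf("  herb A: %d, herb B: %d, disease: %d targets\n",
              length(object@herbA), length(object@herbB),
              length(object@disease)))
  cat(sprintf("  %d pathways (%d planted); %d planted hubs\n",
              length(object@geneSets), length(object@truth$plantedPathways),
              length(object@truth$plantedHubs)))
  invisible(NULL)
})
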