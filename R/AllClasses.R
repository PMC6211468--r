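#' @import methods
#' @importFrom stats median p.adjust phyper quantile sd
#' @importFrom utils read.delim write.table head
NULL

setOldClass("igraph")

#' TargetSet: a deduplicated table of molecular targets
#'
#' Container for one provenance-labelled set of targets (putative targets of
#' a herb, or known therapeutic targets of a disease). Identifiers are opaque
#' strings (gene symbols or protein accessions), trimmed and upper-cased at
#' ingest; each id appears once.
#'
#' @slot entries data.frame with columns `id`, `symbol`, `source` (and any
#'   extra columns carried through from the input table).
#' @seealso [readTargetTable()], [mergeTargetSets()], [intersectTargetSets()]
#' @export
setClass("TargetSet", representation(entries = "data.frame"))

setValidity("TargetSet", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("id", "symbol", "source")
  if (!all(need %in% names(e)))
    msg <- c(msg, paste("entries must have columns", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(e$id)) msg <- c(msg, "duplicate ids in TargetSet")
    if (any(!nzchar(e$id))) msg <- c(msg, "empty ids not allowed")
    if (any(!nzchar(e$source))) msg <- c(msg, "empty source labels not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' EdgeTable: a normalized undirected edge list
#'
#' Unordered id pairs with per-edge provenance. Orientation is normalized
#' (`from` < `to` lexically), self-loops are excluded, and each pair is
#' stored once; merging concatenates source labels.
#'
#' @slot edges data.frame with columns `from`, `to`, `sources` (`;`-joined
#'   provenance labels).
#' @seealso [readEdgeList()], [mergePpiSources()]
#' @export
setClass("EdgeTable", representation(edges = "data.frame"))

setValidity("EdgeTable", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "sources") %in% names(e)))
    return("edges must have columns from, to, sources")
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops not allowed")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be orientation-normalized (from < to)")
    if (anyDuplicated(paste(e$from, e$to))) msg <- c(msg, "duplicate edges not allowed")
    if (any(!nzchar(e$from)) || any(!nzchar(e$to))) msg <- c(msg, "empty ids not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' PathwayAnnotation: named gene sets over an id universe
#'
#' @slot sets named list; each element a character vector of member ids.
#' @slot universe character vector of all ids the annotation knows about.
#' @seealso [readGeneSets()], [enrich()]
#' @export
setClass("PathwayAnnotation",
         representation(sets = "list", universe = "character"))

setValidity("PathwayAnnotation", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
      msg <- c(msg, "all pathways must be named")
    if (anyDuplicated(names(object@sets))) msg <- c(msg, "duplicate pathway names")
    members <- unique(unlist(object@sets, use.names = FALSE))
    if (!all(members %in% object@universe))
      msg <- c(msg, "pathway members must lie in the universe")
  }
  if (length(msg)) msg else TRUE
})

#' InteractionNetwork: the putative/disease/linker interaction graph
#'
#' A simple undirected graph whose vertices carry a `nodeClass` attribute
#' with one of four exclusive labels: `putative` (target of the remedy only),
#' `disease` (known therapeutic target only), `both`, or `linker`
#' (interactional protein connecting the seed targets).
#'
#' @slot graph an `igraph` object; vertex attributes `name` and `nodeClass`.
#' @seealso [buildInteractionNetwork()], [networkSummary()], [screenHubs()]
#' @export
setClass("InteractionNetwork", representation(graph = "igraph"))

.NODE_CLASSES <- c("putative", "disease", "both", "linker")

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    msg <- c(msg, "graph must be simple (no loops or multi-edges)")
  if (is.null(igraph::V(g)$name) && igraph::vcount(g) > 0)
    msg <- c(msg, "vertices must be named")
  cl <- igraph::V(g)$nodeClass
  if (igraph::vcount(g) > 0 && (is.null(cl) || !all(cl %in% .NODE_CLASSES)))
    msg <- c(msg, "every vertex needs a nodeClass in putative/disease/both/linker")
  if (length(msg)) msg else TRUE
})

#' TopologyProfile: the four per-node topological parameters
#'
#' Degree, betweenness, closeness and coreness evaluated on one graph.
#' Betweenness and closeness are normalized to `[0, 1]`; `scope` records
#' which graph was profiled (e.g. the full network or the hub-induced
#' subnetwork), since the major-hub screen requires all four metrics to be
#' computed on the same graph.
#'
#' @slot data data.frame with columns `id`, `degree`, `betweenness`,
#'   `closeness`, `coreness`.
#' @slot scope single string naming the profiled graph.
#' @seealso [profileTopology()]
#' @export
setClass("TopologyProfile",
         representation(data = "data.frame", scope = "character"))

setValidity("TopologyProfile", function(object) {
  d <- object@data
  need <- c("id", "degree", "betweenness", "closeness", "coreness")
  if (!all(need %in% names(d)))
    return(paste("profile needs columns", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(d)) {
    if (any(d$coreness > d$degree)) msg <- c(msg, "coreness must be <= degree")
    if (any(d$degree < 0)) msg <- c(msg, "negative degree")
    rng <- c(d$betweenness, d$closeness)
    if (any(rng < -1e-12 | rng > 1 + 1e-12))
      msg <- c(msg, "normalized betweenness/closeness must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' ScreenThresholds: cutoffs for the two-stage hub screen
#'
#' @slot hubFactor multiplier on the median degree for the first-stage hub
#'   rule (default 2: a hub has degree strictly above twice the median).
#' @slot degreeMin,betweennessMin,closenessMin,corenessMin strict lower
#'   bounds applied to the hub-subnetwork profile in the second stage.
#' @slot mode `"median_derived"` (cutoffs are the medians of the profiled
#'   metrics) or `"explicit"` (user-supplied values).
#' @seealso [screenThresholds()], [deriveMedianThresholds()], [zjwThresholds()]
#' @export
setClass("ScreenThresholds",
         representation(hubFactor = "numeric", degreeMin = "numeric",
                        betweennessMin = "numeric", closenessMin = "numeric",
                        corenessMin = "numeric", mode = "character"))

setValidity("ScreenThresholds", function(object) {
  msg <- character()
  if (length(object@hubFactor) != 1 || !is.finite(object@hubFactor) ||
      object@hubFactor <= 0)
    msg <- c(msg, "hubFactor must be a single positive number")
  if (!object@mode %in% c("median_derived", "explicit"))
    msg <- c(msg, "mode must be median_derived or explicit")
  if (length(msg)) msg else TRUE
})

#' HubScreenResult: outcome of the hub / major-hub screen
#'
#' @slot hubIds ids passing the degree > hubFactor x median(degree) rule.
#' @slot majorHubIds hubs strictly exceeding all four metric thresholds.
#' @slot hubNetwork the hub-induced [InteractionNetwork-class] subnetwork.
#' @slot profile the [TopologyProfile-class] the thresholds were applied to.
#' @slot thresholds the [ScreenThresholds-class] actually used.
#' @slot classCounts named integer: major hubs per node class.
#' @seealso [screenHubs()], [selectMajorHubs()]
#' @export
setClass("HubScreenResult",
         representation(hubIds = "character", majorHubIds = "character",
                        hubNetwork = "InteractionNetwork",
                        profile = "TopologyProfile",
                        thresholds = "ScreenThresholds",
                        classCounts = "integer"))

setValidity("HubScreenResult", function(object) {
  if (!all(object@majorHubIds %in% object@hubIds))
    return("majorHubIds must be a subset of hubIds")
  TRUE
})

#' EnrichmentResult: per-pathway over-representation statistics
#'
#' @slot table data.frame with one row per tested pathway: `pathway`, `K`
#'   (pathway size in universe), `n` (query size in universe), `k` (overlap),
#'   `N` (universe size), `p` (hypergeometric upper tail, `P(X >= k)`),
#'   `q` (Benjamini-Hochberg adjusted), `members` (`;`-joined overlap ids).
#' @slot universeSize,querySize the `N` and `n` used.
#' @seealso [enrich()], [significantPathways()], [topPathways()]
#' @export
setClass("EnrichmentResult",
         representation(table = "data.frame", universeSize = "integer",
                        querySize = "integer"))

setValidity("EnrichmentResult", function(object) {
  t <- object@table
  need <- c("pathway", "K", "n", "k", "N", "p", "q", "members")
  if (!all(need %in% names(t)))
    return(paste("table needs columns", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(t)) {
    if (any(t$k > pmin(t$K, t$n))) msg <- c(msg, "overlap k must be <= min(K, n)")
    if (any(t$p <= 0 | t$p > 1)) msg <- c(msg, "p must lie in (0, 1]")
    if (any(t$q + 1e-12 < t$p)) msg <- c(msg, "q must be >= p")
  }
  if (length(msg)) msg else TRUE
})

#' NullModelReport: the screen contrasted against G(n, m) replicates
#'
#' Every replicate conserves the real network's node set and edge count but
#' rewires edges uniformly at random (Erdos-Renyi G(n, m)); the report
#' contrasts the real major-hub count with the replicate distribution.
#'
#' @slot nReplicates number of randomized counterparts screened.
#' @slot replicateCounts integer vector of per-replicate major-hub counts.
#' @slot realCount major-hub count of the real network under the same policy.
#' @slot exceedance fraction of replicates with count >= `realCount`.
#' @slot thresholdMode the threshold policy applied per replicate.
#' @slot replicateSummary data.frame: per-replicate `components`, `maxCore`.
#' @seealso [nullScreen()], [erdosRenyiCounterpart()]
#' @export
setClass("NullModelReport",
         representation(nReplicates = "integer", replicateCounts = "integer",
                        realCount = "integer", exceedance = "numeric",
                        thresholdMode = "character",
                        replicateSummary = "data.frame"))

setValidity("NullModelReport", function(object) {
  msg <- character()
  if (length(object@replicateCounts) != object@nReplicates)
    msg <- c(msg, "one count per replicate required")
  if (object@exceedance < 0 || object@exceedance > 1)
    msg <- c(msg, "exceedance must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the study-shaped data generator
#'
#' Defaults mirror the shape of a two-herb remedy screen: a sparse
#' scale-free PPI union of 5559 proteins and 21567 interactions with median
#' degree 1, herb target sets of 175 and 348 sharing 106 targets, 90 known
#' disease targets, and planted structure (hubs wired into the network core,
#' pathways enriched around them) giving ground truth for validation.
#'
#' @slot nNodes,nEdges size of the synthetic PPI.
#' @slot attachmentExponent exponent on degree when attaching the non-tree
#'   edges preferentially among internal nodes.
#' @slot nTargetsHerbA,nTargetsHerbB,nOverlap herb target set sizes and
#'   their exact intersection.
#' @slot nDiseaseTargets known therapeutic target count.
#' @slot nPlantedHubs,plantedHubDegree how many hubs to plant and the degree
#'   each is wired up to.
#' @slot nPathways,nPlantedPathways,pathwaySizeRange,plantedPathwayFraction
#'   gene-set generation: total pathways, how many are enriched around the
#'   planted hubs, the size range, and the fraction of a planted pathway's
#'   members drawn from the planted-hub neighborhood.
#' @slot seed integer; the single source of randomness.
#' @seealso [syntheticConfig()], [generateStudyFixture()]
#' @export
setClass("SyntheticConfig",
         representation(nNodes = "integer", nEdges = "integer",
                        attachmentExponent = "numeric",
                        nTargetsHerbA = "integer", nTargetsHerbB = "integer",
                        nOverlap = "integer", nDiseaseTargets = "integer",
                        nPlantedHubs = "integer", plantedHubDegree = "integer",
                        nPathways = "integer", nPlantedPathways = "integer",
                        pathwaySizeRange = "integer",
                        plantedPathwayFraction = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  cnt <- c(nNodes = object@nNodes, nEdges = object@nEdges,
           A = object@nTargetsHerbA, B = object@nTargetsHerbB,
           overlap = object@nOverlap, disease = object@nDiseaseTargets,
           plantedHubs = object@nPlantedHubs, pathways = object@nPathways,
           plantedPathways = object@nPlantedPathways)
  if (any(cnt < 0)) msg <- c(msg, "all counts must be >= 0")
  if (object@nNodes < 1) msg <- c(msg, "nNodes must be positive")
  if (object@nEdges > object@nNodes * (object@nNodes - 1) / 2)
    msg <- c(msg, "nEdges exceeds n(n-1)/2: infeasible for a simple graph")
  if (object@nOverlap > min(object@nTargetsHerbA, object@nTargetsHerbB))
    msg <- c(msg, "nOverlap cannot exceed the smaller herb target set")
  if (object@nPlantedHubs > object@nNodes)
    msg <- c(msg, "cannot plant more hubs than nodes")
  if (object@nPlantedPathways > object@nPathways)
    msg <- c(msg, "cannot plant more pathways than nPathways")
  if (length(object@pathwaySizeRange) != 2 ||
      object@pathwaySizeRange[1] > object@pathwaySizeRange[2] ||
      object@pathwaySizeRange[1] < 1)
    msg <- c(msg, "pathwaySizeRange must be an increasing positive pair")
  if (object@pathwaySizeRange[2] > object@nNodes)
    msg <- c(msg, "pathway sizes cannot exceed the node universe")
  if (object@plantedPathwayFraction < 0 || object@plantedPathwayFraction > 1)
    msg <- c(msg, "plantedPathwayFraction must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticDataset: a generated study fixture with ground truth
#'
#' @slot ppi [EdgeTable-class] of synthetic protein interactions.
#' @slot herbA,herbB,disease [TargetSet-class] objects.
#' @slot geneSets [PathwayAnnotation-class] over the PPI nodes.
#' @slot truth list with `plantedHubs` and `plantedPathways` character ids.
#' @slot config the [SyntheticConfig-class] that produced the bundle.
#' @seealso [generateStudyFixture()], [writeStudyFixture()]
#' @export
setClass("SyntheticDataset",
         representation(ppi = "EdgeTable", herbA = "TargetSet",
                        herbB = "TargetSet", disease = "TargetSet",
                        geneSets = "PathwayAnnotation", truth = "list",
                        config = "SyntheticConfig"))

setValidity("SyntheticDataset", function(object) {
  nodes <- unique(c(object@ppi@edges$from, object@ppi@edges$to))
  msg <- character()
  tids <- c(targetIds(object@herbA), targetIds(object@herbB),
            targetIds(object@disease))
  if (!all(tids %in% nodes))
    msg <- c(msg, "every target id must appear among the PPI node ids")
  if (!all(object@truth$plantedHubs %in% nodes))
    msg <- c(msg, "planted hubs must be PPI nodes")
  if (!all(object@truth$plantedPathways %in% names(object@geneSets@sets)))
    msg <- c(msg, "planted pathways must exist in the annotation")
  if (length(msg)) msg else TRUE
})
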