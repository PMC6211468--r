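#' Configure the synthetic study generator
#'
#' Defaults emulate the shape of a two-herb network-pharmacology screen:
#' a sparse scale-free PPI union (5559 nodes, 21567 edges, median degree 1,
#' so the twofold-median hub cutoff is 2), herb target sets of 175 and 348
#' with 106 shared targets, 90 known disease targets, 30 planted hubs wired
#' to ~60 partners each, and 50 pathways of 10-50 members of which 5 are
#' planted around the hub neighborhoods.
#'
#' @param nNodes,nEdges PPI size.
#' @param attachmentExponent degree exponent for preferential attachment of
#'   the non-tree edges (default 1, linear).
#' @param nTargetsHerbA,nTargetsHerbB,nOverlap herb target counts and exact
#'   intersection size.
#' @param nDiseaseTargets known therapeutic target count.
#' @param nPlantedHubs,plantedHubDegree planted-hub count and wiring degree.
#' @param nPathways,nPlantedPathways,pathwaySizeRange,plantedPathwayFraction
#'   gene-set shape; `plantedPathwayFraction` of a planted pathway's members
#'   come from the planted-hub neighborhood.
#' @param seed single integer seeding all randomness.
#' @return A validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nNodes = 5559, nEdges = 21567,
                            attachmentExponent = 1,
                            nTargetsHerbA = 175, nTargetsHerbB = 348,
                            nOverlap = 106, nDiseaseTargets = 90,
                            nPlantedHubs = 30, plantedHubDegree = 60,
                            nPathways = 50, nPlantedPathways = 5,
                            pathwaySizeRange = c(20, 80),
                            plantedPathwayFraction = 0.8, seed = 1) {
  new("SyntheticConfig",
      nNodes = as.integer(nNodes), nEdges = as.integer(nEdges),
      attachmentExponent = as.numeric(attachmentExponent),
      nTargetsHerbA = as.integer(nTargetsHerbA),
      nTargetsHerbB = as.integer(nTargetsHerbB),
      nOverlap = as.integer(nOverlap),
      nDiseaseTargets = as.integer(nDiseaseTargets),
      nPlantedHubs = as.integer(nPlantedHubs),
      plantedHubDegree = as.integer(plantedHubDegree),
      nPathways = as.integer(nPathways),
      nPlantedPathways = as.integer(nPlantedPathways),
      pathwaySizeRange = as.integer(pathwaySizeRange),
      plantedPathwayFraction = as.numeric(plantedPathwayFraction),
      seed = as.integer(seed))
}

.syntheticIds <- function(n) sprintf("G%05d", seq_len(n))

# Batch rejection sampler: add `extra` new edges with endpoints drawn with
# probability proportional to `weight(deg)`, falling back to exact
# complement enumeration for small / near-saturated graphs.
.addWeightedEdges <- function(el, deg, extra, weightFun, excludeExisting = TRUE) {
  n <- length(deg)
  seen <- if (nrow(el)) paste(pmin(el[, 1], el[, 2]),
                              pmax(el[, 1], el[, 2])) else character()
  acc <- matrix(0L, 0, 2)
  stall <- 0L
  while (nrow(acc) < extra) {
    need <- extra - nrow(acc)
    w <- weightFun(deg)
    if (sum(w > 0) < 2 || stall > 50L) {
      # exact fallback: enumerate the complement (small graphs only)
      if (choose(n, 2) > 2e5)
        stop("edge sampling stalled on a large graph; relax parameters")
      allPairs <- t(utils::combn(n, 2))
      key <- paste(allPairs[, 1], allPairs[, 2])
      freePairs <- allPairs[!(key %in% seen), , drop = FALSE]
      if (nrow(freePairs) < need)
        stop("not enough free node pairs for the requested edge count")
      pick <- sample.int(nrow(freePairs), need)
      sel <- freePairs[pick, , drop = FALSE]
      acc <- rbind(acc, sel)
      deg[sel[, 1]] <- deg[sel[, 1]] + 1L
      deg[sel[, 2]] <- deg[sel[, 2]] + 1L
      break
    }
    a <- sample.int(n, 2 * need, replace = TRUE, prob = w)
    b <- sample.int(n, 2 * need, replace = TRUE, prob = w)
    ok <- a != b
    p <- cbind(pmin(a, b), pmax(a, b))[ok, , drop = FALSE]
    k <- paste(p[, 1], p[, 2])
    keep <- !duplicated(k) & !(k %in% seen)
    p <- p[keep, , drop = FALSE]
    if (nrow(p) > need) p <- p[seq_len(need), , drop = FALSE]
    stall <- if (nrow(p)) 0L else stall + 1L
    seen <- c(seen, paste(p[, 1], p[, 2]))
    acc <- rbind(acc, p)
    add <- tabulate(c(p), nbins = n)
    deg <- deg + add
  }
  list(edges = acc, deg = deg)
}

#' Generate a synthetic scale-free PPI with planted hubs
#'
#' A preferential-attachment tree anchors the topology; the remaining edges
#' are attached preferentially (weight `degree^attachmentExponent`) among
#' internal (degree >= 2) nodes only, which keeps pendant leaves pendant and
#' pins the median degree at 1 for study-shaped sizes — so the twofold
#' median hub cutoff is 2. Planted hubs are then wired to
#' `max(plantedHubDegree, 2*median+3)` partners drawn with probability
#' proportional to degree (embedding them in the network core), and the
#' edge count is restored exactly by removing edges between two non-planted
#' nodes of lowest degree (both endpoints kept at degree >= 2).
#'
#' @param config a [SyntheticConfig-class].
#' @param seed integer; defaults to `config@seed`.
#' @return list with `ppi` (an [EdgeTable-class]) and `plantedHubs`
#'   (character ids).
#' @export
generatePpi <- function(config, seed = config@seed) {
  set.seed(seed)
  n <- config@nNodes; m <- config@nEdges
  alpha <- config@attachmentExponent
  ids <- .syntheticIds(n)
  if (n == 1 || m == 0)
    return(list(ppi = EdgeTable(), plantedHubs = character()))
  g <- igraph::sample_pa(n, power = 1, m = 1, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- tabulate(c(el), nbins = n)
  if (m < n - 1) {
    # sparser than a spanning tree: drop internal-internal edges first so
    # no node is silently isolated out of the edge table
    while (nrow(el) > m) {
      both2 <- deg[el[, 1]] >= 2 & deg[el[, 2]] >= 2
      i <- if (any(both2)) sample(which(both2), 1) else
        sample.int(nrow(el), 1)
      deg[el[i, ]] <- deg[el[i, ]] - 1L
      el <- el[-i, , drop = FALSE]
    }
  } else if (m > n - 1) {
    res <- .addWeightedEdges(el, deg, m - (n - 1),
                             function(d) ifelse(d >= 2, d^alpha, 0))
    el <- rbind(el, res$edges)
    deg <- res$deg
  }
  planted <- integer(0)
  if (config@nPlantedHubs > 0) {
    planted <- sample.int(n, config@nPlantedHubs)
    target <- max(config@plantedHubDegree,
                  2 * stats::median(deg) + 3)
    adj <- vector("list", n)
    for (i in seq_len(nrow(el))) {
      adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
      adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
    }
    added <- matrix(0L, 0, 2)
    for (p in planted) {
      need <- target - deg[p]
      if (need <= 0) next
      cand <- setdiff(seq_len(n), c(p, adj[[p]]))
      w <- pmax(deg[cand], 1)
      pick <- cand[sample.int(length(cand), min(need, length(cand)),
                              prob = w)]
      newE <- cbind(pmin(p, pick), pmax(p, pick))
      added <- rbind(added, newE)
      deg[p] <- deg[p] + length(pick)
      deg[pick] <- deg[pick] + 1L
      adj[[p]] <- c(adj[[p]], pick)
      for (q in pick) adj[[q]] <- c(adj[[q]], p)
    }
    el <- rbind(el, added)
    # trim back to exactly m edges: remove edges between two non-planted
    # nodes, lowest degree-sum first, never dropping a node below degree 1
    nTrim <- nrow(el) - m
    if (nTrim > 0) {
      isPlanted <- logical(n); isPlanted[planted] <- TRUE
      ord <- order(deg[el[, 1]] + deg[el[, 2]])
      drop <- integer(0)
      for (i in ord) {
        if (length(drop) >= nTrim) break
        a <- el[i, 1]; b <- el[i, 2]
        if (isPlanted[a] || isPlanted[b]) next
        if (deg[a] < 2 || deg[b] < 2) next
        drop <- c(drop, i)
        deg[a] <- deg[a] - 1L; deg[b] <- deg[b] - 1L
      }
      if (length(drop) < nTrim)
        stop("hub planting infeasible: not enough removable edges; ",
             "reduce nPlantedHubs or plantedHubDegree")
      el <- el[-drop, , drop = FALSE]
    }
  }
  list(ppi = EdgeTable(ids[el[, 1]], ids[el[, 2]], "synthetic"),
       plantedHubs = sort(ids[planted]))
}

#' Generate herb and disease target sets over the PPI nodes
#'
#' Herb sets A and B are built with exact cardinalities and exact overlap
#' (`|A| = nTargetsHerbA`, `|B| = nTargetsHerbB`, `|A intersect B| =
#' nOverlap`); planted hubs are placed into A/B first so the remedy's
#' putative targets carry the planted signal. Disease targets are drawn
#' independently from all nodes (so they may intersect the herb sets, as in
#' real data) and carry a drug-database / disease-genetics provenance split
#' of roughly 5:1.
#'
#' @param ppi an [EdgeTable-class] (node universe = its endpoint ids).
#' @param config a [SyntheticConfig-class].
#' @param plantedHubs character ids to place preferentially into the herb
#'   sets.
#' @param seed integer; defaults to `config@seed + 1`.
#' @return list of [TargetSet-class]: `herbA`, `herbB`, `disease`.
#' @export
generateTargetSets <- function(ppi, config, plantedHubs = character(),
                               seed = config@seed + 1) {
  set.seed(seed)
  nodes <- sort(unique(c(ppi@edges$from, ppi@edges$to)))
  nA <- config@nTargetsHerbA; nB <- config@nTargetsHerbB
  nO <- config@nOverlap; nD <- config@nDiseaseTargets
  nUnion <- nA + nB - nO
  if (nUnion > length(nodes))
    stop("herb target union exceeds the PPI node universe")
  if (nD > length(nodes))
    stop("disease target count exceeds the PPI node universe")
  planted <- sample(intersect(plantedHubs, nodes))  # shuffled
  # fill compartments: shared first, then A-only, then B-only
  cap <- c(shared = nO, aOnly = nA - nO, bOnly = nB - nO)
  comp <- list(shared = character(), aOnly = character(), bOnly = character())
  for (p in planted) {
    slot <- names(cap)[cap > lengths(comp)[names(cap)]][1]
    if (is.na(slot)) break
    comp[[slot]] <- c(comp[[slot]], p)
  }
  used <- unlist(comp, use.names = FALSE)
  pool <- sample(setdiff(nodes, used))
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  for (s in names(cap)) {
    short <- cap[[s]] - length(comp[[s]])
    if (short > 0) comp[[s]] <- c(comp[[s]], take(short))
  }
  herbA <- c(comp$shared, comp$aOnly)
  herbB <- c(comp$shared, comp$bOnly)
  diseaseIds <- sample(nodes, nD)
  nDrug <- round(nD * 5 / 6)
  diseaseSrc <- rep(c("drugbank", "omim"),
                    times = c(nDrug, nD - nDrug))
  list(
    herbA = TargetSet(data.frame(id = herbA, symbol = herbA,
                                 source = "tcmsp", herb = "R_coptidis",
                                 stringsAsFactors = FALSE)),
    herbB = TargetSet(data.frame(id = herbB, symbol = herbB,
                                 source = "tcmsp", herb = "E_rutaecarpa",
                                 stringsAsFactors = FALSE)),
    disease = TargetSet(data.frame(id = diseaseIds, symbol = diseaseIds,
                                   source = diseaseSrc,
                                   stringsAsFactors = FALSE)))
}

#' Generate pathway gene sets with planted enrichment
#'
#' The first `nPlantedPathways` pathways draw `plantedPathwayFraction` of
#' their members from the planted-hub neighborhood (the planted hubs plus
#' their direct PPI partners, drawn with probability proportional to degree
#' so the planted signal sits on high-centrality nodes) and the rest
#' uniformly; all other pathways are uniform draws from the node universe.
#'
#' @param ppi an [EdgeTable-class].
#' @param config a [SyntheticConfig-class].
#' @param plantedHubs character ids around which enrichment is planted.
#' @param seed integer; defaults to `config@seed + 2`.
#' @return list with `annotation` (a [PathwayAnnotation-class] whose
#'   universe is the PPI node set) and `plantedPathways` (character names).
#' @export
generateGeneSets <- function(ppi, config, plantedHubs = character(),
                             seed = config@seed + 2) {
  set.seed(seed)
  nodes <- sort(unique(c(ppi@edges$from, ppi@edges$to)))
  nP <- config@nPathways
  if (nP == 0)
    return(list(annotation = PathwayAnnotation(list(), nodes),
                plantedPathways = character()))
  rng <- config@pathwaySizeRange
  if (rng[2] > length(nodes))
    stop("pathway size range exceeds the node universe")
  e <- ppi@edges
  nbr <- unique(c(e$to[e$from %in% plantedHubs],
                  e$from[e$to %in% plantedHubs]))
  pool <- union(plantedHubs, nbr)
  degTab <- table(c(e$from, e$to))
  poolW <- as.numeric(degTab[pool])
  poolW[is.na(poolW)] <- 1
  sizes <- sample(seq(rng[1], rng[2]), nP, replace = TRUE)
  nm <- sprintf("PW%03d", seq_len(nP))
  plantedNames <- nm[seq_len(config@nPlantedPathways)]
  sets <- lapply(seq_len(nP), function(i) {
    s <- sizes[i]
    if (i <= config@nPlantedPathways && length(pool)) {
      nIn <- min(round(config@plantedPathwayFraction * s), length(pool), s)
      inside <- sample(pool, nIn, prob = poolW)
      outside <- sample(setdiff(nodes, inside), s - nIn)
      c(inside, outside)
    } else {
      sample(nodes, s)
    }
  })
  names(sets) <- nm
  list(annotation = PathwayAnnotation(sets, nodes),
       plantedPathways = plantedNames)
}

#' Generate the full study-shaped fixture
#'
#' Runs the PPI, target-set and gene-set generators off one seed and bundles
#' the result with its ground truth (planted hub ids, planted pathway
#' names). Identical configs produce byte-identical serialized fixtures.
#'
#' @param config a [SyntheticConfig-class] (default: study-shaped defaults
#'   of [syntheticConfig()]).
#' @return A [SyntheticDataset-class].
#' @export
generateStudyFixture <- function(config = syntheticConfig()) {
  validObject(config)
  ppiRes <- generatePpi(config)
  targets <- generateTargetSets(ppiRes$ppi, config, ppiRes$plantedHubs)
  gs <- generateGeneSets(ppiRes$ppi, config, ppiRes$plantedHubs)
  new("SyntheticDataset", ppi = ppiRes$ppi, herbA = targets$herbA,
      herbB = targets$herbB, disease = targets$disease,
      geneSets = gs$annotation,
      truth = list(plantedHubs = ppiRes$plantedHubs,
                   plantedPathways = gs$plantedPathways),
      config = config)
}

#' Write a fixture to disk in the ingest formats
#'
#' Emits `ppi_edges.tsv`, `herb_a_targets.tsv`, `herb_b_targets.tsv`,
#' `disease_targets.tsv`, `gene_sets.gmt` and `truth.json` under `dir`,
#' all re-readable through the ingest functions with zero loss.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeStudyFixture <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ppi = file.path(dir, "ppi_edges.tsv"),
             herbA = file.path(dir, "herb_a_targets.tsv"),
             herbB = file.path(dir, "herb_b_targets.tsv"),
             disease = file.path(dir, "disease_targets.tsv"),
             geneSets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  writeEdgeList(dataset@ppi, paths[["ppi"]])
  writeTargetTable(dataset@herbA, paths[["herbA"]])
  writeTargetTable(dataset@herbB, paths[["herbB"]])
  writeTargetTable(dataset@disease, paths[["disease"]])
  writeGeneSets(dataset@geneSets, paths[["geneSets"]])
  writeLines(jsonlite::toJSON(c(dataset@truth,
                                list(seed = dataset@config@seed)),
                              auto_unbox = TRUE, pretty = TRUE),
             paths[["truth"]])
  invisible(paths)
}

#' Read a fixture directory back through the ingest functions
#'
#' @param dir directory written by [writeStudyFixture()].
#' @return list with `ppi`, `herbA`, `herbB`, `disease`, `geneSets`, `truth`.
#' @export
readStudyFixture <- function(dir) {
  list(ppi = readEdgeList(file.path(dir, "ppi_edges.tsv"),
                          fromColumn = "from", toColumn = "to",
                          sourceLabel = "synthetic"),
       herbA = readTargetTable(file.path(dir, "herb_a_targets.tsv")),
       herbB = readTargetTable(file.path(dir, "herb_b_targets.tsv")),
       disease = readTargetTable(file.path(dir, "disease_targets.tsv")),
       geneSets = readGeneSets(file.path(dir, "gene_sets.gmt")),
       truth = jsonlite::fromJSON(file.path(dir, "truth.json")))
}
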