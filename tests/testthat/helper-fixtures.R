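# Small graph builders and a scaled-down synthetic config for fast tests.

edgesDf <- function(...) {
  pairs <- list(...)
  data.frame(from = vapply(pairs, `[[`, character(1), 1),
             to = vapply(pairs, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

pathNet <- function(ids) {
  interactionNetwork(ids, data.frame(from = ids[-length(ids)], to = ids[-1]))
}

cycleNet <- function(n) {
  ids <- sprintf("C%02d", seq_len(n))
  interactionNetwork(ids, data.frame(from = ids, to = ids[c(2:n, 1)]))
}

completeNet <- function(n) {
  ids <- sprintf("K%02d", seq_len(n))
  idx <- t(utils::combn(n, 2))
  interactionNetwork(ids, data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]]))
}

starNet <- function(nLeaves) {
  ids <- c("HUB", sprintf("L%02d", seq_len(nLeaves)))
  interactionNetwork(ids, data.frame(from = "HUB", to = ids[-1]))
}

# scaled-down study shape: same qualitative structure (median degree 1,
# planted hubs, planted pathways), 10x smaller for unit tests; the steeper
# attachment exponent keeps the k-core hierarchy graded at this size, as it
# is at full scale with the default exponent
smallConfig <- function(seed = 1, ...) {
  syntheticConfig(nNodes = 500, nEdges = 1900, attachmentExponent = 1.2,
                  nTargetsHerbA = 30, nTargetsHerbB = 45, nOverlap = 12,
                  nDiseaseTargets = 15, nPlantedHubs = 5,
                  plantedHubDegree = 40, nPathways = 20,
                  nPlantedPathways = 3, pathwaySizeRange = c(10, 30),
                  seed = seed, ...)
}
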