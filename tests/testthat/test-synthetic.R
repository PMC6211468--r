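test_that("generated graphs satisfy the handshake lemma and are simple", {
  for (s in 1:5) {
    cfg <- smallConfig(seed = s)
    ppi <- generatePpi(cfg)$ppi
    e <- edgeTable(ppi)
    expect_identical(nrow(e), 1900L)
    expect_true(all(e$from < e$to))
    expect_false(anyDuplicated(paste(e$from, e$to)) > 0)
    deg <- table(c(e$from, e$to))
    expect_identical(sum(deg), 2L * nrow(e))  # handshake lemma
  }
})

test_that("forced configurations produce the only possible graph", {
  cfg <- syntheticConfig(nNodes = 4, nEdges = 6, nPlantedHubs = 0,
                         nTargetsHerbA = 2, nTargetsHerbB = 2, nOverlap = 1,
                         nDiseaseTargets = 1, nPathways = 0,
                         nPlantedPathways = 0, pathwaySizeRange = c(1, 2),
                         seed = 1)
  e <- edgeTable(generatePpi(cfg)$ppi)
  expect_identical(nrow(e), 6L)  # K4 is the only simple graph with 4/6
  expect_identical(sort(unique(c(e$from, e$to))), sprintf("G%05d", 1:4))
})

test_that("infeasible edge counts are rejected", {
  expect_error(syntheticConfig(nNodes = 4, nEdges = 7), "infeasible")
  expect_error(syntheticConfig(nOverlap = 200, nTargetsHerbA = 100,
                               nTargetsHerbB = 300), "Overlap")
})

test_that("planted hubs exceed twice the median degree of the emitted table", {
  cfg <- syntheticConfig(nNodes = 200, nEdges = 400, nPlantedHubs = 5,
                         plantedHubDegree = 20, nTargetsHerbA = 20,
                         nTargetsHerbB = 30, nOverlap = 10,
                         nDiseaseTargets = 10, pathwaySizeRange = c(5, 10),
                         seed = 3)
  res <- generatePpi(cfg)
  e <- edgeTable(res$ppi)
  deg <- table(c(e$from, e$to))
  med <- median(as.numeric(deg))
  expect_length(res$plantedHubs, 5)
  for (p in res$plantedHubs) expect_gt(deg[[p]], 2 * med)
  # wired to at least 2*median + 3 partners
  for (p in res$plantedHubs) expect_gte(deg[[p]], 2 * med + 3)
})

test_that("target sets have exact cardinalities and overlap for every seed", {
  for (s in c(1, 11, 23)) {
    cfg <- smallConfig(seed = s)
    ppi <- generatePpi(cfg)
    ts <- generateTargetSets(ppi$ppi, cfg, ppi$plantedHubs)
    a <- targetIds(ts$herbA); b <- targetIds(ts$herbB)
    expect_length(a, 30)
    expect_length(b, 45)
    expect_length(intersect(a, b), 12)
    expect_length(union(a, b), 30 + 45 - 12)  # inclusion-exclusion
    expect_length(targetIds(ts$disease), 15)
    # planted hubs preferentially sampled into A union B
    expect_true(all(ppi$plantedHubs %in% union(a, b)))
  }
})

test_that("zero overlap gives disjoint herb sets", {
  cfg <- smallConfig(seed = 2)
  cfg@nOverlap <- 0L
  ppi <- generatePpi(cfg)
  ts <- generateTargetSets(ppi$ppi, cfg, ppi$plantedHubs)
  expect_length(intersect(targetIds(ts$herbA), targetIds(ts$herbB)), 0)
})

test_that("identical configs give byte-identical fixture files", {
  cfg <- smallConfig(seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeStudyFixture(generateStudyFixture(cfg), d1)
  writeStudyFixture(generateStudyFixture(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # different seeds differ
  d3 <- withr::local_tempdir()
  writeStudyFixture(generateStudyFixture(smallConfig(seed = 12)), d3)
  expect_false(identical(readLines(file.path(d1, "ppi_edges.tsv")),
                         readLines(file.path(d3, "ppi_edges.tsv"))))
})

test_that("gene-set generation respects counts, range and planting", {
  cfg <- smallConfig(seed = 5)
  ppi <- generatePpi(cfg)
  gs <- generateGeneSets(ppi$ppi, cfg, ppi$plantedHubs)
  expect_length(pathwayList(gs$annotation), 20)
  sz <- lengths(pathwayList(gs$annotation))
  expect_true(all(sz >= 10 & sz <= 30))
  expect_length(gs$plantedPathways, 3)
  # empty annotation
  cfg0 <- smallConfig(seed = 5); cfg0@nPathways <- 0L; cfg0@nPlantedPathways <- 0L
  gs0 <- generateGeneSets(ppi$ppi, cfg0, ppi$plantedHubs)
  expect_length(pathwayList(gs0$annotation), 0)
})

test_that("fraction-1 planted pathways live entirely in the hub neighborhood", {
  cfg <- smallConfig(seed = 7)
  cfg@plantedPathwayFraction <- 1
  ppi <- generatePpi(cfg)
  gs <- generateGeneSets(ppi$ppi, cfg, ppi$plantedHubs)
  e <- edgeTable(ppi$ppi)
  nbr <- unique(c(e$to[e$from %in% ppi$plantedHubs],
                  e$from[e$to %in% ppi$plantedHubs]))
  pool <- union(ppi$plantedHubs, nbr)
  for (nm in gs$plantedPathways)
    expect_true(all(pathwayList(gs$annotation)[[nm]] %in% pool))
})

test_that("planted pathways score better than non-planted on the truth set", {
  cfg <- smallConfig(seed = 5)
  ds <- generateStudyFixture(cfg)
  res <- enrich(ds@truth$plantedHubs, ds@geneSets)
  tab <- enrichmentTable(res)
  planted <- tab$p[tab$pathway %in% ds@truth$plantedPathways]
  others <- tab$p[!tab$pathway %in% ds@truth$plantedPathways]
  expect_true(all(planted < median(others)))
})

test_that("fixtures round-trip through the ingest readers with zero loss", {
  cfg <- smallConfig(seed = 4)
  ds <- generateStudyFixture(cfg)
  d <- withr::local_tempdir()
  writeStudyFixture(ds, d)
  back <- suppressMessages(readStudyFixture(d))
  expect_identical(edgeTable(back$ppi), edgeTable(ds@ppi))
  expect_setequal(targetIds(back$herbA), targetIds(ds@herbA))
  expect_setequal(targetIds(back$herbB), targetIds(ds@herbB))
  expect_setequal(targetIds(back$disease), targetIds(ds@disease))
  expect_identical(pathwayList(back$geneSets), pathwayList(ds@geneSets))
  expect_setequal(back$truth$plantedHubs, ds@truth$plantedHubs)
})
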