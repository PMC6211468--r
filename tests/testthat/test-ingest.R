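test_that("target tables deduplicate, normalize and report drops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id", "P1", "P2", "P1"), f)
  expect_message(ts <- readTargetTable(f, "src"), "1 duplicate")
  expect_length(ts, 2)
  expect_setequal(targetIds(ts), c("P1", "P2"))
  # trimming and case normalization
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id", " p1 ", "P1"), f2)
  expect_length(suppressMessages(readTargetTable(f2, "src")), 1)
  # committed 10-row fixture with 3 duplicates -> 7
  ts3 <- suppressMessages(readTargetTable(test_path("fixtures", "targets_dup.tsv")))
  expect_length(ts3, 7)
  # schema errors
  expect_error(readTargetTable(f, idColumn = "uniprot"), "id column")
  # empty file -> empty set with warning
  fe <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id", fe)
  expect_warning(tse <- suppressMessages(readTargetTable(fe, "src")), "empty")
  expect_length(tse, 0)
})

test_that("merging target sets unions ids and concatenates provenance", {
  s1 <- TargetSet(data.frame(id = c("P1", "P2")), "drugbank")
  s2 <- TargetSet(data.frame(id = c("P2", "P3")), "omim")
  m <- mergeTargetSets(list(s1, s2))
  expect_setequal(targetIds(m), c("P1", "P2", "P3"))
  e <- targetEntries(m)
  expect_identical(e$source[e$id == "P2"], "drugbank;omim")
  # disjoint 75 + 15 -> 90
  big <- TargetSet(data.frame(id = sprintf("D%02d", 1:75)), "drugbank")
  small <- TargetSet(data.frame(id = sprintf("O%02d", 1:15)), "omim")
  expect_length(mergeTargetSets(list(big, small)), 90)
  # identity: X union empty = X
  expect_setequal(targetIds(mergeTargetSets(list(s1, TargetSet()))),
                  targetIds(s1))
})

test_that("intersection keeps shared ids and is idempotent", {
  s1 <- TargetSet(data.frame(id = c("P1", "P2")), "a")
  s2 <- TargetSet(data.frame(id = c("P2", "P3")), "b")
  expect_setequal(targetIds(intersectTargetSets(s1, s2)), "P2")
  expect_setequal(targetIds(intersectTargetSets(s1, s1)), targetIds(s1))
})

test_that("edge lists normalize orientation, loops and duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "A\tB", "B\tA", "A\tA"), f)
  et <- suppressMessages(readEdgeList(f))
  expect_identical(nrow(edgeTable(et)), 1L)
  expect_identical(edgeTable(et)$from, "A")
  expect_identical(edgeTable(et)$to, "B")
  # empty file
  fe <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb", fe)
  expect_warning(ee <- readEdgeList(fe), "empty")
  expect_identical(nrow(edgeTable(ee)), 0L)
})

test_that("unparseable edge rows are skipped, too many fail the read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "A\tB", "C\t", "D\tE"), f)
  expect_warning(et <- readEdgeList(f, maxSkipFraction = 0.5), "skipped")
  expect_identical(nrow(edgeTable(et)), 2L)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "A\tB", "C\t", "D\t", "E\t"), f2)
  expect_error(suppressWarnings(readEdgeList(f2)), "unparseable")
})

test_that("merging PPI sources unions pairs and preserves provenance", {
  t1 <- EdgeTable("A", "B", "string")
  t2 <- EdgeTable(c("A", "B"), c("B", "C"), "intact")
  m <- mergePpiSources(list(t1, t2))
  e <- edgeTable(m)
  expect_identical(nrow(e), 2L)
  expect_identical(e$sources[e$from == "A" & e$to == "B"], "string;intact")
  # 8 distinct single-edge tables -> 8 edges
  singles <- lapply(1:8, function(i) EdgeTable(sprintf("X%d", i),
                                               sprintf("Y%d", i), "s"))
  expect_identical(nrow(edgeTable(mergePpiSources(singles))), 8L)
})

test_that("committed overlapping edge fixtures merge to the brute-force union", {
  paths <- file.path(test_path("fixtures"),
                     sprintf("edges_overlap_%d.tsv", 1:3))
  tabs <- lapply(paths, readEdgeList)
  merged <- mergePpiSources(tabs)
  # independent set-union oracle on the raw files
  raw <- unlist(lapply(paths, function(p) {
    t <- read.delim(p, colClasses = "character")
    paste(pmin(t[[1]], t[[2]]), pmax(t[[1]], t[[2]]))
  }))
  expect_identical(nrow(edgeTable(merged)), length(unique(raw)))
  expect_identical(nrow(edgeTable(merged)), 58L)
})

test_that("GMT parsing collapses members and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("pw1\tdesc\tA\tB\tA", f)
  ann <- readGeneSets(f)
  expect_identical(pathwayList(ann)$pw1, c("A", "B"))
  # committed 5-pathway fixture with sizes 3,5,8,10,12
  ann5 <- readGeneSets(test_path("fixtures", "pathways5.gmt"))
  expect_identical(unname(lengths(pathwayList(ann5))), c(3L, 5L, 8L, 10L, 12L))
  # duplicate names are an error
  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\td\tA", "pw1\td\tB"), f2)
  expect_error(readGeneSets(f2), "duplicate pathway")
  # short line names the line number
  f3 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\td\tA", "pw2\td"), f3)
  expect_error(readGeneSets(f3), "line 2")
  # empty file
  f4 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(), f4)
  expect_warning(a0 <- readGeneSets(f4), "empty")
  expect_length(a0, 0)
})

test_that("reading a file twice and merging equals reading once", {
  f <- test_path("fixtures", "targets_dup.tsv")
  once <- suppressMessages(readTargetTable(f))
  twice <- mergeTargetSets(list(once, suppressMessages(readTargetTable(f))))
  expect_setequal(targetIds(twice), targetIds(once))
  p <- test_path("fixtures", "edges_overlap_1.tsv")
  eOnce <- readEdgeList(p)
  eTwice <- mergePpiSources(list(eOnce, readEdgeList(p)))
  expect_identical(edgeTable(eTwice)[, c("from", "to")],
                   edgeTable(eOnce)[, c("from", "to")])
})

test_that("network export round-trips and carries class labels", {
  net <- interactionNetwork(c("A", "B", "C", "D"),
                            edgesDf(c("A", "B"), c("B", "C"), c("C", "A")),
                            classes = c(A = "putative", B = "disease",
                                        C = "both", D = "linker"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeNetwork(net, gml, "graphml")
  back <- readNetwork(gml)
  expect_setequal(nodeIds(back), nodeIds(net))
  expect_identical(nodeClasses(back)[nodeIds(net)], nodeClasses(net))
  eOrig <- igraph::as_edgelist(asIgraph(net))
  eBack <- igraph::as_edgelist(asIgraph(back))
  expect_setequal(paste(pmin(eOrig[, 1], eOrig[, 2]), pmax(eOrig[, 1], eOrig[, 2])),
                  paste(pmin(eBack[, 1], eBack[, 2]), pmax(eBack[, 1], eBack[, 2])))
  # sif: one edge per line, isolated node as its own line
  sif <- withr::local_tempfile(fileext = ".sif")
  writeNetwork(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 4)  # 3 edges + isolated D
  expect_identical(sum(grepl(" pp ", lines)), 3L)
  expect_error(writeNetwork(net, sif, "xgmml"))
})

test_that("id maps rewrite identifiers before merging", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id", "tp53", "EGFR"), f)
  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines("TP53\tP04637", m)
  ts <- readTargetTable(f, "src", idMap = m)
  expect_setequal(targetIds(ts), c("P04637", "EGFR"))
})
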