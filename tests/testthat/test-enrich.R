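# enumeration oracle: upper-tail overlap probability by counting all
# C(N, n) draws explicitly
enumUpperTail <- function(N, K, n, k) {
  universe <- seq_len(N)
  success <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% success))
  mean(hits >= k)
}

annotationFor <- function(sets, universe) PathwayAnnotation(sets, universe)

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  # the fully worked case: N=10, K=5, n=4, k=4 -> 5/210
  uni <- sprintf("U%02d", 1:10)
  ann <- annotationFor(list(pw = uni[1:5]), uni)
  res <- enrich(uni[2:5], ann)
  expect_equal(enrichmentTable(res)$p, 5 / 210, tolerance = 1e-12)
  expect_equal(enrichmentTable(res)$p, enumUpperTail(10, 5, 4, 4),
               tolerance = 1e-12)
  # systematic sweep of small problems against the enumeration oracle
  set.seed(42)
  for (N in c(6, 9, 12, 15)) {
    uni <- sprintf("U%02d", seq_len(N))
    for (rep in 1:8) {
      K <- sample(seq_len(N), 1)
      n <- sample(seq_len(N - 1), 1)
      query <- sample(uni, n)
      ann <- annotationFor(list(pw = uni[seq_len(K)]), uni)
      k <- sum(query %in% uni[seq_len(K)])
      expect_equal(enrichmentTable(enrich(query, ann))$p,
                   enumUpperTail(N, K, n, k), tolerance = 1e-10,
                   info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
})

test_that("degenerate overlaps give p = 1", {
  uni <- sprintf("U%02d", 1:12)
  # zero overlap: upper tail at 0 is 1 exactly
  ann <- annotationFor(list(pw = uni[1:4]), uni)
  res <- enrich(uni[9:12], ann)
  expect_identical(enrichmentTable(res)$k, 0L)
  expect_equal(enrichmentTable(res)$p, 1)
  # K = N: the overlap is forced to n
  annAll <- annotationFor(list(pw = uni), uni)
  resAll <- enrich(uni[1:5], annAll)
  expect_identical(enrichmentTable(resAll)$k, 5L)
  expect_equal(enrichmentTable(resAll)$p, 1)
})

test_that("p equals the one-sided Fisher exact test on random tables", {
  set.seed(7)
  for (i in 1:100) {
    N <- sample(20:60, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    uni <- sprintf("U%03d", seq_len(N))
    query <- sample(uni, n)
    ann <- annotationFor(list(pw = uni[seq_len(K)]), uni)
    tab <- enrichmentTable(enrich(query, ann))
    k <- tab$k
    fisher <- stats::fisher.test(
      matrix(c(k, n - k, K - k, N - K - n + k), 2), alternative = "greater")
    expect_equal(tab$p, fisher$p.value, tolerance = 1e-9)
  }
})

test_that("empty universes and disjoint queries are rejected", {
  uni <- c("A", "B")
  ann <- annotationFor(list(pw = "A"), uni)
  expect_error(enrich(c("Z1", "Z2"), ann), "no ids in the universe")
  expect_error(enrich("A", ann, universe = "Q9"), "empty universe")
  # zero-size pathways (after restriction) are skipped
  ann2 <- annotationFor(list(pw1 = "A", pw2 = "C"), c("A", "B", "C"))
  res <- enrich("A", ann2, universe = c("A", "B"))
  expect_identical(enrichmentTable(res)$pathway, "pw1")
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustBH(0.04), 0.04)          # single p is its own q
  expect_equal(adjustBH(rep(0.2, 5)), rep(0.2, 5))  # all equal: q = p
  # order restored and monotone in sorted order
  p <- c(0.9, 0.001, 0.02, 0.04, 0.3)
  q <- adjustBH(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
  expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
  expect_error(adjustBH(c(0.5, NA)), "0, 1")
})

test_that("significance filtering is strict and sorted", {
  tab <- data.frame(pathway = c("a", "b", "c"), K = 5L, n = 4L,
                    k = c(3L, 2L, 1L), N = 20L,
                    p = c(0.04, 0.05, 0.06), q = c(0.12, 0.12, 0.12),
                    members = "")
  res <- new("EnrichmentResult", table = tab, universeSize = 20L,
             querySize = 4L)
  keep <- significantPathways(res, alpha = 0.05)
  expect_identical(keep$pathway, "a")   # 0.05 itself excluded
  expect_identical(nrow(significantPathways(res, alpha = 1.0)), 3L)
  expect_identical(nrow(significantPathways(res, alpha = 0.05, useQ = TRUE)), 0L)
})

test_that("top pathways rank by p with overlap and name tie-breaks", {
  tab <- data.frame(pathway = c("z", "a", "m", "b"), K = 10L, n = 5L,
                    k = c(4L, 2L, 4L, 1L), N = 50L,
                    p = c(0.01, 0.01, 0.01, 0.04),
                    q = c(0.02, 0.02, 0.02, 0.04), members = "")
  res <- new("EnrichmentResult", table = tab, universeSize = 50L,
             querySize = 5L)
  top <- topPathways(res, 3)
  expect_identical(top$pathway, c("m", "z", "a"))  # k desc, then name
  expect_identical(nrow(topPathways(res, 0)), 0L)
  expect_identical(nrow(topPathways(res, 99)), 4L)
  # full sort oracle on a generated fixture (alpha = 1 keeps p < 1 strictly)
  cfg <- smallConfig(seed = 8)
  ds <- generateStudyFixture(cfg)
  r <- enrich(ds@truth$plantedHubs, ds@geneSets)
  full <- enrichmentTable(r)
  sig <- significantPathways(r, alpha = 1, useQ = FALSE)
  ord <- order(full$p, -full$k, full$pathway)
  expect_identical(sig$pathway, full$pathway[ord][full$p[ord] < 1])
})

test_that("random queries yield a near-uniform false-positive rate", {
  # large balanced pathways keep the hypergeometric close to continuous
  set.seed(31)
  N <- 2000
  uni <- sprintf("U%04d", seq_len(N))
  sets <- lapply(1:150, function(i) sample(uni, 100))
  names(sets) <- sprintf("pw%03d", 1:150)
  ann <- annotationFor(sets, uni)
  fp <- vapply(1:10, function(i) {
    query <- sample(uni, 200)
    mean(enrichmentTable(enrich(query, ann))$p < 0.05)
  }, numeric(1))
  # 1500 near-independent tests: the rate should sit near alpha, below it
  # on average because the statistic is discrete
  expect_gt(mean(fp), 0.02)
  expect_lt(mean(fp), 0.07)
})

test_that("module assignment groups pathways by category", {
  sig <- data.frame(pathway = c("p1", "p2", "p3"), K = 5L, n = 3L,
                    k = 2L, N = 30L, p = 0.01, q = 0.02,
                    members = c("A;B", "B;C", "D"))
  map <- data.frame(pathway = c("p1", "p2"),
                    category = c("inflammation", "inflammation"))
  expect_warning(mods <- assignModules(sig, map), "uncategorized")
  expect_setequal(names(mods), c("inflammation", "uncategorized"))
  expect_identical(mods$inflammation$nPathways, 2L)
  # multi-membership: B appears once per category it hits
  expect_setequal(mods$inflammation$members, c("A", "B", "C"))
  expect_setequal(mods$uncategorized$members, "D")
  # single category -> one module; empty input -> empty partition
  map3 <- data.frame(pathway = c("p1", "p2", "p3"), category = "x")
  expect_length(assignModules(sig, map3), 1)
  expect_length(assignModules(sig[0, ], map3), 0)
})
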