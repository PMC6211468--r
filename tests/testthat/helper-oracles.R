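# Independent brute-force oracles for the topological metrics, built on
# adjacency matrices and matrix powers only — no igraph calls, so they stay
# independent of the implementation they check.

adjacencyOf <- function(net) {
  if (is(net, "InteractionNetwork")) {
    ids <- nodeIds(net)
    el <- igraph::as_edgelist(asIgraph(net), names = TRUE)
  } else stop("adjacencyOf expects an InteractionNetwork")
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(el)) {
    A[cbind(el[, 1], el[, 2])] <- 1
    A[cbind(el[, 2], el[, 1])] <- 1
  }
  A
}

# all-pairs shortest-path distances and geodesic counts via matrix powers:
# the first power d with (A^d)[s,t] > 0 gives the distance, and the entry
# itself counts the s-t geodesics (minimal walks are paths)
oraclePaths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  C <- matrix(0, n, n); diag(C) <- 1
  P <- A
  for (d in seq_len(max(n - 1, 1))) {
    hit <- P > 0 & !is.finite(D)
    if (any(hit)) {
      D[hit] <- d
      C[hit] <- P[hit]
    }
    P <- P %*% A
  }
  list(D = D, C = C)
}

oracleDegree <- function(A) rowSums(A)

oracleBetweenness <- function(A, normalized = TRUE) {
  n <- nrow(A)
  b <- numeric(n)
  if (n >= 3) {
    sp <- oraclePaths(A)
    D <- sp$D; C <- sp$C
    for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
      if (!is.finite(D[s, t])) next
      v <- setdiff(seq_len(n), c(s, t))
      on <- is.finite(D[s, v]) & is.finite(D[v, t]) &
        (D[s, v] + D[v, t] == D[s, t])
      b[v[on]] <- b[v[on]] + C[s, v[on]] * C[v[on], t] / C[s, t]
    }
  }
  if (normalized) b <- if (n < 3) numeric(n) else b / ((n - 1) * (n - 2) / 2)
  stats::setNames(b, rownames(A))
}

oracleCloseness <- function(A) {
  n <- nrow(A)
  D <- oraclePaths(A)$D
  out <- numeric(n)
  for (i in seq_len(n)) {
    comp <- which(is.finite(D[i, ]))
    r <- length(comp)
    if (r > 1 && n > 1)
      out[i] <- ((r - 1) / (n - 1)) * ((r - 1) / sum(D[i, comp]))
  }
  stats::setNames(out, rownames(A))
}

oracleCoreness <- function(A) {
  n <- nrow(A)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    k <- k + 1L
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])[alive]
      low <- deg < k
      if (!any(low)) break
      victims <- which(alive)[low]
      core[victims] <- k - 1L
      alive[victims] <- FALSE
      if (!any(alive)) break
    }
    if (any(alive) && all(rowSums(A[, alive, drop = FALSE])[alive] >= k))
      core[alive] <- k
  }
  stats::setNames(core, rownames(A))
}

# exhaustive enumeration of all labeled graphs on n nodes via edge bitmasks,
# keeping the connected ones
allConnectedLabeledGraphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  nP <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^nP) - 1L) {
    on <- bitwAnd(mask, 2^(seq_len(nP) - 1)) > 0
    if (sum(on) < n - 1) next
    A <- matrix(0, n, n)
    sel <- pairs[on, , drop = FALSE]
    A[sel] <- 1; A[sel[, 2:1, drop = FALSE]] <- 1
    R <- diag(n) + A
    for (i in seq_len(n - 1)) R <- R %*% (diag(n) + A)
    if (all(R > 0)) out[[length(out) + 1L]] <- A
  }
  out
}

netFromAdjacency <- function(A) {
  ids <- sprintf("N%02d", seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  interactionNetwork(ids, data.frame(from = ids[idx[, 1]],
                                     to = ids[idx[, 2]]))
}

randomNet <- function(n, m, seed) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("N%02d", seq_len(n)))
  el <- igraph::as_edgelist(g, names = TRUE)
  interactionNetwork(sprintf("N%02d", seq_len(n)),
                     data.frame(from = el[, 1], to = el[, 2]))
}
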