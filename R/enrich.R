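#' Hypergeometric over-representation analysis
#'
#' For each pathway with K members in the universe, a query of n ids drawn
#' from a universe of N, and an observed overlap of k, the p-value is the
#' hypergeometric upper tail `P(X >= k)` — the probability of an overlap at
#' least as large under random draws. Pathways with no members in the
#' universe are skipped. q-values are Benjamini-Hochberg adjusted over all
#' tested pathways.
#'
#' @param query character vector of ids (e.g. major hubs); restricted to the
#'   universe before testing.
#' @param annotation a [PathwayAnnotation-class].
#' @param universe `NULL` (the annotation's universe) or a character vector
#'   of background ids (e.g. the profiled network's nodes); pathways and
#'   query are restricted to it.
#' @return An [EnrichmentResult-class], rows in annotation order.
#' @export
enrich <- function(query, annotation, universe = NULL) {
  uni <- if (is.null(universe)) annotation@universe
         else intersect(unique(.normalizeId(universe)), annotation@universe)
  if (!length(uni)) stop("empty universe")
  q <- intersect(unique(.normalizeId(query)), uni)
  if (!length(q)) stop("query has no ids in the universe")
  N <- length(uni); n <- length(q)
  rows <- lapply(names(annotation@sets), function(nm) {
    mem <- intersect(annotation@sets[[nm]], uni)
    K <- length(mem)
    if (K == 0) return(NULL)
    ov <- intersect(mem, q)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, K = K, n = n, k = k, N = N, p = p,
               members = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(pathway = character(), K = integer(), n = integer(),
                      k = integer(), N = integer(), p = numeric(),
                      members = character(), stringsAsFactors = FALSE)
  tab$q <- adjustBH(tab$p)
  tab <- tab[, c("pathway", "K", "n", "k", "N", "p", "q", "members")]
  rownames(tab) <- NULL
  new("EnrichmentResult", table = tab, universeSize = as.integer(N),
      querySize = as.integer(n))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
adjustBH <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter significant pathways
#'
#' Strict `p < alpha` (the raw-p convention) or `q < alpha` (recommended
#' when many pathways are tested), sorted by ascending p.
#'
#' @param result an [EnrichmentResult-class].
#' @param alpha significance level (default 0.05).
#' @param useQ filter on BH q instead of raw p (default `FALSE`).
#' @return data.frame of significant rows, ascending p.
#' @export
significantPathways <- function(result, alpha = 0.05, useQ = FALSE) {
  tab <- result@table
  keep <- if (useQ) tab$q < alpha else tab$p < alpha
  out <- tab[keep, , drop = FALSE]
  out <- out[order(out$p, -out$k, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k remarkable pathways
#'
#' The k smallest p-values among the significant pathways; ties broken by
#' larger overlap, then pathway name.
#'
#' @param result an [EnrichmentResult-class].
#' @param k number of pathways to keep (default 10).
#' @param alpha,useQ significance filter, as in [significantPathways()].
#' @return data.frame of at most `k` rows.
#' @export
topPathways <- function(result, k = 10, alpha = 0.05, useQ = FALSE) {
  if (k < 0) stop("k must be >= 0")
  sig <- significantPathways(result, alpha, useQ)
  utils::head(sig, k)
}

#' Group significant pathways into functional modules
#'
#' Assigns each significant pathway to a category via a user-supplied map
#' and groups the pathways and their overlapping query members per
#' category. A member occurring in pathways of several categories is listed
#' in each (multi-membership).
#'
#' @param significant data.frame from [significantPathways()] (or an
#'   [EnrichmentResult-class], in which case the default filter is applied).
#' @param categoryMap data.frame with columns `pathway`, `category`.
#' @return named list; per category a list with `pathways`, `members`, and
#'   their counts. Pathways missing from the map go to `"uncategorized"`
#'   with a warning.
#' @export
assignModules <- function(significant, categoryMap) {
  if (is(significant, "EnrichmentResult"))
    significant <- significantPathways(significant)
  if (!all(c("pathway", "category") %in% names(categoryMap)))
    stop("categoryMap needs columns pathway, category")
  if (!nrow(significant)) return(list())
  cat <- categoryMap$category[match(significant$pathway, categoryMap$pathway)]
  if (anyNA(cat)) {
    warning(sum(is.na(cat)), " pathway(s) missing from the category map; ",
            "assigned 'uncategorized'")
    cat[is.na(cat)] <- "uncategorized"
  }
  out <- lapply(split(seq_len(nrow(significant)), cat), function(idx) {
    mem <- unique(unlist(strsplit(significant$members[idx], ";", fixed = TRUE)))
    mem <- mem[nzchar(mem)]
    list(pathways = significant$pathway[idx],
         nPathways = length(idx),
         members = sort(mem),
         nMembers = length(mem))
  })
  out
}
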