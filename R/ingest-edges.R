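#' Construct an EdgeTable from id pairs
#'
#' Normalizes orientation (unordered pairs stored with `from < to`), drops
#' self-loops, and collapses duplicates while concatenating their source
#' labels.
#'
#' @param from,to character vectors of endpoint ids (already normalized or
#'   not; ids are trimmed/upper-cased here).
#' @param sources per-edge provenance labels (recycled).
#' @return An [EdgeTable-class].
#' @export
EdgeTable <- function(from = character(), to = character(),
                      sources = "unknown") {
  from <- .normalizeId(from); to <- .normalizeId(to)
  sources <- rep_len(as.character(sources), length(from))
  ok <- nzchar(from) & nzchar(to)
  from <- from[ok]; to <- to[ok]; sources <- sources[ok]
  loop <- from == to
  from <- from[!loop]; to <- to[!loop]; sources <- sources[!loop]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  src <- vapply(split(sources, key), function(s)
    paste(unique(unlist(strsplit(s, ";", fixed = TRUE))), collapse = ";"),
    character(1))
  first <- !duplicated(key)
  edges <- data.frame(from = a[first], to = b[first],
                      sources = unname(src[key[first]]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new("EdgeTable", edges = edges)
}

#' Read a PPI edge list (TSV/CSV)
#'
#' Rows with missing/empty endpoints are skipped with a warning; the read
#' fails outright if more than `maxSkipFraction` of rows are unusable, so a
#' mis-declared column spec cannot silently truncate a database export.
#' Self-loops are dropped (count reported), orientation is normalized and
#' duplicate pairs collapsed.
#'
#' @param path TSV (default) or CSV file.
#' @param fromColumn,toColumn column names or 1-based indices of the two
#'   endpoint columns.
#' @param sourceLabel provenance label recorded on every edge.
#' @param header does the file have a header row?
#' @param idMap optional id mapping table, as in [readTargetTable()].
#' @param maxSkipFraction failure threshold for unparseable rows (default 0.1).
#' @return An [EdgeTable-class].
#' @export
readEdgeList <- function(path, fromColumn = 1, toColumn = 2,
                         sourceLabel = "unknown", header = TRUE,
                         idMap = NULL, maxSkipFraction = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(.readDelim(path, header = header), error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0) {
    warning("empty edge list: ", path)
    return(EdgeTable())
  }
  pick <- function(col) {
    if (is.numeric(col)) {
      if (col > ncol(tab)) stop("edge list ", path, " has no column ", col)
      tab[[col]]
    } else {
      if (!col %in% names(tab))
        stop("edge list ", path, " lacks declared column '", col, "'")
      tab[[col]]
    }
  }
  from <- .normalizeId(pick(fromColumn))
  to <- .normalizeId(pick(toColumn))
  bad <- !nzchar(from) | !nzchar(to) | is.na(from) | is.na(to)
  if (any(bad)) {
    warning(sum(bad), " unparseable row(s) skipped in ", basename(path))
    if (mean(bad) > maxSkipFraction)
      stop(sprintf("%.0f%% of rows in %s are unparseable (limit %.0f%%)",
                   100 * mean(bad), path, 100 * maxSkipFraction))
    from <- from[!bad]; to <- to[!bad]
  }
  from <- applyIdMap(from, idMap); to <- applyIdMap(to, idMap)
  nLoop <- sum(from == to)
  if (nLoop > 0)
    message(nLoop, " self-loop(s) dropped while reading ", basename(path))
  EdgeTable(from, to, sourceLabel)
}

#' Merge PPI edge tables
#'
#' Union of unordered pairs across sources; per-edge source lists are
#' preserved (`;`-joined, deduplicated).
#'
#' @param tables list of [EdgeTable-class] objects.
#' @return An [EdgeTable-class].
#' @export
mergePpiSources <- function(tables) {
  if (is(tables, "EdgeTable")) tables <- list(tables)
  if (!length(tables)) stop("need at least one EdgeTable")
  from <- unlist(lapply(tables, function(t) t@edges$from), use.names = FALSE)
  to <- unlist(lapply(tables, function(t) t@edges$to), use.names = FALSE)
  src <- unlist(lapply(tables, function(t) t@edges$sources), use.names = FALSE)
  EdgeTable(from, to, src)
}

#' Write an edge table as 2+1-column TSV
#'
#' @param x an [EdgeTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  utils::write.table(x@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
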