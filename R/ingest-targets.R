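.normalizeId <- function(x) toupper(trimws(as.character(x)))

.readDelim <- function(path, header = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.delim(path, sep = sep, header = header,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", blank.lines.skip = TRUE)
}

#' Construct a TargetSet from a data.frame
#'
#' Ids are trimmed and upper-cased; duplicate ids are collapsed first-seen.
#'
#' @param entries data.frame with at least an `id` column; `symbol` and
#'   `source` are filled from `id` / `sourceLabel` when absent.
#' @param sourceLabel provenance label used when `entries` has no `source`.
#' @return A [TargetSet-class].
#' @export
TargetSet <- function(entries = data.frame(id = character()),
                      sourceLabel = "unknown") {
  if (!"id" %in% names(entries)) stop("entries must have an 'id' column")
  entries$id <- .normalizeId(entries$id)
  entries <- entries[nzchar(entries$id), , drop = FALSE]
  if (!"symbol" %in% names(entries)) entries$symbol <- entries$id
  if (!"source" %in% names(entries))
    entries$source <- rep_len(sourceLabel, nrow(entries))
  entries$source[!nzchar(entries$source)] <- sourceLabel
  dup <- duplicated(entries$id)
  if (any(dup)) entries <- entries[!dup, , drop = FALSE]
  rownames(entries) <- NULL
  new("TargetSet", entries = entries[, union(c("id", "symbol", "source"),
                                             names(entries)), drop = FALSE])
}

#' Read a target table (TSV/CSV) into a TargetSet
#'
#' One row per target. Identifiers are treated as opaque strings after
#' trimming and upper-casing; an optional two-column mapping table can be
#' applied first (e.g. symbol -> accession) so that heterogeneous sources
#' land in one namespace before merging.
#'
#' @param path TSV (default) or CSV file with a header row.
#' @param sourceLabel provenance label recorded for every row (ignored when
#'   the file has its own `source` column).
#' @param idColumn name of the identifier column (default `"id"`).
#' @param symbolColumn optional name of a display-symbol column.
#' @param idMap optional data.frame (or path) with two columns mapping input
#'   ids to canonical ids; unmapped ids pass through unchanged.
#' @return A [TargetSet-class]. Duplicate ids are collapsed first-seen and
#'   the dropped count is reported via `message()`; an empty file yields an
#'   empty set with a warning.
#' @export
readTargetTable <- function(path, sourceLabel = "unknown", idColumn = "id",
                            symbolColumn = NULL, idMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(.readDelim(path), error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0) {
    warning("empty target table: ", path)
    return(TargetSet(data.frame(id = character()), sourceLabel))
  }
  if (!idColumn %in% names(tab))
    stop("target table ", path, " lacks declared id column '", idColumn, "'")
  if (!is.null(symbolColumn) && !symbolColumn %in% names(tab))
    stop("target table ", path, " lacks declared symbol column '",
         symbolColumn, "'")
  ids <- .normalizeId(tab[[idColumn]])
  ids <- applyIdMap(ids, idMap)
  entries <- data.frame(
    id = ids,
    symbol = if (is.null(symbolColumn)) ids else trimws(tab[[symbolColumn]]),
    source = if ("source" %in% names(tab)) tab[["source"]] else sourceLabel,
    stringsAsFactors = FALSE)
  entries <- entries[nzchar(entries$id), , drop = FALSE]
  nDup <- sum(duplicated(entries$id))
  if (nDup > 0)
    message(nDup, " duplicate id(s) collapsed while reading ", basename(path))
  TargetSet(entries, sourceLabel)
}

#' Apply an id mapping table
#'
#' @param ids character vector of (already normalized) ids.
#' @param idMap `NULL`, a two-column data.frame, or a path to a headerless
#'   two-column TSV (`from`, `to`). Unmapped ids pass through.
#' @return character vector of mapped ids.
#' @export
applyIdMap <- function(ids, idMap = NULL) {
  if (is.null(idMap)) return(ids)
  if (is.character(idMap) && length(idMap) == 1)
    idMap <- utils::read.delim(idMap, header = FALSE,
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  if (ncol(idMap) < 2) stop("id map needs two columns (from, to)")
  from <- .normalizeId(idMap[[1]]); to <- .normalizeId(idMap[[2]])
  hit <- match(ids, from)
  ifelse(is.na(hit), ids, to[hit])
}

#' Merge target sets by id
#'
#' Union by id; provenance labels of ids seen in several sets are
#' concatenated (`;`-joined, deduplicated). For non-key fields the
#' first-seen record wins.
#'
#' @param sets list of [TargetSet-class] objects (at least one).
#' @return A [TargetSet-class].
#' @export
mergeTargetSets <- function(sets) {
  if (is(sets, "TargetSet")) sets <- list(sets)
  if (!length(sets)) stop("need at least one TargetSet")
  all <- do.call(rbind, lapply(sets, function(s)
    s@entries[, c("id", "symbol", "source"), drop = FALSE]))
  if (!nrow(all)) return(TargetSet(data.frame(id = character())))
  src <- vapply(split(all$source, all$id), function(s)
    paste(unique(unlist(strsplit(s, ";", fixed = TRUE))), collapse = ";"),
    character(1))
  first <- all[!duplicated(all$id), , drop = FALSE]
  first$source <- unname(src[first$id])
  TargetSet(first)
}

#' Intersect two target sets by id
#'
#' Entries whose ids occur in both sets; sources from both are concatenated.
#'
#' @param a,b [TargetSet-class] objects.
#' @return A [TargetSet-class].
#' @export
intersectTargetSets <- function(a, b) {
  keep <- a@entries$id %in% b@entries$id
  out <- a@entries[keep, , drop = FALSE]
  if (nrow(out)) {
    bsrc <- b@entries$source[match(out$id, b@entries$id)]
    out$source <- vapply(seq_len(nrow(out)), function(i)
      paste(unique(unlist(strsplit(c(out$source[i], bsrc[i]), ";",
                                   fixed = TRUE))), collapse = ";"),
      character(1))
  }
  TargetSet(out)
}

#' Write a TargetSet as TSV
#'
#' @param x a [TargetSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTargetTable <- function(x, path) {
  utils::write.table(x@entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
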