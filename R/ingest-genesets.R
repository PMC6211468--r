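#' Construct a PathwayAnnotation
#'
#' @param sets named list of member id character vectors (ids normalized,
#'   deduplicated per set).
#' @param universe id universe; defaults to the union of all members.
#' @return A [PathwayAnnotation-class].
#' @export
PathwayAnnotation <- function(sets = list(), universe = NULL) {
  sets <- lapply(sets, function(m) unique(.normalizeId(m)))
  if (is.null(universe))
    universe <- unique(unlist(sets, use.names = FALSE))
  else
    universe <- unique(.normalizeId(universe))
  if (is.null(universe)) universe <- character()
  new("PathwayAnnotation", sets = sets, universe = universe)
}

#' Read gene sets in GMT format
#'
#' One pathway per line: name, description, then tab-separated member ids.
#' Duplicate members within a line are collapsed; a duplicated pathway name
#' or a line with fewer than three fields is an error naming the line.
#'
#' @param path GMT file.
#' @return A [PathwayAnnotation-class] whose universe is the union of all
#'   members. An empty file yields an empty annotation with a warning.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(PathwayAnnotation())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed GMT line ", which(nf < 3)[1], " in ", path,
         " (need name, description, >=1 member)")
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate pathway name '", nm[duplicated(nm)][1], "' in ", path)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  PathwayAnnotation(sets)
}

#' Write gene sets in GMT format
#'
#' @param annotation a [PathwayAnnotation-class].
#' @param path output file.
#' @param descriptions optional named character of per-pathway descriptions.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(annotation, path, descriptions = NULL) {
  nm <- names(annotation@sets)
  desc <- if (is.null(descriptions)) rep("na", length(nm)) else
    ifelse(is.na(descriptions[nm]), "na", descriptions[nm])
  lines <- vapply(seq_along(nm), function(i)
    paste(c(nm[i], desc[i], annotation@sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict an annotation to a universe
#'
#' Intersects every pathway and the universe with `ids`; pathways left empty
#' are kept (size 0) so that downstream code can skip them explicitly.
#'
#' @param annotation a [PathwayAnnotation-class].
#' @param ids character vector of ids to restrict to.
#' @return A [PathwayAnnotation-class].
#' @export
restrictAnnotation <- function(annotation, ids) {
  ids <- unique(.normalizeId(ids))
  keep <- intersect(annotation@universe, ids)
  PathwayAnnotation(lapply(annotation@sets, intersect, keep), keep)
}
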