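#' Construct a pathway set
#'
#' A pathway set maps pathway identifiers to sets of KO (KEGG orthology)
#' member identifiers. Members are deduplicated; pathway identifiers must be
#' unique and non-empty.
#'
#' @param members Named list; each element a character vector of KO ids.
#' @param descriptions Optional character vector of free-text descriptions,
#'   recycled to the number of pathways. Defaults to the pathway id.
#' @return An object of class `pathway_set`: a named list of character
#'   vectors with a `descriptions` attribute.
#' @examples
#' ps <- pathway_set(list(glycolysis = c("K00001", "K00002"),
#'                        tca        = c("K00030", "K00031", "K00032")))
#' ps
#' @export
pathway_set <- function(members, descriptions = NULL) {
  if (!is.list(members) || length(members) == 0L) {
    stop_validation("'members' must be a non-empty named list of character vectors")
  }
  ids <- names(members)
  if (is.null(ids) || any(is.na(ids)) || any(ids == "")) {
    stop_validation("every pathway must have a non-empty name")
  }
  if (anyDuplicated(ids)) {
    stop_validation("duplicate pathway ids: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(lengths(members) == 0L)) {
    stop_validation("pathways with zero members are not allowed")
  }
  if (is.null(descriptions)) descriptions <- ids
  descriptions <- rep_len(as.character(descriptions), length(members))
  names(descriptions) <- ids
  structure(members, descriptions = descriptions, class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  k <- lengths(x)
  cat(sprintf("Pathway set: %d pathways, sizes %d-%d (median %g)\n",
              length(x), min(k), max(k), stats::median(k)))
  show <- utils::head(names(x), 5L)
  for (id in show) {
    cat(sprintf("  %s (k = %d): %s%s\n", id, length(x[[id]]),
                paste(utils::head(x[[id]], 4L), collapse = ", "),
                if (length(x[[id]]) > 4L) ", ..." else ""))
  }
  if (length(x) > 5L) cat(sprintf("  ... and %d more\n", length(x) - 5L))
  invisible(x)
}

#' @export
`[.pathway_set` <- function(x, i) {
  out <- unclass(x)[i]
  pathway_set(out, descriptions = attr(x, "descriptions")[names(out)])
}

# Restrict a pathway set to a KO universe and drop pathways smaller than
# min_k after the intersection. Returns a plain named list plus the drop
# notice text (emitted by callers).
intersect_pathways <- function(pathways, universe, min_k) {
  kept <- lapply(pathways, function(m) intersect(m, universe))
  k <- lengths(kept)
  dropped <- names(kept)[k < min_k]
  if (length(dropped)) {
    message(sprintf("dropping %d pathway(s) with fewer than %d members in the KO universe: %s",
                    length(dropped), min_k, paste(dropped, collapse = ", ")))
  }
  kept[k >= min_k]
}
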