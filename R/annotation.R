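#' Translate protein identifiers through a mapping table
#'
#' Applies a two-column identifier mapping (e.g. UniProt to TAIR locus).
#' One-to-many mappings expand to all targets; identifiers absent from the
#' mapping are reported separately and excluded from the translated output.
#'
#' @param ids character vector of source identifiers.
#' @param mapping data frame whose first two columns are source and target
#'   identifiers.
#' @return list with elements `translated` (data frame `from`, `to`, one
#'   row per mapping hit, in the order of `ids`) and `unmapped` (character
#'   vector).
#' @export
translateIds <- function(ids, mapping) {
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  if (nrow(mapping) == 0L)
    stop("empty identifier mapping", call. = FALSE)
  from <- as.character(mapping[[1L]])
  to <- as.character(mapping[[2L]])
  ids <- as.character(ids)
  hits <- lapply(ids, function(id) to[from == id])
  mapped <- lengths(hits) > 0L
  translated <- data.frame(
    from = rep(ids[mapped], lengths(hits)[mapped]),
    to = unlist(hits[mapped], use.names = FALSE),
    stringsAsFactors = FALSE)
  list(translated = translated, unmapped = unique(ids[!mapped]))
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Extends each protein's direct term set with every ancestor of each
#' direct term (transitive `is_a`/`part_of` closure), the standard GO
#' true-path rule. Annotations to terms absent from the graph are skipped
#' (a single warning reports how many).
#'
#' @param annotations data frame with columns `protein_id`, `term_id`
#'   (direct annotations).
#' @param graph an [OntologyGraph-class].
#' @return data frame `protein_id`, `term_id` containing the direct
#'   annotations plus all propagated ones (unique rows, sorted).
#' @export
propagateAnnotations <- function(annotations, graph) {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "term_id") %in% colnames(annotations)))
  known <- annotations$term_id %in% termIds(graph)
  if (any(!known))
    warning(sum(!known), " annotation(s) to terms absent from the graph ",
            "were skipped")
  annotations <- annotations[known, , drop = FALSE]
  if (!nrow(annotations))
    return(data.frame(protein_id = character(), term_id = character(),
                      stringsAsFactors = FALSE))
  anc <- termAncestors(graph, unique(annotations$term_id))
  extraN <- lengths(anc)[annotations$term_id]
  out <- rbind(annotations[, c("protein_id", "term_id")],
               data.frame(protein_id = rep(annotations$protein_id, extraN),
                          term_id = unlist(anc[annotations$term_id],
                                           use.names = FALSE),
                          stringsAsFactors = FALSE))
  out <- unique(out)
  out <- out[order(out$protein_id, out$term_id), ]
  rownames(out) <- NULL
  out
}
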