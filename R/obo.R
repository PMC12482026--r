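#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas (id, name, namespace, `is_a`, and `part_of`
#' `relationship` lines), drops obsolete terms (and edges touching them),
#' ignores other stanza types, and returns a validated
#' [OntologyGraph-class]. Trailing `! comment` text on reference lines is
#' stripped. A cycle or a malformed stanza is an error (naming a cycle
#' member, or the offending line number).
#'
#' @param path path to an OBO file.
#' @return an [OntologyGraph-class].
#' @seealso [writeOBO()]
#' @export
parseOBO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  inTerm <- FALSE
  cur <- NULL
  curLine <- NA_integer_
  terms <- list()
  edges <- list()
  flush <- function() {
    if (is.null(cur)) return()
    if (is.na(cur$id) || !nzchar(cur$id))
      stop("malformed [Term] stanza at line ", curLine, ": missing id",
           call. = FALSE)
    if (!isTRUE(cur$obsolete)) {
      terms[[length(terms) + 1L]] <<- data.frame(
        id = cur$id,
        name = if (is.na(cur$name)) cur$id else cur$name,
        namespace = if (is.na(cur$namespace)) "unknown" else cur$namespace,
        stringsAsFactors = FALSE)
      if (length(cur$parents))
        edges[[length(edges) + 1L]] <<- data.frame(
          child = cur$id,
          parent = vapply(cur$parents, `[[`, character(1), "id"),
          relation = vapply(cur$parents, `[[`, character(1), "rel"),
          stringsAsFactors = FALSE)
    }
    cur <<- NULL
  }
  stripComment <- function(v) trimws(sub("!.*$", "", v))
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "[Term]") {
      flush()
      inTerm <- TRUE
      curLine <- i
      cur <- list(id = NA_character_, name = NA_character_,
                  namespace = NA_character_, obsolete = FALSE,
                  parents = list())
      next
    }
    if (grepl("^\\[", line)) {        # [Typedef] etc.
      flush()
      inTerm <- FALSE
      next
    }
    if (!inTerm || !nzchar(line)) next
    if (!grepl("^[A-Za-z_]+:", line))
      stop("malformed line ", i, " in [Term] stanza: '", line, "'",
           call. = FALSE)
    key <- sub(":.*$", "", line)
    value <- trimws(sub("^[A-Za-z_]+:", "", line))
    if (key == "id") cur$id <- value
    else if (key == "name") cur$name <- value
    else if (key == "namespace") cur$namespace <- value
    else if (key == "is_obsolete") cur$obsolete <- identical(value, "true")
    else if (key == "is_a")
      cur$parents[[length(cur$parents) + 1L]] <-
        list(id = stripComment(value), rel = "is_a")
    else if (key == "relationship") {
      parts <- strsplit(stripComment(value), "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of")
        cur$parents[[length(cur$parents) + 1L]] <-
          list(id = parts[2L], rel = "part_of")
    }
  }
  flush()
  terms <- if (length(terms)) do.call(rbind, terms) else
    data.frame(id = character(), name = character(),
               namespace = character(), stringsAsFactors = FALSE)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)
  # drop edges whose parent was obsolete or external to the file
  edges <- edges[edges$parent %in% terms$id & edges$child %in% terms$id, ,
                 drop = FALSE]
  rownames(edges) <- NULL
  OntologyGraph(terms, edges)
}

#' Write an OntologyGraph as a minimal OBO file
#'
#' Emits `format-version: 1.2` and one `[Term]` stanza per term with its
#' `is_a` and `relationship: part_of` lines, in a form [parseOBO()] reads
#' back into an identical graph.
#'
#' @param graph an [OntologyGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(graph, path) {
  stopifnot(is(graph, "OntologyGraph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  ed <- graph@edges
  for (i in seq_len(nrow(graph@terms))) {
    tm <- graph@terms[i, ]
    stanza <- c("[Term]",
                paste0("id: ", tm$id),
                paste0("name: ", tm$name),
                paste0("namespace: ", tm$namespace))
    mine <- ed[ed$child == tm$id, , drop = FALSE]
    if (nrow(mine)) {
      isa <- mine$parent[mine$relation == "is_a"]
      po <- mine$parent[mine$relation == "part_of"]
      stanza <- c(stanza,
                  if (length(isa)) paste0("is_a: ", isa),
                  if (length(po)) paste0("relationship: part_of ", po))
    }
    writeLines(c(stanza, ""), con)
  }
  invisible(path)
}

#' Ancestors of ontology terms
#'
#' Transitive closure of the child -> parent edges, optionally restricted
#' to a subset of relation types. The queried term itself is not included.
#'
#' @param graph an [OntologyGraph-class].
#' @param ids term ids to query; defaults to all terms.
#' @param relations edge types to traverse (default both `is_a` and
#'   `part_of`).
#' @return named list mapping each queried id to a character vector of
#'   ancestor ids.
#' @export
termAncestors <- function(graph, ids = NULL,
                          relations = c("is_a", "part_of")) {
  stopifnot(is(graph, "OntologyGraph"))
  all <- graph@terms$id
  if (is.null(ids)) ids <- all
  ed <- graph@edges[graph@edges$relation %in% relations, , drop = FALSE]
  parents <- split(ed$parent, factor(ed$child, levels = all))
  cache <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    ps <- parents[[id]]
    out <- if (is.null(ps) || !length(ps)) character(0) else
      unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    cache[[id]] <- out
    out
  }
  res <- lapply(ids, function(id) {
    if (!id %in% all) character(0) else anc(id)
  })
  names(res) <- ids
  res
}
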