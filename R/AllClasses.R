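#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Peptide-level quantification container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one linear-scale
#' intensity value per precursor (row) and sample (column). Row metadata
#' carries the precursor identifier and the protein group each precursor is
#' assigned to; column metadata carries the experimental condition of each
#' sample. Missing cells are `NA` (a precursor not observed in a run), never
#' zero. This is the entry point of the pipeline: both quantification methods
#' consume it.
#'
#' @slot ... inherited from `SummarizedExperiment`; the single assay is named
#'   `"intensity"`.
#'
#' @seealso [quantifyProteins()], [simulateDataset()], [readPeptideTable()]
#' @export
setClass("PeptideQuant", contains = "SummarizedExperiment")

setValidity("PeptideQuant", function(object) {
  msg <- character()
  if (!("intensity" %in% assayNames(object)))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- rowData(object)
  if (!all(c("precursor_id", "protein_group") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'precursor_id' and 'protein_group'")
  else if (anyDuplicated(rd$precursor_id))
    msg <- c(msg, "duplicated precursor_id")
  if (!("condition" %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'condition'")
  if ("intensity" %in% assayNames(object)) {
    x <- assay(object, "intensity")
    if (any(!is.na(x) & x <= 0))
      msg <- c(msg, "intensities must be strictly positive when present")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideQuant object
#'
#' @param intensity numeric matrix of linear-scale intensities, precursors in
#'   rows and samples in columns; `NA` marks a missing cell. Column names are
#'   the sample identifiers.
#' @param proteinGroup character vector assigning each precursor to exactly
#'   one protein group.
#' @param condition character or factor giving each sample's experimental
#'   condition (one per column of `intensity`).
#' @param precursorId precursor identifiers; defaults to the row names of
#'   `intensity`.
#'
#' @return A [PeptideQuant-class] object.
#' @examples
#' m <- matrix(2^rnorm(6, 20), 2, 3,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' pq <- PeptideQuant(m, proteinGroup = c("A", "A"),
#'                    condition = c("WT", "WT", "KO"))
#' @export
PeptideQuant <- function(intensity, proteinGroup, condition,
                         precursorId = rownames(intensity)) {
  intensity <- as.matrix(intensity)
  if (is.null(precursorId))
    precursorId <- sprintf("precursor%04d", seq_len(nrow(intensity)))
  if (is.null(colnames(intensity)))
    colnames(intensity) <- sprintf("sample%02d", seq_len(ncol(intensity)))
  rownames(intensity) <- precursorId
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(precursor_id = as.character(precursorId),
                        protein_group = as.character(proteinGroup)),
    colData = DataFrame(condition = as.character(condition),
                        row.names = colnames(intensity))
  )
  new("PeptideQuant", se)
}

#' Protein-level abundance container
#'
#' A [SummarizedExperiment::SummarizedExperiment] of protein-group log2
#' abundances (assay `"log2"`, rows = protein groups, columns = samples,
#' `NA` = missing). Row metadata records the number of peptides behind each
#' protein; the quantification method (`"maxlfq"` or `"summed"`) is stored in
#' the object metadata and is uniform for the whole matrix.
#'
#' @seealso [quantifyProteins()], [diffTest()]
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

setValidity("ProteinQuant", function(object) {
  msg <- character()
  if (!("log2" %in% assayNames(object)))
    msg <- c(msg, "assay 'log2' is required")
  if (!("n_peptides" %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must contain 'n_peptides'")
  if (is.null(metadata(object)$method) ||
      !metadata(object)$method %in% c("maxlfq", "summed"))
    msg <- c(msg, "metadata 'method' must be 'maxlfq' or 'summed'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated protein group")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinQuant object
#'
#' Usually produced by [quantifyProteins()]; the constructor is exported for
#' tests and for reading matrices back from disk.
#'
#' @param log2mat numeric matrix of log2 abundances (protein groups x
#'   samples), `NA` = missing.
#' @param nPeptides integer vector, peptides per protein group.
#' @param condition per-sample condition labels.
#' @param method `"maxlfq"` or `"summed"`.
#' @return A [ProteinQuant-class] object.
#' @export
ProteinQuant <- function(log2mat, nPeptides, condition,
                         method = c("maxlfq", "summed")) {
  method <- match.arg(method)
  log2mat <- as.matrix(log2mat)
  se <- SummarizedExperiment(
    assays = list(log2 = log2mat),
    rowData = DataFrame(n_peptides = as.integer(nPeptides),
                        row.names = rownames(log2mat)),
    colData = DataFrame(condition = as.character(condition),
                        row.names = colnames(log2mat)),
    metadata = list(method = method)
  )
  new("ProteinQuant", se)
}

#' Gene Ontology graph
#'
#' A rooted acyclic directed graph of ontology terms. `terms` is a data frame
#' with columns `id`, `name`, `namespace`; `edges` has columns `child`,
#' `parent`, `relation` with `relation` either `"is_a"` or `"part_of"` and
#' edges pointing child -> parent. Validity enforces acyclicity, edge
#' endpoints, and that `is_a` edges never cross namespaces.
#'
#' @seealso [parseOBO()], [simulateOntology()], [termAncestors()]
#' @export
setClass("OntologyGraph",
         representation(terms = "data.frame", edges = "data.frame"))

# Kahn's algorithm; returns character(0) when acyclic, otherwise the ids
# left with unresolved in-edges (members of at least one cycle)
.cycleMembers <- function(ids, edges) {
  # edges are directed child -> parent; in-degree counts a node's children
  indeg <- setNames(integer(length(ids)), ids)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  outEdges <- split(edges$parent, edges$child)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in outEdges[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(ids)) character(0) else names(indeg)[indeg > 0L]
}

setValidity("OntologyGraph", function(object) {
  msg <- character()
  tm <- object@terms
  ed <- object@edges
  if (!all(c("id", "name", "namespace") %in% colnames(tm)))
    msg <- c(msg, "terms must have columns id, name, namespace")
  else if (anyDuplicated(tm$id))
    msg <- c(msg, "duplicated term id")
  if (!all(c("child", "parent", "relation") %in% colnames(ed)))
    msg <- c(msg, "edges must have columns child, parent, relation")
  else {
    if (!all(ed$relation %in% c("is_a", "part_of")))
      msg <- c(msg, "edge relation must be is_a or part_of")
    if (!all(c(ed$child, ed$parent) %in% tm$id))
      msg <- c(msg, "edge endpoint not among terms")
    else {
      isa <- ed[ed$relation == "is_a", , drop = FALSE]
      if (nrow(isa)) {
        ns <- setNames(tm$namespace, tm$id)
        if (any(ns[isa$child] != ns[isa$parent]))
          msg <- c(msg, "is_a edge crosses namespaces")
      }
      cyc <- .cycleMembers(tm$id, ed)
      if (length(cyc))
        msg <- c(msg, sprintf("graph contains a cycle (e.g. through '%s')",
                              cyc[[1L]]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn OntologyGraph-class constructor.
#' @param terms data frame with columns `id`, `name`, `namespace`.
#' @param edges data frame with columns `child`, `parent`, `relation`.
#' @export
OntologyGraph <- function(terms,
                          edges = data.frame(child = character(),
                                             parent = character(),
                                             relation = character())) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  rownames(edges) <- NULL
  new("OntologyGraph", terms = terms, edges = edges)
}

setMethod("show", "PeptideQuant", function(object) {
  cat(sprintf("PeptideQuant: %d precursors x %d samples, %d protein groups\n",
              nrow(object), ncol(object),
              length(unique(rowData(object)$protein_group))))
  cat("conditions:",
      paste(sprintf("%s (%d)", names(table(colData(object)$condition)),
                    table(colData(object)$condition)), collapse = ", "), "\n")
  x <- assay(object, "intensity")
  cat(sprintf("missing cells: %.1f%%\n", 100 * mean(is.na(x))))
})

setMethod("show", "ProteinQuant", function(object) {
  cat(sprintf("ProteinQuant (%s): %d protein groups x %d samples\n",
              metadata(object)$method, nrow(object), ncol(object)))
  x <- assay(object, "log2")
  cat(sprintf("missing cells: %.1f%%\n", 100 * mean(is.na(x))))
})

setMethod("show", "OntologyGraph", function(object) {
  cat(sprintf("OntologyGraph: %d terms, %d edges (%d is_a, %d part_of)\n",
              nrow(object@terms), nrow(object@edges),
              sum(object@edges$relation == "is_a"),
              sum(object@edges$relation == "part_of")))
  cat("namespaces:", paste(unique(object@terms$namespace), collapse = ", "),
      "\n")
})
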