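#' Sample design of a quantification container
#'
#' @param object a [PeptideQuant-class] or [ProteinQuant-class] object.
#' @return data frame with columns `sample_id` and `condition`.
#' @export
setGeneric("sampleDesign", function(object) standardGeneric("sampleDesign"))

#' @rdname sampleDesign
setMethod("sampleDesign", "SummarizedExperiment", function(object) {
  data.frame(sample_id = colnames(object),
             condition = as.character(colData(object)$condition),
             stringsAsFactors = FALSE)
})

#' Quantification method tag of a ProteinQuant object
#'
#' @param object a [ProteinQuant-class] object.
#' @return `"maxlfq"` or `"summed"`.
#' @export
setGeneric("quantMethod", function(object) standardGeneric("quantMethod"))

#' @rdname quantMethod
setMethod("quantMethod", "ProteinQuant", function(object) {
  metadata(object)$method
})

#' Peptides per protein group
#'
#' @param object a [ProteinQuant-class] object.
#' @return named integer vector.
#' @export
setGeneric("nPeptides", function(object) standardGeneric("nPeptides"))

#' @rdname nPeptides
setMethod("nPeptides", "ProteinQuant", function(object) {
  setNames(rowData(object)$n_peptides, rownames(object))
})

#' Term identifiers of an ontology graph
#'
#' @param object an [OntologyGraph-class] object.
#' @return character vector of term ids.
#' @export
setGeneric("termIds", function(object) standardGeneric("termIds"))

#' @rdname termIds
setMethod("termIds", "OntologyGraph", function(object) object@terms$id)

#' Term metadata of an ontology graph
#'
#' @param object an [OntologyGraph-class] object.
#' @return data frame with columns `id`, `name`, `namespace`.
#' @export
setGeneric("termInfo", function(object) standardGeneric("termInfo"))

#' @rdname termInfo
setMethod("termInfo", "OntologyGraph", function(object) object@terms)

#' Roll peptide intensities up to protein-group abundances
#'
#' @param object a [PeptideQuant-class] object.
#' @param method `"maxlfq"` (pairwise median log-ratios + least squares) or
#'   `"summed"` (log2 of summed linear intensities).
#' @param minShared minimum number of peptides observed in both samples for
#'   a sample pair to contribute a ratio (MaxLFQ only).
#' @param medianCenter if `TRUE`, center each sample's protein estimates on a
#'   common median after rollup (off by default; cross-run normalization is
#'   assumed to have happened upstream).
#' @return a [ProteinQuant-class] object.
#' @export
setGeneric("quantifyProteins",
           function(object, method = c("maxlfq", "summed"), minShared = 1L,
                    medianCenter = FALSE)
             standardGeneric("quantifyProteins"))

#' Differential abundance testing with permutation FDR
#'
#' @param object a [ProteinQuant-class] object.
#' @param ... passed to methods.
#' @return a [S4Vectors::DataFrame] of per-protein statistics; see
#'   [diffTest,ProteinQuant-method].
#' @export
setGeneric("diffTest", function(object, ...) standardGeneric("diffTest"))
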