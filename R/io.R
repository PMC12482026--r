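# On-disk formats. One tabular dialect throughout: TSV, UTF-8, header row,
# empty field = missing, numerics serialized at full precision (%.17g) so
# every writer/reader pair round-trips exactly.

.formatColumn <- function(x) {
  if (is.double(x)) {
    vapply(x, function(v) if (is.na(v)) "" else sprintf("%.17g", v),
           character(1))
  } else {
    out <- as.character(x)
    out[is.na(out)] <- ""
    out
  }
}

.writeTSV <- function(df, path) {
  cells <- vapply(df, .formatColumn, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(colnames(df), collapse = "\t"),
             if (nrow(df)) apply(cells, 1L, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# strict TSV reader: uniform field counts (error names the line), header row,
# empty field -> NA
.readTSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; pad to header width, but a row
  # *longer* than the header is ragged
  header <- parts[[1L]]
  nc <- length(header)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) > nc)
      stop("ragged row at line ", i, " of ", path, call. = FALSE)
    if (length(parts[[i]]) < nc)
      parts[[i]] <- c(parts[[i]], rep("", nc - length(parts[[i]])))
  }
  body <- parts[-1L]
  df <- as.data.frame(
    lapply(seq_len(nc), function(j)
      vapply(body, `[[`, character(1), j)),
    stringsAsFactors = FALSE, optional = TRUE)
  colnames(df) <- header
  df[df == ""] <- NA
  df
}

.numericColumn <- function(chr, path, column) {
  out <- suppressWarnings(as.numeric(chr))
  bad <- which(!is.na(chr) & is.na(out))
  if (length(bad))
    stop("non-numeric value '", chr[bad[1L]], "' in column '", column,
         "' at line ", bad[1L] + 1L, " of ", path, call. = FALSE)
  out
}

#' Write / read a peptide quantification table
#'
#' Wide TSV: `precursor_id`, `protein_group`, then one linear-intensity
#' column per sample; empty field = missing.
#'
#' @param object a [PeptideQuant-class].
#' @param path file path.
#' @return `writePeptideTable` returns `path` invisibly;
#'   `readPeptideTable` returns a [PeptideQuant-class].
#' @export
writePeptideTable <- function(object, path) {
  stopifnot(is(object, "PeptideQuant"))
  x <- assay(object, "intensity")
  df <- data.frame(precursor_id = rowData(object)$precursor_id,
                   protein_group = rowData(object)$protein_group,
                   stringsAsFactors = FALSE)
  for (s in colnames(x)) df[[s]] <- x[, s]
  .writeTSV(df, path)
}

#' @rdname writePeptideTable
#' @param design sample design: a data frame with columns `sample_id`,
#'   `condition`, or a path to one written by [writeSampleDesign()].
#' @export
readPeptideTable <- function(path, design) {
  if (is.character(design)) design <- readSampleDesign(design)
  df <- .readTSV(path)
  need <- c("precursor_id", "protein_group")
  if (!all(need %in% colnames(df)))
    stop("peptide table needs columns precursor_id and protein_group",
         call. = FALSE)
  if (anyDuplicated(df$precursor_id))
    stop("duplicate precursor_id in ", path, call. = FALSE)
  sampleCols <- setdiff(colnames(df), need)
  unknown <- setdiff(sampleCols, design$sample_id)
  if (length(unknown))
    stop("sample(s) missing from design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  x <- vapply(sampleCols, function(s) .numericColumn(df[[s]], path, s),
              numeric(nrow(df)))
  if (is.null(dim(x))) x <- matrix(x, nrow = nrow(df),
                                   dimnames = list(NULL, sampleCols))
  rownames(x) <- df$precursor_id
  PeptideQuant(x, proteinGroup = df$protein_group,
               condition = design$condition[match(sampleCols,
                                                  design$sample_id)],
               precursorId = df$precursor_id)
}

#' Write / read a sample design table
#'
#' Two-column TSV: `sample_id`, `condition`.
#'
#' @param design data frame with columns `sample_id`, `condition` (an
#'   object with a [sampleDesign()] method is also accepted).
#' @param path file path.
#' @export
writeSampleDesign <- function(design, path) {
  if (is(design, "SummarizedExperiment")) design <- sampleDesign(design)
  .writeTSV(design[, c("sample_id", "condition")], path)
}

#' @rdname writeSampleDesign
#' @export
readSampleDesign <- function(path) {
  df <- .readTSV(path)
  if (!all(c("sample_id", "condition") %in% colnames(df)))
    stop("design needs columns sample_id and condition", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", path, call. = FALSE)
  df
}

#' Write / read a protein quantification matrix
#'
#' TSV: `protein_group`, `n_peptides`, then one log2-abundance column per
#' sample; empty field = missing. The file itself is method-agnostic; the
#' caller restores the method tag via the `method` argument on read.
#'
#' @param object a [ProteinQuant-class].
#' @param path file path.
#' @export
writeProteinMatrix <- function(object, path) {
  stopifnot(is(object, "ProteinQuant"))
  x <- assay(object, "log2")
  df <- data.frame(protein_group = rownames(x),
                   n_peptides = rowData(object)$n_peptides,
                   stringsAsFactors = FALSE)
  for (s in colnames(x)) df[[s]] <- x[, s]
  .writeTSV(df, path)
}

#' @rdname writeProteinMatrix
#' @param design sample design data frame or path (see
#'   [readPeptideTable()]).
#' @param method method tag to restore (`"maxlfq"` or `"summed"`).
#' @export
readProteinMatrix <- function(path, design, method = c("maxlfq", "summed")) {
  method <- match.arg(method)
  if (is.character(design)) design <- readSampleDesign(design)
  df <- .readTSV(path)
  need <- c("protein_group", "n_peptides")
  if (!all(need %in% colnames(df)))
    stop("protein matrix needs columns protein_group and n_peptides",
         call. = FALSE)
  if (anyDuplicated(df$protein_group))
    stop("duplicate protein_group in ", path, call. = FALSE)
  sampleCols <- setdiff(colnames(df), need)
  x <- vapply(sampleCols, function(s) .numericColumn(df[[s]], path, s),
              numeric(nrow(df)))
  if (is.null(dim(x))) x <- matrix(x, nrow = nrow(df),
                                   dimnames = list(NULL, sampleCols))
  rownames(x) <- df$protein_group
  ProteinQuant(x,
               nPeptides = .numericColumn(df$n_peptides, path, "n_peptides"),
               condition = design$condition[match(sampleCols,
                                                  design$sample_id)],
               method = method)
}

#' Write / read protein-to-term annotations
#'
#' Two-column TSV `protein_id`, `term_id`. `readAnnotations` also accepts
#' GAF 2.x files (17 tab-separated columns, `!` comment lines), from which
#' columns 2 (object id) and 5 (term id) are extracted.
#'
#' @param annotations data frame `protein_id`, `term_id`.
#' @param path file path.
#' @export
writeAnnotations <- function(annotations, path) {
  .writeTSV(annotations[, c("protein_id", "term_id")], path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, "!")) {        # GAF
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 5L)
    if (length(short))
      stop("malformed GAF row at line ", short[1L], " of ", path,
           call. = FALSE)
    return(data.frame(
      protein_id = vapply(parts, `[[`, character(1), 2L),
      term_id = vapply(parts, `[[`, character(1), 5L),
      stringsAsFactors = FALSE))
  }
  df <- .readTSV(path)
  if (!all(c("protein_id", "term_id") %in% colnames(df)))
    stop("annotation table needs columns protein_id and term_id",
         call. = FALSE)
  df
}

#' Write / read a two-column identifier mapping
#'
#' TSV with columns `from`, `to` (e.g. UniProt accession to TAIR locus).
#'
#' @param mapping data frame whose first two columns are source and target
#'   ids.
#' @param path file path.
#' @export
writeIdMapping <- function(mapping, path) {
  df <- data.frame(from = as.character(mapping[[1L]]),
                   to = as.character(mapping[[2L]]),
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' @rdname writeIdMapping
#' @export
readIdMapping <- function(path) {
  df <- .readTSV(path)
  if (ncol(df) < 2L)
    stop("identifier mapping needs two columns", call. = FALSE)
  df[, 1:2]
}

#' Write / read a differential-testing result table
#'
#' Flat TSV of the [diffTest()] DataFrame with the protein group as first
#' column; the pair list and experiment tag are restored on read from the
#' column layout.
#'
#' @param result a [diffTest()] result.
#' @param path file path.
#' @export
writeDiffResult <- function(result, path) {
  df <- as.data.frame(result)
  df <- cbind(data.frame(protein_group = rownames(df),
                         stringsAsFactors = FALSE), df)
  rownames(df) <- NULL
  .writeTSV(df, path)
}

#' @rdname writeDiffResult
#' @export
readDiffResult <- function(path) {
  df <- .readTSV(path)
  out <- DataFrame(df[, -1L, drop = FALSE],
                   row.names = df$protein_group)
  for (cn in colnames(out)) {
    if (cn == "significant") {
      out[[cn]] <- as.logical(out[[cn]])
    } else if (!startsWith(cn, "nValid_")) {
      out[[cn]] <- .numericColumn(out[[cn]], path, cn)
    } else {
      out[[cn]] <- as.integer(out[[cn]])
    }
  }
  pairs <- sub("^q_", "", grep("^q_", colnames(out), value = TRUE))
  conds <- sub("^nValid_", "", grep("^nValid_", colnames(out), value = TRUE))
  metadata(out) <- list(conditions = conds, pairs = pairs,
                        experiment = if ("anova_q" %in% colnames(out))
                          "overexpression" else "knockout")
  out
}

#' Write a generic result table (enrichment, volcano, term scores, truth)
#'
#' Plain TSV writers/readers used by [runPipeline()] for its remaining
#' outputs; numeric columns round-trip at full precision.
#'
#' @param df data frame.
#' @param path file path.
#' @export
writeResultTable <- function(df, path) {
  .writeTSV(as.data.frame(df), path)
}

#' @rdname writeResultTable
#' @param numeric character vector of column names to parse as numeric.
#' @export
readResultTable <- function(path, numeric = character()) {
  df <- .readTSV(path)
  for (cn in intersect(numeric, colnames(df)))
    df[[cn]] <- .numericColumn(df[[cn]], path, cn)
  df
}

#' Write / read a term-score matrix
#'
#' TSV: `term`, then one score column per sample.
#'
#' @param scores matrix from [termScoreMatrix()].
#' @param path file path.
#' @export
writeTermScores <- function(scores, path) {
  df <- data.frame(term = rownames(scores), stringsAsFactors = FALSE)
  for (s in colnames(scores)) df[[s]] <- scores[, s]
  .writeTSV(df, path)
}

#' @rdname writeTermScores
#' @export
readTermScores <- function(path) {
  df <- .readTSV(path)
  x <- vapply(setdiff(colnames(df), "term"),
              function(s) .numericColumn(df[[s]], path, s),
              numeric(nrow(df)))
  if (is.null(dim(x))) x <- matrix(x, nrow = nrow(df))
  rownames(x) <- df$term
  colnames(x) <- setdiff(colnames(df), "term")
  x
}

#' Write the simulator ground truth
#'
#' Protein-level truth as TSV (`protein_group`, `regulated`, one
#' `lfc_<condition>` column per condition).
#'
#' @param truth the `truth` element of [simulateDataset()].
#' @param path file path.
#' @export
writeTruth <- function(truth, path) {
  .writeTSV(truth$proteins, path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  df <- .readTSV(path)
  df$regulated <- as.logical(df$regulated)
  for (cn in grep("^lfc_", colnames(df), value = TRUE))
    df[[cn]] <- .numericColumn(df[[cn]], path, cn)
  df
}
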