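#' Quantitative term-score matrix (term x sample)
#'
#' Summarizes protein-level abundances per ontology term and sample, for
#' heatmap-style overviews of regulated processes. The score of term `t`
#' in sample `s` is the weighted average of the term's member proteins
#' detected in that sample,
#' `score(t, s) = sum_i w_i x_is / sum_i w_i`, with `w_i = 1` for
#' `mode = "none"` (simple average) or `w_i = -log10(p_i)` for
#' `mode = "significance"`, where `p_i` is the protein's parametric ANOVA
#' p-value (clamped to `>= 1e-300`; proteins with an undefined p get
#' weight 0). Unweighted scores show terms whose members change globally;
#' significance weighting highlights terms that are flat on average but
#' contain strongly regulated members. Rows are then z-scored
#' (population SD; zero-variance rows become all zeros) unless
#' `zscore = FALSE`.
#'
#' @param object a [ProteinQuant-class] object (or plain log2 matrix with
#'   protein-group rownames).
#' @param annotations data frame `protein_id`, `term_id`.
#' @param anovaP named numeric vector of parametric ANOVA p-values per
#'   protein; required for `mode = "significance"`.
#' @param mode `"none"` or `"significance"`.
#' @param graph optional [OntologyGraph-class] for annotation propagation.
#' @param propagate propagate annotations first (default `TRUE` when a
#'   graph is supplied).
#' @param zscore apply row-wise z-score normalization (default `TRUE`).
#' @return numeric matrix (terms x samples). Terms with no detected member
#'   are absent; attribute `"weighting"` records the mode, `"zscored"` the
#'   normalization flag, and `"low_support"` flags terms with fewer than 2
#'   detected members.
#' @export
termScoreMatrix <- function(object, annotations, anovaP = NULL,
                            mode = c("none", "significance"), graph = NULL,
                            propagate = TRUE, zscore = TRUE) {
  mode <- match.arg(mode)
  mat <- if (is(object, "ProteinQuant")) assay(object, "log2") else
    as.matrix(object)
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (propagate && !is.null(graph))
    annotations <- propagateAnnotations(annotations, graph)
  annotations <- annotations[annotations$protein_id %in% rownames(mat), ,
                             drop = FALSE]
  annotations <- unique(annotations[, c("protein_id", "term_id")])
  if (!nrow(annotations))
    stop("no annotated protein present in the abundance matrix",
         call. = FALSE)
  if (mode == "significance") {
    if (is.null(anovaP))
      stop("'anovaP' is required for significance weighting", call. = FALSE)
    w <- -log10(pmax(anovaP[rownames(mat)], 1e-300))
    w[is.na(w)] <- 0
  } else {
    w <- rep(1, nrow(mat))
  }
  names(w) <- rownames(mat)

  termsAll <- sort(unique(annotations$term_id))
  # weight matrix W (terms x proteins): w_i where protein i belongs to term
  W <- matrix(0, length(termsAll), nrow(mat),
              dimnames = list(termsAll, rownames(mat)))
  W[cbind(match(annotations$term_id, termsAll),
          match(annotations$protein_id, rownames(mat)))] <-
    w[annotations$protein_id]
  obsMask <- !is.na(mat)
  x0 <- mat
  x0[!obsMask] <- 0
  num <- W %*% x0
  den <- W %*% obsMask
  score <- num / den
  score[den == 0] <- NA_real_

  memberCounts <- as.integer(table(factor(annotations$term_id,
                                          levels = termsAll)))
  keep <- rowSums(!is.na(score)) > 0L
  score <- score[keep, , drop = FALSE]
  lowSupport <- setNames(memberCounts < 2L, termsAll)[keep]
  if (zscore) score <- .zscoreRows(score)
  attr(score, "weighting") <- mode
  attr(score, "zscored") <- isTRUE(zscore)
  attr(score, "low_support") <- lowSupport
  score
}
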