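#' @describeIn diffTest Welch and (for three conditions) ANOVA statistics
#'   with permutation-based FDR on a protein-level log2 abundance matrix.
#'
#'   For every condition pair `(a, b)` with `a` earlier in the condition
#'   order (condition 1 = reference), the log2 difference of condition
#'   means (`b - a`, over valid values only), the Welch t statistic with
#'   parametric p, and the permutation q-value are reported under columns
#'   suffixed `<b>_vs_<a>`. With three conditions a one-way ANOVA F,
#'   parametric p and permutation q are added. Valid-value counts per
#'   condition and a `significant` flag (the experiment's significance
#'   cascade at its default thresholds, see [filterOverexpression()] and
#'   [filterKnockout()]) complete the table. Pairwise permutations shuffle
#'   labels within the pair's samples; ANOVA permutations shuffle all
#'   samples.
#'
#' @param experiment `"auto"` picks `"overexpression"` for three conditions
#'   and `"knockout"` for two.
#' @param nPerm permutation budget per test family (exhaustive enumeration
#'   is used when possible; `choose(10, 5) = 252` for 5 vs 5).
#' @param seed integer seed for sampled permutations.
#' @export
setMethod("diffTest", "ProteinQuant",
          function(object, experiment = c("auto", "overexpression", "knockout"),
                   nPerm = 1000, seed = 1) {
  experiment <- match.arg(experiment)
  mat <- assay(object, "log2")
  condition <- as.character(colData(object)$condition)
  conds <- unique(condition)
  if (length(conds) < 2L)
    stop("need at least two conditions", call. = FALSE)
  if (experiment == "auto")
    experiment <- if (length(conds) >= 3L) "overexpression" else "knockout"
  if (experiment == "overexpression" && length(conds) < 3L)
    stop("the overexpression design needs three conditions", call. = FALSE)
  if (any(table(condition) < 2L))
    stop("need at least two samples per condition", call. = FALSE)

  res <- DataFrame(row.names = rownames(mat))
  condIdx <- lapply(conds, function(cc) which(condition == cc))
  names(condIdx) <- conds
  for (cc in conds)
    res[[paste0("nValid_", cc)]] <-
      as.integer(rowSums(!is.na(mat[, condIdx[[cc]], drop = FALSE])))

  pairs <- utils::combn(conds, 2L)
  pairNames <- character(ncol(pairs))
  diffs <- matrix(NA_real_, nrow(mat), ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    pairNames[k] <- paste0(b, "_vs_", a)
    w <- .rowWelchFull(mat, condIdx[[b]], condIdx[[a]])
    mb <- rowMeans(mat[, condIdx[[b]], drop = FALSE], na.rm = TRUE)
    ma <- rowMeans(mat[, condIdx[[a]], drop = FALSE], na.rm = TRUE)
    d <- mb - ma
    d[!is.finite(d)] <- NA_real_
    diffs[, k] <- d
    sub <- c(condIdx[[a]], condIdx[[b]])
    q <- permutationFDR(mat[, sub, drop = FALSE], condition[sub],
                        statistic = "welch", nPerm = nPerm, seed = seed + k)
    res[[paste0("diff_", pairNames[k])]] <- unname(d)
    res[[paste0("t_", pairNames[k])]] <- unname(w$t)
    res[[paste0("p_", pairNames[k])]] <- unname(w$p)
    res[[paste0("q_", pairNames[k])]] <- unname(q)
  }
  res$maxAbsDiff <- unname(apply(abs(diffs), 1L, function(z) {
    if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)
  }))

  if (length(conds) >= 3L) {
    an <- .rowAnovaF(mat, condIdx, pvalues = TRUE)
    res$anova_F <- unname(an$F)
    res$anova_p <- unname(an$p)
    res$anova_q <- unname(permutationFDR(mat, condition, statistic = "anova",
                                         nPerm = nPerm, seed = seed))
  }

  metadata(res) <- list(conditions = conds, pairs = pairNames,
                        experiment = experiment, nPerm = nPerm, seed = seed)
  res$significant <- if (experiment == "overexpression") {
    rownames(res) %in% filterOverexpression(res)
  } else {
    rownames(res) %in% filterKnockout(res)
  }
  res
})

.pairColumns <- function(result, prefix) {
  pairs <- metadata(result)$pairs
  if (is.null(pairs))
    pairs <- sub(paste0("^", prefix, "_"), "",
                 grep(paste0("^", prefix, "_"), colnames(result), value = TRUE))
  paste0(prefix, "_", pairs)
}

#' Significance cascade for the three-condition (overexpression) design
#'
#' A protein is significantly regulated when it meets all four criteria:
#' valid at `qThreshold` FDR in at least one pairwise Welch test
#' (permutation-corrected), valid at `qThreshold` FDR in the
#' all-conditions ANOVA, at least a `fcThreshold`-fold difference in some
#' inter-group comparison (i.e. `maxAbsDiff >= log2(fcThreshold)`), and a
#' minimum of `minValid` valid values in every condition. Proteins with a
#' missing q-value in any required test are excluded (reported via a
#' message).
#'
#' @param result a [diffTest()] table from a three-condition experiment.
#' @param qThreshold FDR threshold (default 0.01).
#' @param fcThreshold linear fold-change threshold (default 2).
#' @param minValid minimum valid values per condition (default 4).
#' @return character vector of significant protein groups.
#' @export
filterOverexpression <- function(result, qThreshold = 0.01, fcThreshold = 2,
                                 minValid = 4) {
  qCols <- .pairColumns(result, "q")
  if (!all(qCols %in% colnames(result)) || !("anova_q" %in% colnames(result)))
    stop("result lacks pairwise Welch and/or ANOVA q-values", call. = FALSE)
  qmat <- as.matrix(as.data.frame(result[, qCols, drop = FALSE]))
  nValidCols <- grep("^nValid_", colnames(result), value = TRUE)
  nv <- as.matrix(as.data.frame(result[, nValidCols, drop = FALSE]))
  incomplete <- rowSums(is.na(qmat)) == ncol(qmat) | is.na(result$anova_q) |
    is.na(result$maxAbsDiff)
  if (any(incomplete))
    message(sum(incomplete), " protein(s) excluded for undefined statistics")
  minQ <- suppressWarnings(apply(qmat, 1L, min, na.rm = TRUE))
  keep <- !incomplete &
    minQ <= qThreshold &
    result$anova_q <= qThreshold &
    result$maxAbsDiff >= log2(fcThreshold) &
    rowSums(nv >= minValid) == ncol(nv)
  rownames(result)[which(keep)]
}

#' Significance cascade for the two-condition (knockout) design
#'
#' A protein is significantly regulated when its Welch permutation q-value
#' is at most `qThreshold` and the absolute log2 difference of condition
#' means is at least `minAbsLog2`.
#'
#' @param result a [diffTest()] table from a two-condition experiment.
#' @param qThreshold FDR threshold (default 0.01).
#' @param minAbsLog2 minimum |log2 difference| between groups (default 0.8).
#' @return character vector of significant protein groups.
#' @export
filterKnockout <- function(result, qThreshold = 0.01, minAbsLog2 = 0.8) {
  qCols <- .pairColumns(result, "q")
  dCols <- .pairColumns(result, "diff")
  q <- result[[qCols[1L]]]
  d <- result[[dCols[1L]]]
  incomplete <- is.na(q) | is.na(d)
  if (any(incomplete))
    message(sum(incomplete), " protein(s) excluded for undefined statistics")
  keep <- !incomplete & q <= qThreshold & abs(d) >= minAbsLog2
  rownames(result)[which(keep)]
}

#' Candidates with extreme fold changes for summed-intensity review
#'
#' MaxLFQ can fail for proteins that are essentially absent in one
#' condition (no pairwise ratios connect the conditions), so extreme
#' regulation is screened on the summed-intensity matrix: a protein is a
#' candidate when it has zero valid values in some condition and at least
#' `minValidPresent` in another (one-condition dropout), or when some
#' pairwise |log2 difference| of condition means reaches `diffThreshold`.
#' When the peptide table is supplied, each candidate's peptide-level
#' intensity submatrix is attached for inspection -- the automated
#' counterpart of reviewing peptide profiles by eye.
#'
#' @param maxlfq,summed [ProteinQuant-class] matrices over identical
#'   proteins and samples, produced by the two methods.
#' @param minValidPresent valid values required in the detected condition
#'   (default 4).
#' @param diffThreshold |log2 difference| flagging threshold (default 5).
#' @param peptides optional [PeptideQuant-class] used to build the
#'   per-candidate peptide dossier.
#' @return data frame with one row per candidate (`protein_group`,
#'   `reason` = `"dropout"`, `"extreme_fc"` or `"dropout+extreme_fc"`,
#'   per-condition valid counts, and `max_abs_diff_summed`), with the
#'   peptide dossier (a named list of matrices) in attribute `"dossier"`
#'   when `peptides` is given.
#' @export
summingExtremeCandidates <- function(maxlfq, summed, minValidPresent = 4,
                                     diffThreshold = 5, peptides = NULL) {
  stopifnot(is(maxlfq, "ProteinQuant"), is(summed, "ProteinQuant"))
  if (!identical(rownames(maxlfq), rownames(summed)) ||
      !identical(colnames(maxlfq), colnames(summed)))
    stop("matrices must cover identical proteins and samples", call. = FALSE)
  mat <- assay(summed, "log2")
  condition <- as.character(colData(summed)$condition)
  conds <- unique(condition)
  nv <- vapply(conds, function(cc)
    rowSums(!is.na(mat[, condition == cc, drop = FALSE])), numeric(nrow(mat)))
  if (is.null(dim(nv))) nv <- matrix(nv, nrow = 1L)
  colnames(nv) <- conds
  dropout <- rowSums(nv == 0L) > 0L & rowSums(nv >= minValidPresent) > 0L
  means <- vapply(conds, function(cc)
    rowMeans(mat[, condition == cc, drop = FALSE], na.rm = TRUE),
    numeric(nrow(mat)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L)
  pairs <- utils::combn(seq_along(conds), 2L)
  absd <- matrix(NA_real_, nrow(mat), ncol(pairs))
  for (k in seq_len(ncol(pairs)))
    absd[, k] <- abs(means[, pairs[1L, k]] - means[, pairs[2L, k]])
  maxAbs <- apply(absd, 1L, function(z)
    if (all(!is.finite(z))) NA_real_ else max(z[is.finite(z)]))
  extreme <- !is.na(maxAbs) & maxAbs >= diffThreshold
  flagged <- which(dropout | extreme)
  reason <- ifelse(dropout[flagged] & extreme[flagged], "dropout+extreme_fc",
                   ifelse(dropout[flagged], "dropout", "extreme_fc"))
  out <- data.frame(protein_group = rownames(mat)[flagged],
                    reason = reason, stringsAsFactors = FALSE)
  for (cc in conds) out[[paste0("nValid_", cc)]] <- nv[flagged, cc]
  out$max_abs_diff_summed <- maxAbs[flagged]
  rownames(out) <- NULL
  if (!is.null(peptides) && nrow(out)) {
    x <- assay(peptides, "intensity")
    grp <- rowData(peptides)$protein_group
    dossier <- lapply(out$protein_group, function(pg)
      x[grp == pg, , drop = FALSE])
    names(dossier) <- out$protein_group
    attr(out, "dossier") <- dossier
  }
  out
}

#' Left-censored imputation for visualization
#'
#' Replaces each missing cell with a draw from a down-shifted narrow normal
#' distribution fitted per sample: `N(mu_s - downshift * sigma_s,
#' (width * sigma_s)^2)` with `mu_s`, `sigma_s` the mean and SD of the
#' sample's observed values. This mimics values sitting below the detection
#' limit and is intended for volcano/heatmap display only -- testing and
#' filtering always run on the unimputed matrix. Samples with fewer than 3
#' observed values are refused (left untouched, with a warning).
#'
#' @param object a [ProteinQuant-class] object.
#' @param downshift shift of the imputation distribution, in sample SDs
#'   (default 1.8).
#' @param width SD of the imputation distribution, in sample SDs
#'   (default 0.3).
#' @param seed integer seed; the same seed reproduces the imputation.
#' @return a [ProteinQuant-class] with no (or fewer) missing values;
#'   metadata field `imputed` is set to `TRUE`.
#' @export
imputeLeftCensored <- function(object, downshift = 1.8, width = 0.3,
                               seed = 1) {
  stopifnot(is(object, "ProteinQuant"))
  mat <- assay(object, "log2")
  .withSeed(seed, {
    for (s in seq_len(ncol(mat))) {
      miss <- is.na(mat[, s])
      if (!any(miss)) next
      obs <- mat[!miss, s]
      if (length(obs) < 3L) {
        warning("sample '", colnames(mat)[s],
                "' has fewer than 3 observed values; not imputed")
        next
      }
      mu <- mean(obs)
      sigma <- stats::sd(obs)
      mat[miss, s] <- stats::rnorm(sum(miss), mu - downshift * sigma,
                                   width * sigma)
    }
  })
  out <- ProteinQuant(mat, nPeptides = rowData(object)$n_peptides,
                      condition = colData(object)$condition,
                      method = metadata(object)$method)
  metadata(out)$imputed <- TRUE
  out
}

#' Volcano table for one condition pair
#'
#' One record per protein: the log2 difference of condition means (x axis)
#' and `-log10` of the pair's permutation q-value (y axis), plus the
#' experiment's significance flag. The difference is taken from the test
#' results for proteins meeting the valid-value criterion in both
#' conditions of the pair and recomputed on the imputed matrix otherwise,
#' so dropout proteins appear at an extreme but finite position.
#'
#' @param result a [diffTest()] table.
#' @param imputed the matching [imputeLeftCensored()] output.
#' @param pair pair name, e.g. `"OE1_vs_WT"`; defaults to the first pair.
#' @param minValid valid values per condition below which the difference is
#'   recomputed on imputed data (default 4).
#' @return data frame with columns `protein_group`, `log2diff`,
#'   `negLog10Q`, `significant`, `from_imputed`.
#' @export
volcanoTable <- function(result, imputed, pair = NULL, minValid = 4) {
  pairs <- metadata(result)$pairs
  if (is.null(pair)) pair <- pairs[1L]
  if (!pair %in% pairs) stop("unknown pair '", pair, "'", call. = FALSE)
  ab <- strsplit(pair, "_vs_", fixed = TRUE)[[1L]]
  b <- ab[1L]; a <- ab[2L]
  d <- result[[paste0("diff_", pair)]]
  q <- result[[paste0("q_", pair)]]
  nvA <- result[[paste0("nValid_", a)]]
  nvB <- result[[paste0("nValid_", b)]]
  useImputed <- nvA < minValid | nvB < minValid
  if (any(useImputed)) {
    mat <- assay(imputed, "log2")
    mat <- mat[rownames(result), , drop = FALSE]
    condition <- as.character(colData(imputed)$condition)
    dImp <- rowMeans(mat[, condition == b, drop = FALSE], na.rm = TRUE) -
      rowMeans(mat[, condition == a, drop = FALSE], na.rm = TRUE)
    d[useImputed] <- dImp[useImputed]
  }
  y <- -log10(pmax(q, .Machine$double.xmin))
  y[is.na(q)] <- NA_real_
  data.frame(protein_group = rownames(result),
             log2diff = d,
             negLog10Q = y,
             significant = result$significant,
             from_imputed = useImputed,
             stringsAsFactors = FALSE)
}
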