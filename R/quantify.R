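#' Pairwise median log-ratios between samples for one protein
#'
#' First stage of the MaxLFQ rollup: for every ordered sample pair `(s, t)`
#' with at least `minShared` peptides observed in both, the ratio estimate is
#' the median over shared peptides of `x_t - x_s` in log2. The returned
#' matrix is antisymmetric (`r_ts = -r_st`); pairs with fewer than
#' `minShared` shared peptides are `NA`.
#'
#' @param x numeric matrix of log2 peptide intensities (peptides x samples),
#'   `NA` = missing.
#' @param minShared minimum number of shared peptides per pair.
#' @return samples x samples matrix of median log2 ratios (`NA` diagonal).
#' @examples
#' x <- rbind(c(10, 12), c(11, 13))
#' pairwiseMedianLogRatios(x)[1, 2]  # 2
#' @export
pairwiseMedianLogRatios <- function(x, minShared = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one peptide", call. = FALSE)
  minShared <- max(1L, .assertCount(minShared, "minShared", 0))
  n <- ncol(x)
  R <- matrix(NA_real_, n, n, dimnames = list(colnames(x), colnames(x)))
  obs <- !is.na(x)
  if (n >= 2L) {
    for (s in 1:(n - 1L)) {
      for (t in (s + 1L):n) {
        sh <- obs[, s] & obs[, t]
        if (sum(sh) >= minShared) {
          r <- stats::median(x[sh, t] - x[sh, s])
          R[s, t] <- r
          R[t, s] <- -r
        }
      }
    }
  }
  R
}

#' MaxLFQ-style protein profile from one peptide submatrix
#'
#' Estimates a per-sample log2 abundance profile by least squares on the
#' pairwise median log-ratios: samples are nodes, valid pairs are edges, and
#' within each connected component the profile `p` minimizes
#' `sum over edges (p_t - p_s - r_st)^2`, anchored so that the component's
#' mean estimate equals the mean of all observed log2 peptide intensities in
#' those samples (which preserves the overall intensity level and makes the
#' estimate shift-equivariant). Only the largest component is reported
#' (ties broken toward the component containing the lexicographically
#' smallest sample name); samples outside it, or without data, are `NA`.
#'
#' @inheritParams pairwiseMedianLogRatios
#' @return named numeric vector of per-sample log2 abundances (`NA` allowed).
#' @examples
#' x <- rbind(c(10, 12, 11), c(13, 15, 14))
#' maxLFQProfile(x)  # c(11.5, 13.5, 12.5)
#' @export
maxLFQProfile <- function(x, minShared = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one peptide", call. = FALSE)
  n <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("S%03d", seq_len(n))
  p <- setNames(rep(NA_real_, n), colnames(x))
  hasData <- colSums(!is.na(x)) > 0L
  if (!any(hasData)) return(p)

  R <- pairwiseMedianLogRatios(x, minShared = minShared)
  valid <- which(!is.na(R) & upper.tri(R), arr.ind = TRUE)
  comp <- .connectedComponents(n, valid)
  comp[!hasData] <- NA_integer_

  sizes <- table(comp)
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(best) > 1L) {
    # tie: the component holding the lexicographically smallest sample name
    anchorName <- min(colnames(x)[comp %in% best & hasData])
    best <- comp[match(anchorName, colnames(x))]
  }
  members <- which(!is.na(comp) & comp == best)
  anchor <- mean(x[, members], na.rm = TRUE)
  m <- length(members)
  if (m == 1L) {
    p[members] <- mean(x[, members], na.rm = TRUE)
    return(p)
  }
  idx <- match(seq_len(n), members)   # sample -> position in component
  L <- matrix(0, m, m)
  b <- numeric(m)
  for (e in seq_len(nrow(valid))) {
    s <- valid[e, 1L]; t <- valid[e, 2L]
    i <- idx[s]; j <- idx[t]
    if (is.na(i) || is.na(j)) next
    r <- R[s, t]                       # target: p_t - p_s = r
    L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
    b[j] <- b[j] + r
    b[i] <- b[i] - r
  }
  # Laplacian is singular (profile level unidentifiable); adding the rank-one
  # term J/m pins the component mean to the anchor without perturbing the
  # ratio fit, because b is orthogonal to the ones vector.
  sol <- solve(L + matrix(1 / m, m, m), b + anchor)
  p[members] <- sol
  p
}

#' Summed-intensity protein profile
#'
#' The simple alternative rollup used for proteins with extreme fold
#' changes that MaxLFQ may not quantify properly: per sample, the log2 of
#' the sum of observed linear peptide intensities. A sample in which no
#' peptide is observed is `NA`.
#'
#' @inheritParams pairwiseMedianLogRatios
#' @return named numeric vector of per-sample log2 abundances.
#' @examples
#' sumQuantify(matrix(log2(c(100, 300)), 2, 1))  # log2(400)
#' @export
sumQuantify <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one peptide", call. = FALSE)
  tot <- colSums(2^x, na.rm = TRUE)
  tot[colSums(!is.na(x)) == 0L] <- NA_real_
  setNames(log2(tot), colnames(x))
}

#' @describeIn quantifyProteins roll up every protein group of a
#'   [PeptideQuant-class] table with the chosen method. Protein groups are
#'   emitted in sorted order, so the result is invariant to peptide row
#'   order.
#' @export
setMethod("quantifyProteins", "PeptideQuant",
          function(object, method = c("maxlfq", "summed"), minShared = 1L,
                   medianCenter = FALSE) {
  method <- match.arg(method)
  x <- log2(assay(object, "intensity"))
  groups <- rowData(object)$protein_group
  proteins <- sort(unique(groups))
  idx <- split(seq_len(nrow(x)), groups)
  out <- matrix(NA_real_, length(proteins), ncol(x),
                dimnames = list(proteins, colnames(x)))
  fun <- if (method == "maxlfq") {
    function(sub) maxLFQProfile(sub, minShared = minShared)
  } else {
    sumQuantify
  }
  for (i in seq_along(proteins)) {
    out[i, ] <- fun(x[idx[[proteins[i]]], , drop = FALSE])
  }
  if (isTRUE(medianCenter)) {
    med <- apply(out, 2, stats::median, na.rm = TRUE)
    out <- sweep(out, 2, med - stats::median(med))
  }
  ProteinQuant(out,
               nPeptides = lengths(idx)[proteins],
               condition = colData(object)$condition,
               method = method)
})
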