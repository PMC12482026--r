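#' Permutation-based FDR (pooled null) for row-wise test statistics
#'
#' Estimates per-protein q-values in the SAM style: condition labels are
#' shuffled across all samples (whole columns, preserving each protein's
#' peptide structure), the statistic is recomputed for every protein, and
#' all null statistics are pooled. For a threshold `c`,
#' `FDR(c) = ((1/B) * #\{null >= c\}) / max(1, #\{observed >= c\})`, and the
#' q-value of protein `i` is the minimum of `FDR(c)` over thresholds
#' `c <= stat_i` (the smallest estimated FDR of any rejection region that
#' contains protein `i`), capped at 1. This is non-increasing in the
#' statistic by construction.
#'
#' All distinct label assignments are enumerated exhaustively when their
#' number is at most `nPerm` (e.g. `choose(10, 5) = 252` for a 5 vs 5
#' two-group design); otherwise `nPerm` random shuffles are drawn. The
#' identity labeling is included among enumerated assignments, which floors
#' the smallest attainable q at `1/B` and keeps the estimate conservative.
#'
#' @param mat numeric matrix (proteins x samples) of log2 abundances.
#' @param condition per-column condition labels (2 levels for
#'   `statistic = "welch"`, 2+ for `"anova"`).
#' @param statistic `"welch"` (|t|) or `"anova"` (F).
#' @param nPerm permutation budget (default 1000). Fewer than 10 available
#'   permutations triggers a warning.
#' @param seed integer seed used when shuffles are sampled.
#' @return numeric vector of q-values, `NA` for proteins whose statistic is
#'   undefined (fewer than two valid values in some group).
#' @seealso [diffTest()]
#' @export
permutationFDR <- function(mat, condition, statistic = c("welch", "anova"),
                           nPerm = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  mat <- as.matrix(mat)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(mat))
  lev <- unique(condition)
  if (statistic == "welch" && length(lev) != 2L)
    stop("'welch' needs exactly two conditions", call. = FALSE)
  if (length(lev) < 2L)
    stop("need at least two conditions", call. = FALSE)

  statFun <- function(labels) {
    if (statistic == "welch") {
      .rowWelchAbsT(mat, which(labels == lev[1L]), which(labels == lev[2L]))
    } else {
      .rowAnovaF(mat, lapply(lev, function(l) which(labels == l)))
    }
  }
  obs <- statFun(condition)

  total <- .nDistinctPerms(condition)
  if (total <= nPerm + 0.5) {
    perms <- .multisetPerms(condition)
  } else {
    perms <- .withSeed(seed, {
      matrix(unlist(lapply(seq_len(nPerm), function(i) sample(condition))),
             nrow = length(condition))
    })
  }
  B <- ncol(perms)
  if (B < 10L)
    warning("only ", B, " distinct permutations available; ",
            "FDR estimate will be coarse")
  nullStats <- unlist(lapply(seq_len(B), function(b) statFun(perms[, b])),
                      use.names = FALSE)
  .qFromPooledNull(obs, nullStats, B)
}

# q-values from an observed statistic vector and a pooled null sample.
# Thresholds are the observed values themselves; q_i = min FDR over
# thresholds <= stat_i, capped at 1.
.qFromPooledNull <- function(obs, nullStats, B) {
  q <- rep(NA_real_, length(obs))
  ok <- which(!is.na(obs))
  if (!length(ok)) return(q)
  nullStats <- nullStats[!is.na(nullStats)]
  nullSorted <- sort(nullStats)
  obsOk <- obs[ok]
  ord <- order(obsOk)
  thr <- obsOk[ord]
  nObs <- length(thr)
  # counts >= threshold via binary search on the sorted vectors
  nullGE <- length(nullSorted) -
    findInterval(thr, nullSorted, left.open = TRUE)
  obsGE <- nObs - (seq_len(nObs) - 1L)
  # ties among observed values: every tied copy counts in #{obs >= c}
  if (anyDuplicated(thr)) {
    first <- match(thr, thr)
    obsGE <- obsGE[first]
  }
  fdr <- pmin(1, (nullGE / B) / pmax(1, obsGE))
  # running minimum over ascending thresholds = min FDR over c <= stat_i
  q[ok[ord]] <- cummin(fdr)
  q
}
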