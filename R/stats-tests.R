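#' Two-sample Welch t test statistic
#'
#' Welch statistic with Welch--Satterthwaite degrees of freedom and
#' two-sided parametric p-value. Missing values are dropped; fewer than two
#' valid values in either group leaves the statistic undefined (all `NA`),
#' which downstream code flags and excludes from testing.
#'
#' @param x,y numeric vectors (log2 abundances of the two groups).
#' @return named vector `c(t, df, p)`; `t` is oriented as
#'   `mean(x) - mean(y)`.
#' @examples
#' welchT(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4, p = 0.2879
#' @export
welchT <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    return(c(t = NA_real_, df = NA_real_, p = NA_real_))
  vx <- stats::var(x) / nx
  vy <- stats::var(y) / ny
  se2 <- vx + vy
  if (se2 == 0) {
    # identical constants in both groups: no evidence either way
    tt <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
    df <- nx + ny - 2
    return(c(t = tt, df = df, p = if (is.finite(tt)) 1 else .Machine$double.xmin))
  }
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  c(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' One-way fixed-effects ANOVA
#'
#' Standard one-way F statistic over `k >= 2` groups with parametric
#' p-value. Groups with fewer than two valid values leave the statistic
#' undefined. A zero within-group mean square with non-zero between-group
#' variation yields `F = Inf` with the p-value clamped to the smallest
#' representable positive double.
#'
#' @param groups list of numeric vectors (one per group); `NA`s dropped.
#' @return named vector `c(F, df1, df2, p)`.
#' @examples
#' oneWayANOVA(list(1:3, 2:4, 3:5))  # F = 3, p = 0.125
#' @export
oneWayANOVA <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  ns <- lengths(groups)
  if (any(ns < 2L))
    return(c(F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_))
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0)
      return(c(F = 0, df1 = df1, df2 = df2, p = 1))
    return(c(F = Inf, df1 = df1, df2 = df2, p = .Machine$double.xmin))
  }
  Fstat <- (ssb / df1) / (ssw / df2)
  c(F = Fstat, df1 = df1, df2 = df2,
    p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

# ---- vectorized row-wise statistics (used by the permutation machinery) ----

# per-group row summaries on a (proteins x samples) matrix; rows are centered
# on their grand mean first, which costs nothing statistically (both
# statistics are location invariant) and improves conditioning
.rowGroupStats <- function(mat, idx) {
  x <- mat[, idx, drop = FALSE]
  n <- rowSums(!is.na(x))
  s <- rowSums(x, na.rm = TRUE)
  m <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(x * x, na.rm = TRUE)
  v <- ifelse(n > 1, pmax(0, ss - n * m^2) / (n - 1), NA_real_)
  list(n = n, m = m, v = v)
}

# |Welch t| per row for two column index sets; NA where a group has < 2 valid
.rowWelchAbsT <- function(mat, idx1, idx2) {
  mat <- mat - rowMeans(mat, na.rm = TRUE)
  g1 <- .rowGroupStats(mat, idx1)
  g2 <- .rowGroupStats(mat, idx2)
  ok <- g1$n >= 2L & g2$n >= 2L
  se2 <- g1$v / g1$n + g2$v / g2$n
  tt <- abs(g1$m - g2$m) / sqrt(se2)
  tt[ok & se2 == 0 & g1$m == g2$m] <- 0
  tt[!ok] <- NA_real_
  tt
}

# signed Welch t, df and parametric p per row (orientation m1 - m2)
.rowWelchFull <- function(mat, idx1, idx2) {
  cmat <- mat - rowMeans(mat, na.rm = TRUE)
  g1 <- .rowGroupStats(cmat, idx1)
  g2 <- .rowGroupStats(cmat, idx2)
  ok <- g1$n >= 2L & g2$n >= 2L
  v1 <- g1$v / g1$n
  v2 <- g2$v / g2$n
  se2 <- v1 + v2
  tt <- (g1$m - g2$m) / sqrt(se2)
  df <- se2^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- ok & se2 == 0
  if (any(zero, na.rm = TRUE)) {
    eq <- zero & (g1$m == g2$m)
    tt[eq] <- 0; df[eq] <- g1$n[eq] + g2$n[eq] - 2; p[eq] <- 1
    ne <- zero & (g1$m != g2$m)
    tt[ne] <- Inf * sign(g1$m[ne] - g2$m[ne])
    df[ne] <- g1$n[ne] + g2$n[ne] - 2
    p[ne] <- .Machine$double.xmin
  }
  tt[!ok] <- NA_real_; df[!ok] <- NA_real_; p[!ok] <- NA_real_
  list(t = tt, df = df, p = p)
}

# one-way F (and parametric p if wanted) per row; groupsIdx: list of column
# index vectors. NA where any group has < 2 valid values.
.rowAnovaF <- function(mat, groupsIdx, pvalues = FALSE) {
  mat <- mat - rowMeans(mat, na.rm = TRUE)
  k <- length(groupsIdx)
  stats <- lapply(groupsIdx, function(ix) .rowGroupStats(mat, ix))
  ns <- vapply(stats, `[[`, numeric(nrow(mat)), "n")
  if (is.null(dim(ns))) ns <- matrix(ns, nrow = 1L)
  ok <- rowSums(ns >= 2L) == k
  N <- rowSums(ns)
  ms <- vapply(stats, `[[`, numeric(nrow(mat)), "m")
  if (is.null(dim(ms))) ms <- matrix(ms, nrow = 1L)
  grand <- rowSums(ns * ms) / N
  ssb <- rowSums(ns * (ms - grand)^2)
  vs <- vapply(stats, `[[`, numeric(nrow(mat)), "v")
  if (is.null(dim(vs))) vs <- matrix(vs, nrow = 1L)
  ssw <- rowSums((ns - 1) * vs)
  df1 <- k - 1
  df2 <- N - k
  Fstat <- (ssb / df1) / (ssw / df2)
  Fstat[ok & ssw == 0 & ssb > 0] <- Inf
  Fstat[ok & ssw == 0 & ssb == 0] <- 0
  Fstat[!ok] <- NA_real_
  if (!pvalues) return(Fstat)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  p[is.finite(Fstat) & Fstat == 0] <- 1
  p[is.infinite(Fstat)] <- .Machine$double.xmin
  p[!ok] <- NA_real_
  list(F = Fstat, df1 = rep(df1, nrow(mat)), df2 = df2, p = p)
}
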