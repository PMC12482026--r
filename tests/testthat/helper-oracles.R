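# Independent oracles used to cross-check the implementation. These are
# written from the definitions (dense normal equations, explicit
# combinatorics) and deliberately share no code with the package internals.

# Brute-force MaxLFQ reference: pairwise medians by explicit sorting, BFS
# connected components, dense KKT solve of the anchored least-squares
# problem  min ||A p - r||^2  s.t.  mean(p over component) = anchor.
oracleMaxLFQ <- function(x, minShared = 1) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("S%03d", seq_len(n))
  med <- function(v) {
    v <- sort(v)
    k <- length(v)
    if (k %% 2L) v[(k + 1L) / 2L] else (v[k / 2L] + v[k / 2L + 1L]) / 2
  }
  edges <- NULL
  ratios <- numeric(0)
  if (n >= 2L) {
    for (s in 1:(n - 1L)) {
      for (t in (s + 1L):n) {
        sh <- which(!is.na(x[, s]) & !is.na(x[, t]))
        if (length(sh) >= minShared) {
          edges <- rbind(edges, c(s, t))
          ratios <- c(ratios, med(x[sh, t] - x[sh, s]))
        }
      }
    }
  }
  hasData <- colSums(!is.na(x)) > 0L
  prof <- setNames(rep(NA_real_, n), colnames(x))
  if (!any(hasData)) return(prof)
  # BFS components over samples with data
  adj <- matrix(FALSE, n, n)
  if (!is.null(edges)) {
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  compId <- rep(NA_integer_, n)
  cid <- 0L
  for (start in which(hasData)) {
    if (!is.na(compId[start])) next
    cid <- cid + 1L
    queue <- start
    compId[start] <- cid
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & hasData & is.na(compId))
      compId[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  sizes <- table(compId)
  biggest <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(biggest) > 1L) {
    nmin <- min(colnames(x)[compId %in% biggest])
    biggest <- compId[match(nmin, colnames(x))]
  }
  memb <- which(!is.na(compId) & compId == biggest)
  anchor <- mean(x[, memb], na.rm = TRUE)
  m <- length(memb)
  if (m == 1L) {
    prof[memb] <- mean(x[, memb], na.rm = TRUE)
    return(prof)
  }
  inComp <- !is.null(edges) &
    edges[, 1L] %in% memb & edges[, 2L] %in% memb
  A <- matrix(0, sum(inComp), m)
  r <- ratios[inComp]
  ce <- edges[inComp, , drop = FALSE]
  for (i in seq_len(nrow(ce))) {
    A[i, match(ce[i, 1L], memb)] <- -1
    A[i, match(ce[i, 2L], memb)] <- 1
  }
  # KKT system for the equality-constrained least squares
  kkt <- rbind(cbind(2 * crossprod(A), rep(1, m)),
               c(rep(1, m), 0))
  rhs <- c(2 * crossprod(A, r), m * anchor)
  sol <- solve(kkt, rhs)
  prof[memb] <- sol[seq_len(m)]
  prof
}

# one-sided hypergeometric upper tail from explicit binomial coefficients
oracleHyperP <- function(k, K, N, n) {
  js <- seq(k, min(n, K))
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# random peptide submatrix with missingness; returns NULL unless the
# sample-pair graph is connected over all samples (checked independently
# of the package, via the oracle's BFS)
randomConnectedFixture <- function(nPep, nSamp, missRate) {
  x <- matrix(rnorm(nPep * nSamp, 20, 2), nPep, nSamp,
              dimnames = list(NULL, sprintf("S%02d", seq_len(nSamp))))
  x[matrix(runif(nPep * nSamp) < missRate, nPep, nSamp)] <- NA
  if (any(colSums(!is.na(x)) == 0L)) return(NULL)
  # connectivity via shared-peptide graph
  conn <- diag(nSamp) > 0
  for (s in seq_len(nSamp - 1L)) {
    for (t in (s + 1L):nSamp) {
      if (any(!is.na(x[, s]) & !is.na(x[, t]))) conn[s, t] <- conn[t, s] <- TRUE
    }
  }
  reach <- conn
  for (k in seq_len(nSamp)) reach <- reach | (reach %*% reach > 0)
  if (!all(reach)) return(NULL)
  x
}

# small complete peptide table for quantify_all checks
toyPeptideTable <- function() {
  x <- 2^rbind(c(10, 12, 11, 10.5),
               c(13, 15, 14, 13.5),
               c(20, 20, 20, 20),
               c(18, 19, 17, 18))
  rownames(x) <- c("A_p1", "A_p2", "B_p1", "C_p1")
  colnames(x) <- c("WT_r1", "WT_r2", "KO_r1", "KO_r2")
  PeptideQuant(x, proteinGroup = c("A", "A", "B", "C"),
               condition = c("WT", "WT", "KO", "KO"))
}
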