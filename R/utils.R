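# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic entry points route
# their randomness through this, so no function leaks global RNG state.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

.assertCount <- function(x, name, min = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %s", name, min), call. = FALSE)
  }
  as.integer(x)
}

.assertNumber <- function(x, name, min = -Inf, strict = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (if (strict) x <= min else x < min) {
    stop(sprintf("'%s' must be %s %s", name, if (strict) ">" else ">=", min),
         call. = FALSE)
  }
  as.numeric(x)
}

# Row-wise z-score with population (n-denominator) standard deviation.
# Zero-variance rows map to all zeros; NA cells stay NA.
.zscoreRows <- function(m) {
  mu <- rowMeans(m, na.rm = TRUE)
  centered <- m - mu
  sdp <- sqrt(rowMeans(centered^2, na.rm = TRUE))
  div <- ifelse(is.finite(sdp) & sdp > 0, sdp, 1)
  centered / div
}

# connected components of an undirected graph over nodes 1..n given an
# edge list (two-column integer matrix); returns integer membership vector
.connectedComponents <- function(n, edges) {
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# All distinct orderings (multiset permutations) of a label vector, as a
# matrix with one permutation per column. Callers guard on the count.
.multisetPerms <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  ux <- unique(x)
  blocks <- lapply(ux, function(u) {
    i <- match(u, x)
    rest <- .multisetPerms(x[-i])
    rbind(matrix(u, 1L, ncol(rest)), rest)
  })
  do.call(cbind, blocks)
}

# Number of distinct orderings of a label vector.
.nDistinctPerms <- function(x) {
  tab <- table(x)
  exp(lfactorial(length(x)) - sum(lfactorial(tab)))
}
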