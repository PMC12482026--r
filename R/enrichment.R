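#' Fisher-exact term enrichment against the detected background
#'
#' For every annotated term with at least one detected member, tests
#' over-representation of the significant set among the term's detected
#' proteins versus all detected proteins as background. With `k`
#' significant proteins in the term, `n` detected proteins in the term,
#' `K` significant overall and `N` detected overall, the one-sided p-value
#' is the hypergeometric upper tail `P(X >= k)`; `alternative =
#' "two.sided"` switches to the standard two-sided Fisher exact test.
#' Benjamini-Hochberg correction is applied within each namespace by
#' default (mirroring per-ontology result panels), or across all terms
#' with `byNamespace = FALSE`.
#'
#' @param significant character vector of significant protein ids (must be
#'   a subset of `detected`).
#' @param detected character vector of all detected (background) protein
#'   ids.
#' @param annotations data frame `protein_id`, `term_id`.
#' @param graph optional [OntologyGraph-class]; required for propagation,
#'   namespaces and term names.
#' @param propagate propagate annotations to ancestors first (default
#'   `TRUE`, needs `graph`).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @param byNamespace apply BH within each namespace separately (default
#'   `TRUE` when namespaces are available).
#' @return data frame ordered by p-value with columns `term`, `name`,
#'   `namespace`, `k`, `n`, `K`, `N`, `pct` (percentage of significantly
#'   regulated proteins among the term's detected proteins), `p`, `q`, and
#'   `low_support` (`TRUE` for terms with fewer than 2 detected members).
#' @examples
#' ann <- data.frame(protein_id = c("a", "b", "c"),
#'                   term_id = "T1")
#' fisherEnrichment(c("a", "b"), letters[1:10], ann)
#' @export
fisherEnrichment <- function(significant, detected, annotations,
                             graph = NULL, propagate = TRUE,
                             alternative = c("greater", "two.sided"),
                             byNamespace = TRUE) {
  alternative <- match.arg(alternative)
  significant <- unique(as.character(significant))
  detected <- unique(as.character(detected))
  if (!all(significant %in% detected))
    stop("'significant' must be a subset of 'detected'", call. = FALSE)
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (propagate && !is.null(graph))
    annotations <- propagateAnnotations(annotations, graph)
  annotations <- annotations[annotations$protein_id %in% detected, ,
                             drop = FALSE]
  annotations <- unique(annotations[, c("protein_id", "term_id")])
  N <- length(detected)
  K <- length(significant)
  members <- split(annotations$protein_id, annotations$term_id)
  n <- lengths(members)
  k <- vapply(members, function(m) sum(m %in% significant), integer(1))
  terms <- names(members)
  p <- if (alternative == "greater") {
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  } else {
    vapply(seq_along(terms), function(i) {
      tab <- matrix(c(k[i], K - k[i], n[i] - k[i], N - K - n[i] + k[i]), 2L)
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    }, numeric(1))
  }
  if (!is.null(graph)) {
    info <- termInfo(graph)
    nm <- info$name[match(terms, info$id)]
    ns <- info$namespace[match(terms, info$id)]
  } else {
    nm <- terms
    ns <- rep(NA_character_, length(terms))
  }
  q <- rep(NA_real_, length(p))
  if (byNamespace && !all(is.na(ns))) {
    for (nsp in unique(ns)) {
      sel <- if (is.na(nsp)) is.na(ns) else !is.na(ns) & ns == nsp
      q[sel] <- stats::p.adjust(p[sel], method = "BH")
    }
  } else {
    q <- stats::p.adjust(p, method = "BH")
  }
  out <- data.frame(term = terms, name = nm, namespace = ns,
                    k = as.integer(k), n = as.integer(n),
                    K = K, N = N, pct = 100 * k / n,
                    p = p, q = q, low_support = n < 2L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
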