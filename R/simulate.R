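#' Parameters of the peptide-level data simulator
#'
#' Bundles and validates the generative-model parameters used by
#' [simulateDataset()]. Defaults describe a typical leaf-tissue DIA
#' experiment: 5 biological replicates per condition, thousands of protein
#' groups with on average ~5 peptides each, log2 intensities around 20,
#' small replicate noise, and a minority of truly regulated proteins.
#'
#' @param nConditions number of conditions (2 or 3); condition 1 is the
#'   reference (wild type).
#' @param nReplicates replicates per condition (default 5).
#' @param nProteins number of protein groups.
#' @param peptideMean mean of the Poisson part of the peptides-per-protein
#'   distribution; counts are `1 + Poisson(peptideMean)` truncated at
#'   `peptideMax`.
#' @param peptideMax upper truncation for peptides per protein.
#' @param baseAbundanceMean,baseAbundanceSd mean/sd of protein base
#'   abundance `b_i` (log2-intensity units).
#' @param peptideOffsetSd sd of the per-peptide ionization offset `o_j`
#'   (log2 units).
#' @param replicateNoiseSd sd of the per-cell measurement noise (log2 units).
#' @param fracRegulated proportion of proteins carrying a true condition
#'   effect, in \[0, 1\].
#' @param effectSizes positive log2 fold changes assignable to regulated
#'   proteins; each regulated protein draws one magnitude and a random sign.
#' @param censorMidpoint,censorScale logistic censoring parameters (log2
#'   units): a cell at log2 intensity `x` is missing with probability
#'   `1 / (1 + exp((x - censorMidpoint) / censorScale))`, so low-intensity
#'   cells drop out preferentially (left-censored, MNAR). `censorScale` must
#'   be positive; `censorMidpoint = -Inf` disables missingness.
#' @param conditionLabels condition names; defaults to `WT`/`KO` for two
#'   conditions and `WT`/`OE1`/`OE2` for three.
#'
#' @return A validated list of class `SimulationParams`.
#' @seealso [simulateDataset()]
#' @export
simulationParams <- function(nConditions = 3,
                             nReplicates = 5,
                             nProteins = 2000,
                             peptideMean = 4,
                             peptideMax = 20,
                             baseAbundanceMean = 20,
                             baseAbundanceSd = 2,
                             peptideOffsetSd = 1,
                             replicateNoiseSd = 0.25,
                             fracRegulated = 0.05,
                             effectSizes = c(1.5, 2, 3),
                             censorMidpoint = 16,
                             censorScale = 0.8,
                             conditionLabels = NULL) {
  nConditions <- .assertCount(nConditions, "nConditions", 2)
  if (nConditions > 3)
    stop("'nConditions' must be 2 or 3", call. = FALSE)
  nReplicates <- .assertCount(nReplicates, "nReplicates", 2)
  nProteins <- .assertCount(nProteins, "nProteins", 1)
  peptideMean <- .assertNumber(peptideMean, "peptideMean", 0)
  peptideMax <- .assertCount(peptideMax, "peptideMax", 1)
  baseAbundanceSd <- .assertNumber(baseAbundanceSd, "baseAbundanceSd", 0)
  peptideOffsetSd <- .assertNumber(peptideOffsetSd, "peptideOffsetSd", 0)
  replicateNoiseSd <- .assertNumber(replicateNoiseSd, "replicateNoiseSd", 0)
  fracRegulated <- .assertNumber(fracRegulated, "fracRegulated", 0)
  if (fracRegulated > 1)
    stop("'fracRegulated' must be in [0, 1]", call. = FALSE)
  censorScale <- .assertNumber(censorScale, "censorScale", 0, strict = TRUE)
  if (!is.numeric(effectSizes) || !length(effectSizes) ||
      any(is.na(effectSizes)))
    stop("'effectSizes' must be a non-empty numeric vector", call. = FALSE)
  if (is.null(conditionLabels)) {
    conditionLabels <- if (nConditions == 2) c("WT", "KO")
                       else c("WT", "OE1", "OE2")
  }
  if (length(conditionLabels) != nConditions ||
      anyDuplicated(conditionLabels))
    stop("'conditionLabels' must be ", nConditions, " distinct labels",
         call. = FALSE)
  structure(list(
    nConditions = nConditions, nReplicates = nReplicates,
    nProteins = nProteins, peptideMean = peptideMean,
    peptideMax = peptideMax, baseAbundanceMean = baseAbundanceMean,
    baseAbundanceSd = baseAbundanceSd, peptideOffsetSd = peptideOffsetSd,
    replicateNoiseSd = replicateNoiseSd, fracRegulated = fracRegulated,
    effectSizes = as.numeric(effectSizes), censorMidpoint = censorMidpoint,
    censorScale = censorScale,
    conditionLabels = as.character(conditionLabels)
  ), class = "SimulationParams")
}

#' @export
print.SimulationParams <- function(x, ...) {
  cat("SimulationParams:\n")
  cat(sprintf("  %d conditions (%s) x %d replicates, %d proteins\n",
              x$nConditions, paste(x$conditionLabels, collapse = "/"),
              x$nReplicates, x$nProteins))
  cat(sprintf("  base log2 abundance ~ N(%g, %g), peptide offset sd %g, noise sd %g\n",
              x$baseAbundanceMean, x$baseAbundanceSd, x$peptideOffsetSd,
              x$replicateNoiseSd))
  cat(sprintf("  regulated fraction %g, |log2FC| in {%s}\n", x$fracRegulated,
              paste(x$effectSizes, collapse = ", ")))
  cat(sprintf("  logistic censoring: midpoint %g, scale %g\n",
              x$censorMidpoint, x$censorScale))
  invisible(x)
}

#' Simulate a peptide-level DIA dataset with known ground truth
#'
#' Generates a [PeptideQuant-class] table under the generative model the
#' downstream analysis assumes. For protein `i`, peptide `j`, sample `s` in
#' condition `c`, the log2 intensity is
#' `x = b_i + o_j + delta_ic + eps` with `b_i ~ N(baseAbundanceMean,
#' baseAbundanceSd)`, `o_j ~ N(0, peptideOffsetSd)`,
#' `eps ~ N(0, replicateNoiseSd)` and `delta_ic` the true log2 fold change
#' of condition `c` versus condition 1 (zero for unregulated proteins; a
#' regulated protein carries one drawn effect in one randomly chosen
#' non-reference condition). Each cell is then censored (set missing) with
#' logistic probability decreasing in `x`, and intensities are emitted on
#' the linear scale `2^x`.
#'
#' @param params a [simulationParams()] object.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A list with elements
#'   \describe{
#'     \item{peptides}{[PeptideQuant-class] with conditions in `colData`.}
#'     \item{truth}{list of class `SyntheticTruth`: `proteins` (data frame
#'       with `protein_group`, `regulated` and one `lfc_<condition>` column
#'       per condition), `peptides` (data frame with `precursor_id`,
#'       `protein_group`, `ionization_offset`), and `censored` (logical
#'       matrix aligned with the intensity assay).}
#'   }
#' @examples
#' sim <- simulateDataset(simulationParams(nProteins = 50), seed = 1)
#' sim$peptides
#' colSums(sim$truth$proteins[, -(1:2)] != 0)  # regulated per condition
#' @export
simulateDataset <- function(params = simulationParams(), seed = 1) {
  stopifnot(inherits(params, "SimulationParams"))
  .withSeed(seed, {
    p <- params
    conds <- p$conditionLabels
    sampleCondition <- rep(conds, each = p$nReplicates)
    sampleIds <- paste0(sampleCondition, "_r",
                        rep(seq_len(p$nReplicates), times = p$nConditions))
    nSamples <- length(sampleIds)

    proteinIds <- sprintf("PROT%05d", seq_len(p$nProteins))
    regulated <- runif(p$nProteins) < p$fracRegulated
    lfc <- matrix(0, p$nProteins, p$nConditions,
                  dimnames = list(proteinIds, conds))
    nReg <- sum(regulated)
    if (nReg > 0 && p$nConditions >= 2) {
      # sample.int indexing avoids base::sample's scalar-expansion trap
      target <- 1L + sample.int(p$nConditions - 1L, nReg, replace = TRUE)
      effect <- p$effectSizes[sample.int(length(p$effectSizes), nReg,
                                         replace = TRUE)] *
        sample(c(-1, 1), nReg, replace = TRUE)
      lfc[cbind(which(regulated), target)] <- effect
    }

    nPep <- pmin(1L + rpois(p$nProteins, p$peptideMean), p$peptideMax)
    proteinOfPep <- rep(seq_len(p$nProteins), times = nPep)
    nPepTotal <- length(proteinOfPep)
    pepWithin <- sequence(nPep)
    precursorIds <- sprintf("%s_pep%02d", proteinIds[proteinOfPep], pepWithin)

    b <- rnorm(p$nProteins, p$baseAbundanceMean, p$baseAbundanceSd)
    o <- rnorm(nPepTotal, 0, p$peptideOffsetSd)

    delta <- lfc[proteinOfPep, match(sampleCondition, conds), drop = FALSE]
    x <- b[proteinOfPep] + o + delta +
      matrix(rnorm(nPepTotal * nSamples, 0, p$replicateNoiseSd),
             nPepTotal, nSamples)
    pMiss <- 1 / (1 + exp((x - p$censorMidpoint) / p$censorScale))
    censored <- matrix(runif(nPepTotal * nSamples), nPepTotal, nSamples) < pMiss
    intensity <- 2^x
    intensity[censored] <- NA_real_
    dimnames(intensity) <- list(precursorIds, sampleIds)
    dimnames(censored) <- dimnames(intensity)

    peptides <- PeptideQuant(intensity,
                             proteinGroup = proteinIds[proteinOfPep],
                             condition = sampleCondition,
                             precursorId = precursorIds)
    truthProteins <- data.frame(protein_group = proteinIds,
                                regulated = regulated,
                                stringsAsFactors = FALSE)
    for (k in seq_len(p$nConditions))
      truthProteins[[paste0("lfc_", conds[k])]] <- lfc[, k]
    truth <- structure(list(
      proteins = truthProteins,
      peptides = data.frame(precursor_id = precursorIds,
                            protein_group = proteinIds[proteinOfPep],
                            ionization_offset = o,
                            stringsAsFactors = FALSE),
      censored = censored
    ), class = "SyntheticTruth")
    list(peptides = peptides, truth = truth)
  })
}

#' Simulate a toy ontology with planted enriched terms
#'
#' Builds a rooted acyclic `is_a` DAG (term `k > 1` attaches to one or two
#' earlier terms, so acyclicity holds by construction), random direct
#' annotations, and a set of "planted" terms whose members are drawn
#' preferentially from a caller-supplied significant set, so that downstream
#' enrichment analysis has a known positive control.
#'
#' @param nTerms number of terms (term 1 is the root).
#' @param proteins character vector of protein identifiers to annotate.
#' @param plantedTerms how many terms to plant (must be `<= nTerms - 1`;
#'   the root is never planted).
#' @param significantSet protein ids that planted terms should over-sample;
#'   required when `plantedTerms > 0`.
#' @param plantedFraction fraction of each planted term's members drawn from
#'   `significantSet` (default 0.8).
#' @param termSize direct members per planted term.
#' @param annotationsPerProtein average number of random direct annotations
#'   per protein for the background.
#' @param namespace ontology namespace of all terms.
#' @param seed integer seed.
#' @return A list with elements `graph` ([OntologyGraph-class]),
#'   `annotations` (data frame `protein_id`, `term_id`; direct annotations)
#'   and `planted` (character vector of planted term ids).
#' @export
simulateOntology <- function(nTerms, proteins, plantedTerms = 0,
                             significantSet = character(),
                             plantedFraction = 0.8, termSize = 20,
                             annotationsPerProtein = 3,
                             namespace = "biological_process", seed = 1) {
  nTerms <- .assertCount(nTerms, "nTerms", 1)
  plantedTerms <- .assertCount(plantedTerms, "plantedTerms", 0)
  if (plantedTerms > max(0L, nTerms - 1L))
    stop("'plantedTerms' must be <= nTerms - 1", call. = FALSE)
  proteins <- as.character(proteins)
  if (plantedTerms > 0 && !length(significantSet))
    stop("planted terms need a non-empty 'significantSet'", call. = FALSE)
  .withSeed(seed, {
    ids <- sprintf("TOY:%07d", seq_len(nTerms))
    terms <- data.frame(id = ids,
                        name = sprintf("synthetic term %d", seq_len(nTerms)),
                        namespace = namespace, stringsAsFactors = FALSE)
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
    if (nTerms > 1) {
      childEdges <- lapply(2:nTerms, function(k) {
        nPar <- if (k > 2) sample(1:2, 1) else 1L
        data.frame(child = ids[k],
                   parent = ids[sample.int(k - 1L, min(nPar, k - 1L))],
                   relation = "is_a", stringsAsFactors = FALSE)
      })
      edges <- do.call(rbind, childEdges)
    }
    graph <- OntologyGraph(terms, edges)

    # background: each protein gets ~annotationsPerProtein random direct terms
    nAnn <- rpois(length(proteins), annotationsPerProtein)
    ann <- data.frame(
      protein_id = rep(proteins, nAnn),
      term_id = ids[sample.int(nTerms, sum(nAnn), replace = TRUE)],
      stringsAsFactors = FALSE)

    planted <- character(0)
    if (plantedTerms > 0) {
      # plant only in leaves: an internal node's propagated membership is
      # dominated by its descendants' random annotations, which would make
      # the planted signal unrecoverable by design
      leaves <- setdiff(ids[-1L], edges$parent)
      if (length(leaves) < plantedTerms)
        stop("not enough leaf terms to plant; increase nTerms",
             call. = FALSE)
      planted <- sample(leaves, plantedTerms)
      sig <- intersect(significantSet, proteins)
      other <- setdiff(proteins, sig)
      for (t in planted) {
        nSig <- min(length(sig), round(plantedFraction * termSize))
        nOth <- min(length(other), termSize - nSig)
        members <- c(sample(sig, nSig), if (nOth > 0) sample(other, nOth))
        ann <- rbind(ann, data.frame(protein_id = members, term_id = t,
                                     stringsAsFactors = FALSE))
      }
    }
    ann <- unique(ann)
    ann <- ann[order(ann$protein_id, ann$term_id), ]
    rownames(ann) <- NULL
    list(graph = graph, annotations = ann, planted = planted)
  })
}
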