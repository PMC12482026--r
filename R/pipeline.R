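#' Pipeline configuration
#'
#' Bundles and validates everything [runPipeline()] needs. Thresholds
#' default to the significance-cascade values used throughout the package
#' (1% FDR, twofold change, 4 valid values per condition for the
#' three-condition design; 0.8 log2 units for the two-condition design).
#'
#' @param experiment `"overexpression"` (3 conditions) or `"knockout"`
#'   (2 conditions).
#' @param peptides path to a peptide quantification TSV.
#' @param design path to a sample-design TSV.
#' @param outDir output directory (created if needed).
#' @param qThreshold,fcThreshold,minValid,minAbsLog2 cascade thresholds.
#' @param nPerm permutation budget.
#' @param seed integer seed driving every stochastic stage.
#' @param minShared MaxLFQ minimum shared peptides per sample pair.
#' @param obo,annotations,mapping optional ontology inputs (OBO file,
#'   protein-to-term TSV/GAF, identifier-mapping TSV). Enrichment and term
#'   scores run only when `obo` and `annotations` are given.
#' @param propagate propagate annotations up the DAG (default `TRUE`).
#' @param weighting term-score weighting mode(s) to emit.
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(experiment = c("overexpression", "knockout"),
                           peptides, design, outDir,
                           qThreshold = 0.01, fcThreshold = 2,
                           minValid = 4, minAbsLog2 = 0.8,
                           nPerm = 1000, seed = 1, minShared = 1,
                           obo = NULL, annotations = NULL, mapping = NULL,
                           propagate = TRUE,
                           weighting = c("none", "significance")) {
  experiment <- match.arg(experiment)
  .assertNumber(qThreshold, "qThreshold", 0, strict = TRUE)
  .assertNumber(fcThreshold, "fcThreshold", 0, strict = TRUE)
  .assertCount(minValid, "minValid", 1)
  .assertNumber(minAbsLog2, "minAbsLog2", 0, strict = TRUE)
  .assertCount(nPerm, "nPerm", 2)
  weighting <- match.arg(weighting, several.ok = TRUE)
  structure(list(experiment = experiment, peptides = peptides,
                 design = design, outDir = outDir,
                 qThreshold = qThreshold, fcThreshold = fcThreshold,
                 minValid = minValid, minAbsLog2 = minAbsLog2,
                 nPerm = nPerm, seed = seed, minShared = minShared,
                 obo = obo, annotations = annotations, mapping = mapping,
                 propagate = isTRUE(propagate), weighting = weighting),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the arguments of [pipelineConfig()]; relative input
#' paths are resolved against the file's directory.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  for (f in c("peptides", "design", "obo", "annotations", "mapping")) {
    if (!is.null(raw[[f]]) && !grepl("^(/|[A-Za-z]:)", raw[[f]]))
      raw[[f]] <- file.path(base, raw[[f]])
  }
  do.call(pipelineConfig, raw)
}

.stageLog <- function(name, rowsIn, rowsOut, t0) {
  message(sprintf("[%s] %s -> %s rows (%.2fs)", name, rowsIn, rowsOut,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full quantification-to-ontology pipeline
#'
#' Stage order: peptide rollup with both methods (MaxLFQ and summing) ->
#' differential testing -> significance cascade -> extreme-fold-change
#' candidate dossier -> left-censored imputation -> volcano tables -> GO
#' enrichment -> term-score matrices -> run manifest. All inputs are
#' validated before anything is written; all randomness derives from the
#' config seed, so identical config + inputs give identical outputs.
#'
#' @param config a [pipelineConfig()] (or path readable by
#'   [readPipelineConfig()]).
#' @return invisibly, a list with the in-memory stage results
#'   (`maxlfq`, `summed`, `diff`, `significant`, `candidates`,
#'   `enrichment`, `termScores`, `manifest`); files are written under
#'   `config$outDir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))

  # ---- validation: fail before writing anything ----
  for (f in c("peptides", "design"))
    if (!file.exists(config[[f]]))
      stop("input not readable: ", config[[f]], call. = FALSE)
  for (f in c("obo", "annotations", "mapping"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("input not readable: ", config[[f]], call. = FALSE)
  design <- readSampleDesign(config$design)
  nCond <- length(unique(design$condition))
  if (config$experiment == "overexpression" && nCond != 3L)
    stop("overexpression design needs 3 conditions, found ", nCond,
         call. = FALSE)
  if (config$experiment == "knockout" && nCond != 2L)
    stop("knockout design needs 2 conditions, found ", nCond, call. = FALSE)
  peptides <- readPeptideTable(config$peptides, design)

  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outDir, ...)
  manifest <- list(
    config = config[setdiff(names(config), "outDir")],
    package_version = as.character(utils::packageVersion("dialfq")),
    input_checksums = as.list(tools::md5sum(unlist(
      Filter(Negate(is.null),
             config[c("peptides", "design", "obo", "annotations",
                      "mapping")])))),
    stages = list())
  stage <- function(name, rowsIn, rowsOut, t0) {
    manifest$stages[[name]] <<- list(
      rows_in = rowsIn, rows_out = rowsOut,
      seconds = round(as.numeric(Sys.time()) - t0, 3))
    .stageLog(name, rowsIn, rowsOut, t0)
  }

  # ---- quantification ----
  t0 <- as.numeric(Sys.time())
  maxlfq <- quantifyProteins(peptides, "maxlfq", minShared = config$minShared)
  summed <- quantifyProteins(peptides, "summed")
  writeProteinMatrix(maxlfq, out("protein_maxlfq.tsv"))
  writeProteinMatrix(summed, out("protein_summed.tsv"))
  stage("quantify", nrow(peptides), nrow(maxlfq), t0)

  # ---- differential testing ----
  t0 <- as.numeric(Sys.time())
  res <- diffTest(maxlfq, experiment = config$experiment,
                  nPerm = config$nPerm, seed = config$seed)
  writeDiffResult(res, out("diff_result.tsv"))
  stage("diffstats", nrow(maxlfq), nrow(res), t0)

  # ---- significance cascade ----
  t0 <- as.numeric(Sys.time())
  significant <- if (config$experiment == "overexpression") {
    filterOverexpression(res, qThreshold = config$qThreshold,
                         fcThreshold = config$fcThreshold,
                         minValid = config$minValid)
  } else {
    filterKnockout(res, qThreshold = config$qThreshold,
                   minAbsLog2 = config$minAbsLog2)
  }
  writeResultTable(data.frame(protein_group = significant,
                              stringsAsFactors = FALSE),
                   out("significant.tsv"))
  stage("filter", nrow(res), length(significant), t0)

  # ---- extreme-fold-change candidates ----
  t0 <- as.numeric(Sys.time())
  candidates <- summingExtremeCandidates(maxlfq, summed,
                                         minValidPresent = config$minValid,
                                         peptides = peptides)
  writeResultTable(candidates, out("extreme_candidates.tsv"))
  dossier <- attr(candidates, "dossier")
  if (length(dossier)) {
    dossierDf <- do.call(rbind, lapply(names(dossier), function(pg) {
      d <- data.frame(protein_group = pg,
                      precursor_id = rownames(dossier[[pg]]),
                      stringsAsFactors = FALSE)
      cbind(d, as.data.frame(dossier[[pg]]))
    }))
    writeResultTable(dossierDf, out("extreme_candidate_peptides.tsv"))
  }
  stage("extreme_candidates", nrow(res), nrow(candidates), t0)

  # ---- imputation + volcano ----
  t0 <- as.numeric(Sys.time())
  imputed <- imputeLeftCensored(maxlfq, seed = config$seed)
  nPair <- 0L
  for (pair in metadata(res)$pairs) {
    vt <- volcanoTable(res, imputed, pair, minValid = config$minValid)
    writeResultTable(vt, out(sprintf("volcano_%s.tsv", pair)))
    nPair <- nPair + nrow(vt)
  }
  stage("volcano", nrow(res), nPair, t0)

  # ---- ontology ----
  enrichment <- NULL
  termScores <- list()
  if (!is.null(config$obo) && !is.null(config$annotations)) {
    t0 <- as.numeric(Sys.time())
    graph <- parseOBO(config$obo)
    ann <- readAnnotations(config$annotations)
    detected <- rownames(res)
    sig <- significant
    if (!is.null(config$mapping)) {
      mapping <- readIdMapping(config$mapping)
      trDet <- translateIds(detected, mapping)
      trSig <- translateIds(sig, mapping)
      detected <- unique(trDet$translated$to)
      sig <- unique(trSig$translated$to)
      if (length(trDet$unmapped))
        writeResultTable(data.frame(protein_id = trDet$unmapped,
                                    stringsAsFactors = FALSE),
                         out("unmapped_ids.tsv"))
    }
    enrichment <- fisherEnrichment(sig, detected, ann, graph,
                                   propagate = config$propagate)
    writeResultTable(enrichment, out("enrichment.tsv"))
    anovaP <- if ("anova_p" %in% colnames(res))
      setNames(res$anova_p, rownames(res)) else NULL
    scoreInput <- assay(maxlfq, "log2")
    if (!is.null(config$mapping)) {
      tr <- translateIds(rownames(scoreInput), mapping)$translated
      # keep one row per translated id (first mapping wins)
      tr <- tr[!duplicated(tr$to), ]
      scoreInput <- scoreInput[tr$from, , drop = FALSE]
      rownames(scoreInput) <- tr$to
      if (!is.null(anovaP)) {
        anovaP <- anovaP[tr$from]
        names(anovaP) <- tr$to
      }
    }
    for (mode in config$weighting) {
      if (mode == "significance" && is.null(anovaP)) next
      sc <- termScoreMatrix(scoreInput, ann, anovaP = anovaP, mode = mode,
                            graph = graph, propagate = config$propagate)
      writeTermScores(sc, out(sprintf("term_scores_%s.tsv", mode)))
      termScores[[mode]] <- sc
    }
    stage("ontology", length(detected),
          if (is.null(enrichment)) 0L else nrow(enrichment), t0)
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(maxlfq = maxlfq, summed = summed, diff = res,
                 significant = significant, candidates = candidates,
                 enrichment = enrichment, termScores = termScores,
                 manifest = manifest))
}
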