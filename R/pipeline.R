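#' @importFrom tools md5sum
#' @importFrom utils packageVersion head
NULL

#' Pipeline configuration
#'
#' Collects every stage threshold of the integrated analysis with the
#' study's defaults: fold-change 1 (log2), p 0.05, gene set sizes 10-250
#' (proteins) / 10-600 (RNA) / 5-150 (methylome ORA), over-representation
#' count > 4, semantic-similarity cutoff 0.4, 1000 most variant features
#' for clustering, BH/BY alpha 0.05. Thresholds are validated before any
#' computation; a YAML file with the same field names can be supplied
#' instead of arguments.
#'
#' @param simulation a \code{\link{simulationConfig}} describing the
#'   synthetic study to analyse (default), or NULL when file inputs are
#'   given.
#' @param inputs optional named list of file paths (\code{proteome},
#'   \code{transcriptome}, \code{methylome}, \code{annotations},
#'   \code{cpgAnnotation}, \code{gmt}) read with the package readers.
#' @param fcThreshold,pThreshold differential selection thresholds.
#' @param gseaMinSize,gseaMaxSize,rnaMaxSize,methMinSize,methMaxSize gene
#'   set size windows.
#' @param oraMinCount minimum ORA overlap for an over-representation call.
#' @param similarityThreshold semantic-redundancy cutoff.
#' @param topVariant number of most-variant features for clustering.
#' @param alpha BH/BY significance level.
#' @param nPerm GSEA permutations; \code{kRange}, \code{nResamples},
#'   \code{subsampleFrac} configure consensus clustering.
#' @param kRange candidate cluster numbers.
#' @param nResamples consensus-clustering resampling iterations.
#' @param subsampleFrac consensus-clustering subsample fraction.
#' @param seed integer master seed for every stochastic stage.
#' @param outputDir directory for intermediate tables and the manifest;
#'   NULL keeps everything in memory.
#' @param yaml optional path to a YAML file overriding the arguments.
#' @return a validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           inputs = NULL,
                           fcThreshold = 1, pThreshold = 0.05,
                           gseaMinSize = 10L, gseaMaxSize = 250L,
                           rnaMaxSize = 600L,
                           methMinSize = 5L, methMaxSize = 150L,
                           oraMinCount = 5L,
                           similarityThreshold = 0.4,
                           topVariant = 1000L, alpha = 0.05,
                           nPerm = 1000L, kRange = 2:5,
                           nResamples = 1000L, subsampleFrac = 0.8,
                           seed = 1L, outputDir = NULL, yaml = NULL) {
  cfg <- list(simulation = simulation, inputs = inputs,
              fcThreshold = fcThreshold, pThreshold = pThreshold,
              gseaMinSize = gseaMinSize, gseaMaxSize = gseaMaxSize,
              rnaMaxSize = rnaMaxSize, methMinSize = methMinSize,
              methMaxSize = methMaxSize, oraMinCount = oraMinCount,
              similarityThreshold = similarityThreshold,
              topVariant = topVariant, alpha = alpha, nPerm = nPerm,
              kRange = kRange, nResamples = nResamples,
              subsampleFrac = subsampleFrac, seed = seed,
              outputDir = outputDir)
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    for (k in names(over)) cfg[[k]] <- over[[k]]
  }
  if (cfg$pThreshold <= 0 || cfg$pThreshold > 1)
    stop("pThreshold must lie in (0, 1]")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must lie in (0, 1]")
  if (cfg$fcThreshold < 0) stop("fcThreshold must be >= 0")
  if (cfg$similarityThreshold < 0 || cfg$similarityThreshold > 1)
    stop("similarityThreshold must lie in [0, 1]")
  if (cfg$gseaMinSize < 1 || cfg$gseaMaxSize < cfg$gseaMinSize)
    stop("invalid GSEA size range")
  if (cfg$subsampleFrac <= 0 || cfg$subsampleFrac > 1)
    stop("subsampleFrac must lie in (0, 1]")
  if (!is.null(cfg$inputs)) {
    missing <- !vapply(unlist(cfg$inputs), file.exists, TRUE)
    if (any(missing))
      stop("input file(s) not found: ",
           paste(unlist(cfg$inputs)[missing], collapse = ", "))
  }
  structure(cfg, class = "PipelineConfig")
}

# one root term plus one child per gene set: the minimal DAG that lets the
# redundancy filter run over a plain GMT collection
.dagFromCollection <- function(sets) {
  ids <- setIds(sets)
  terms <- data.frame(id = c("ROOT", ids),
                      name = c("root", ids),
                      namespace = "gene_sets", stringsAsFactors = FALSE)
  parents <- c(list(ROOT = character()),
               setNames(rep(list("ROOT"), length(ids)), ids))
  OntologyDAG(terms, parents, geneSets(sets))
}

.stageLog <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.2fs)", stage, paste(..., collapse = " "),
                  as.numeric(Sys.time()) - t0))
}

#' Run the integrated multi-omics pipeline
#'
#' Executes the full analysis in the study's order: normalization, batch
#' adjustment (when more than one batch is present), subgroup-stratified
#' differential testing, combined ranking, preranked GSEA of proteome and
#' transcriptome, over-representation analysis with semantic-redundancy
#' pruning, the histomorphology-independent selection, the promoter
#' methylation-protein correlation ORA, the three-omics term overlap, and
#' consensus clustering. Every stochastic stage derives its seed from the
#' config seed, so a rerun with the same config is bit-identical. When
#' \code{outputDir} is set, every intermediate table is written as TSV/JSON
#' together with a manifest recording package version, seed, parameters and
#' file checksums.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return (invisibly) a result bundle: the input objects plus
#'   \code{differential} (per-subgroup tables), \code{selection},
#'   \code{ranks}, \code{gseaProteome}, \code{gseaTranscriptome},
#'   \code{ora}, \code{oraPruned}, \code{methylation} (correlation table,
#'   significant genes, ORA), \code{overlap}, \code{clustering}, and
#'   \code{manifest}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- as.numeric(Sys.time())

  # --- acquire -------------------------------------------------------------
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    ann <- readSampleAnnotation(inp$annotations)
    data <- list(
      proteome = readOmicsMatrix(inp$proteome, "proteome", sampleInfo = ann),
      transcriptome = if (!is.null(inp$transcriptome))
        readOmicsMatrix(inp$transcriptome, "transcriptome", sampleInfo = ann),
      methylome = if (!is.null(inp$methylome))
        readOmicsMatrix(inp$methylome, "methylome"),
      annotations = ann,
      cpgAnnotation = if (!is.null(inp$cpgAnnotation))
        readCpgAnnotation(inp$cpgAnnotation),
      geneSets = readGmt(inp$gmt),
      truth = NULL)
  } else {
    data <- generateMultiOmics(config$simulation)
  }
  .stageLog("acquire", t0, sprintf("proteome %d x %d", nrow(data$proteome),
                                   ncol(data$proteome)))

  ann <- data$annotations
  tumor <- ann$sample_id[!ann$is_reference]
  prot <- data$proteome[, tumor]

  # --- normalize + batch ---------------------------------------------------
  prot <- medianCenter(prot)
  if (length(unique(ann[tumor, "batch"])) > 1L)
    prot <- combatAdjust(prot)$corrected
  .stageLog("normalize", t0, "median-centered",
            if (length(unique(ann[tumor, "batch"])) > 1L) "+ batch-adjusted" else "")

  # --- differential --------------------------------------------------------
  etantr <- tumor[ann[tumor, "subgroup"] == "ETANTR"]
  eblmepl <- tumor[ann[tumor, "subgroup"] == "EBL_MEPL"]
  others <- tumor[ann[tumor, "entity"] %in% c("ATRT", "MB")]
  diffEtantr <- differentialTable(prot, etantr, others)
  diffEbl <- differentialTable(prot, eblmepl, others)
  diffEtmr <- differentialTable(prot, c(etantr, eblmepl), others)
  selection <- morphologyIndependentSelection(
    diffEtantr, diffEbl, config$fcThreshold, config$pThreshold)
  .stageLog("differential", t0, sprintf("%d morphology-independent features",
                                        nrow(selection)))

  # --- ranking + GSEA ------------------------------------------------------
  scoreOf <- function(d) setNames(rankStatistic(d$fc, pmax(d$p, 1e-300)), d$feature)
  ranks <- combineSubgroupRanks(scoreOf(diffEtantr), scoreOf(diffEbl))
  gseaProt <- gseaPreranked(ranks, data$geneSets,
                            minSize = config$gseaMinSize,
                            maxSize = config$gseaMaxSize,
                            nPerm = config$nPerm, seed = config$seed)
  gseaRna <- NULL
  if (!is.null(data$transcriptome)) {
    rna <- medianCenter(data$transcriptome[, tumor])
    diffRnaA <- differentialTable(rna, etantr, others)
    diffRnaB <- differentialTable(rna, eblmepl, others)
    rnaRanks <- combineSubgroupRanks(scoreOf(diffRnaA), scoreOf(diffRnaB))
    gseaRna <- gseaPreranked(rnaRanks, data$geneSets,
                             minSize = config$gseaMinSize,
                             maxSize = config$rnaMaxSize,
                             nPerm = config$nPerm, seed = config$seed + 1L)
  }
  .stageLog("gsea", t0, sprintf("%d proteome sets tested", nrow(gseaProt)))

  # --- ORA + redundancy pruning -------------------------------------------
  sigProteins <- diffEtmr$feature[!is.na(diffEtmr$p) &
                                    diffEtmr$p <= config$pThreshold]
  ora <- oraHypergeometric(sigProteins, rownames(prot), data$geneSets,
                           minSize = config$gseaMinSize,
                           maxSize = config$gseaMaxSize,
                           pThreshold = config$pThreshold,
                           minCount = config$oraMinCount)
  dag <- .dagFromCollection(data$geneSets)
  oraPruned <- redundancyFilter(ora, dag, config$similarityThreshold)
  .stageLog("ora", t0, sprintf("%d terms, %d after pruning",
                               nrow(ora), nrow(oraPruned)))

  # --- methylome link ------------------------------------------------------
  methylation <- NULL
  if (!is.null(data$methylome) && !is.null(data$cpgAnnotation)) {
    meth <- filterProbes(data$methylome, data$cpgAnnotation)
    corr <- promoterCorrelation(meth, prot, data$cpgAnnotation)
    sigGenes <- intersect(significantGenes(corr, config$alpha), sigProteins)
    methOra <- if (length(sigGenes))
      methylationOra(sigGenes, sigProteins, data$geneSets,
                     minSize = config$methMinSize,
                     maxSize = config$methMaxSize)
    methylation <- list(correlation = corr, significantGenes = sigGenes,
                        ora = methOra)
    .stageLog("methylome", t0, sprintf("%d pairs, %d correlated genes",
                                       nrow(corr), length(sigGenes)))
  }

  # --- three-omics overlap -------------------------------------------------
  overlap <- NULL
  if (!is.null(gseaRna) && !is.null(methylation)) {
    protTerms <- gseaProt$set_id[gseaProt$padj <= config$alpha]
    rnaTerms <- gseaRna$set_id[gseaRna$padj <= config$alpha]
    methTerms <- if (!is.null(methylation$ora))
      methylation$ora$term[methylation$ora$over_represented] else character()
    overlap <- triomicsOverlap(protTerms, rnaTerms, methTerms)
  }

  # --- clustering ----------------------------------------------------------
  topFeat <- selectTopVariant(prot, min(config$topVariant, nrow(prot)))
  clustering <- consensusCluster(prot[topFeat, ], kRange = config$kRange,
                                 nResamples = config$nResamples,
                                 subsampleFrac = config$subsampleFrac,
                                 seed = config$seed + 2L)
  .stageLog("clustering", t0, sprintf("chosen k = %d", chosenK(clustering)))

  bundle <- list(data = data, proteomeNormalized = prot,
                 differential = list(ETANTR = diffEtantr, EBL_MEPL = diffEbl,
                                     ETMR = diffEtmr),
                 selection = selection, ranks = ranks,
                 gseaProteome = gseaProt, gseaTranscriptome = gseaRna,
                 ora = ora, oraPruned = oraPruned,
                 methylation = methylation, overlap = overlap,
                 clustering = clustering)

  if (!is.null(config$outputDir)) {
    bundle$manifest <- .writePipelineOutputs(bundle, config)
  }
  invisible(bundle)
}

.writeTsv <- function(df, path) {
  df <- as.data.frame(df)
  for (cn in colnames(df))
    if (is.list(df[[cn]]))
      df[[cn]] <- vapply(df[[cn]], paste, character(1), collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.writePipelineOutputs <- function(bundle, config) {
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$outputDir, name)
  files <- c(
    writeOmicsMatrix(bundle$proteomeNormalized, out("proteome_normalized.tsv")),
    .writeTsv(bundle$differential$ETANTR, out("differential_etantr.tsv")),
    .writeTsv(bundle$differential$EBL_MEPL, out("differential_ebl_mepl.tsv")),
    .writeTsv(bundle$differential$ETMR, out("differential_etmr.tsv")),
    .writeTsv(bundle$selection, out("morphology_independent.tsv")),
    .writeTsv(data.frame(gene = names(bundle$ranks), score = bundle$ranks),
              out("combined_ranks.tsv")),
    .writeTsv(bundle$gseaProteome, out("gsea_proteome.tsv")),
    .writeTsv(bundle$ora, out("ora_proteome.tsv")),
    .writeTsv(bundle$oraPruned, out("ora_proteome_pruned.tsv")))
  if (!is.null(bundle$gseaTranscriptome))
    files <- c(files, .writeTsv(bundle$gseaTranscriptome, out("gsea_transcriptome.tsv")))
  if (!is.null(bundle$methylation)) {
    files <- c(files, .writeTsv(bundle$methylation$correlation,
                                out("methylation_correlation.tsv")))
    if (!is.null(bundle$methylation$ora))
      files <- c(files, .writeTsv(bundle$methylation$ora, out("methylation_ora.tsv")))
  }
  if (!is.null(bundle$overlap)) {
    jsonlite::write_json(bundle$overlap, out("triomics_overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, out("triomics_overlap.json"))
  }
  cm <- consensusMatrix(bundle$clustering)
  files <- c(files,
             writeOmicsMatrix(cm, out("consensus_matrix.tsv"), idColumn = "sample_id"),
             .writeTsv(data.frame(sample = rownames(bundle$clustering@assignments),
                                  bundle$clustering@assignments,
                                  check.names = FALSE),
                       out("cluster_assignments.tsv")))
  manifest <- list(
    package = "rosetteomics",
    version = as.character(packageVersion("rosetteomics")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("simulation", "inputs", "outputDir"))],
    files = as.list(md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
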