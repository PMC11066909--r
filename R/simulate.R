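#' @importFrom stats rnorm plogis
NULL

#' Simulation configuration for the synthetic multi-omics study
#'
#' Bundles and validates the parameters of the synthetic generator. The
#' defaults emulate the study design: 40 embryonal brain tumors in 3
#' entities (16 ETMR split into 8 ETANTR and 8 EBL/MEPL, 9 AT/RT, 15 MB),
#' a methylome available for a 28-sample subset, one planted differentially
#' abundant 20-gene set at +1.5 log2 units in ETMR, promoter CpGs
#' anti-correlated with 12 of its proteins at strength 0.9, additive
#' Gaussian log2 noise of 0.5, and a transcriptome that attenuates the
#' proteome signal.
#'
#' @param nFeatures number of gene-symbol features.
#' @param groupSizes named counts for \code{ETMR_ETANTR},
#'   \code{ETMR_EBL_MEPL}, \code{ATRT}, \code{MB} (each >= 2).
#' @param nSets,setSize number and size of (non-overlapping) gene sets
#'   drawn from the feature pool.
#' @param plantedSets list of lists with \code{set_id}, \code{effect}
#'   (log2 units) and \code{scope} (\code{"both"}, \code{"ETANTR_only"},
#'   \code{"EBL_MEPL_only"}).
#' @param noiseSd additive Gaussian noise on the log2 proteome scale.
#' @param rnaAttenuation fraction of the proteome signal carried by the
#'   transcriptome; \code{rnaNoiseSd} its own noise.
#' @param rnaNoiseSd transcriptome noise (log2 units).
#' @param nBatches number of batches the tumor samples are split into
#'   (round-robin); \code{batchShift}/\code{batchScale} give per-batch
#'   location/scale distortions (length \code{nBatches}).
#' @param batchShift,batchScale per-batch location shift and scale factor
#'   applied after signal and noise.
#' @param nReferencePerBatch replicate-like reference samples added to each
#'   batch (small independent noise \code{refNoiseSd} around a shared
#'   reference profile).
#' @param refNoiseSd reference replicate noise (log2 units).
#' @param methylLink list of lists with \code{gene}, \code{nCpgs},
#'   \code{sign} (+1/-1) and \code{strength} in [0, 1]; \code{NULL} plants
#'   anti-correlated promoter CpGs on the first 12 genes of the first
#'   planted set.
#' @param nMethylomeSamples size of the methylome subset (default 28).
#' @param nCpgsBackground unlinked CpGs (a mixture of promoter, body and
#'   flagged probes forming the null family).
#' @param seed integer seed; identical seeds give bitwise-identical output
#'   (R's default Mersenne-Twister RNG).
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nFeatures = 2000L,
                             groupSizes = c(ETMR_ETANTR = 8L, ETMR_EBL_MEPL = 8L,
                                            ATRT = 9L, MB = 15L),
                             nSets = 25L, setSize = 20L,
                             plantedSets = list(list(set_id = "SET01",
                                                     effect = 1.5,
                                                     scope = "both")),
                             noiseSd = 0.5,
                             rnaAttenuation = 0.6, rnaNoiseSd = 0.5,
                             nBatches = 1L, batchShift = 0, batchScale = 1,
                             nReferencePerBatch = 0L, refNoiseSd = 0.1,
                             methylLink = NULL,
                             nMethylomeSamples = 28L,
                             nCpgsBackground = 200L,
                             seed = 1L) {
  need <- c("ETMR_ETANTR", "ETMR_EBL_MEPL", "ATRT", "MB")
  if (!all(need %in% names(groupSizes)))
    stop("groupSizes needs entries: ", paste(need, collapse = ", "))
  if (any(groupSizes[need] < 2L)) stop("all group sizes must be >= 2")
  if (nSets * setSize > nFeatures)
    stop("nSets * setSize exceeds nFeatures")
  for (ps in plantedSets) {
    if (!all(c("set_id", "effect", "scope") %in% names(ps)))
      stop("each planted set needs set_id, effect and scope")
    if (!is.finite(ps$effect)) stop("planted effect sizes must be finite")
    if (!ps$scope %in% c("both", "ETANTR_only", "EBL_MEPL_only"))
      stop("unknown planted-set scope: ", ps$scope)
  }
  batchShift <- rep_len(batchShift, nBatches)
  batchScale <- rep_len(batchScale, nBatches)
  if (any(batchScale <= 0)) stop("batch scale factors must be positive")
  for (ml in methylLink) {
    if (!all(c("gene", "nCpgs", "sign", "strength") %in% names(ml)))
      stop("each methylLink entry needs gene, nCpgs, sign and strength")
    if (ml$strength < 0 || ml$strength > 1)
      stop("methylLink strength must lie in [0, 1]")
    if (!ml$sign %in% c(-1, 1)) stop("methylLink sign must be -1 or +1")
  }
  structure(list(
    nFeatures = as.integer(nFeatures), groupSizes = groupSizes[need],
    nSets = as.integer(nSets), setSize = as.integer(setSize),
    plantedSets = plantedSets, noiseSd = noiseSd,
    rnaAttenuation = rnaAttenuation, rnaNoiseSd = rnaNoiseSd,
    nBatches = as.integer(nBatches), batchShift = batchShift,
    batchScale = batchScale,
    nReferencePerBatch = as.integer(nReferencePerBatch),
    refNoiseSd = refNoiseSd, methylLink = methylLink,
    nMethylomeSamples = as.integer(nMethylomeSamples),
    nCpgsBackground = as.integer(nCpgsBackground),
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Generate a matched synthetic multi-omics study
#'
#' Emits proteome, transcriptome and methylome matrices with matched sample
#' ids, sample and CpG annotations, the gene-set collection, and a truth
#' record of every planted effect. Baseline feature means are N(0, 1);
#' planted sets are shifted by their effect size in ETMR samples of the
#' configured scope; the transcriptome carries an attenuated copy of the
#' proteome signal; promoter CpGs of linked genes follow a latent Gaussian
#' tied to the protein level (then logistic-squashed into [0, 1]); batch
#' shift/scale is applied after signal and noise; reference samples are
#' replicate-like draws shared across batches.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{proteome}, \code{transcriptome},
#'   \code{methylome} (\linkS4class{OmicsMatrix}), \code{annotations}
#'   (sample data.frame), \code{cpgAnnotation}, \code{geneSets}
#'   (\linkS4class{GeneSetCollection}) and \code{truth}.
#' @export
generateMultiOmics <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed, .generateMultiOmicsImpl(config))
}

.generateMultiOmicsImpl <- function(cfg) {
  nf <- cfg$nFeatures
  features <- sprintf("G%04d", seq_len(nf))
  mu <- rnorm(nf)

  gs <- cfg$groupSizes
  groups <- rep(names(gs), gs)
  nTumor <- length(groups)
  sampleIds <- sprintf("S%03d", seq_len(nTumor))
  entity <- ifelse(startsWith(groups, "ETMR"), "ETMR",
                   ifelse(groups == "ATRT", "ATRT", "MB"))
  subgroup <- ifelse(groups == "ETMR_ETANTR", "ETANTR",
                     ifelse(groups == "ETMR_EBL_MEPL", "EBL_MEPL", "none"))
  batch <- sprintf("B%d", (seq_len(nTumor) - 1L) %% cfg$nBatches + 1L)

  # non-overlapping gene sets drawn from a shuffled feature pool
  pool <- sample(features)
  sets <- lapply(seq_len(cfg$nSets), function(i)
    sort(pool[seq((i - 1L) * cfg$setSize + 1L, i * cfg$setSize)]))
  names(sets) <- sprintf("SET%02d", seq_len(cfg$nSets))
  geneSets <- GeneSetCollection(sets)

  warnings <- character()
  if (length(cfg$plantedSets) > 1L) {
    ids <- vapply(cfg$plantedSets, `[[`, "", "set_id")
    for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
      a <- sets[[ids[i]]]; b <- sets[[ids[j]]]
      ov <- length(intersect(a, b)) / min(length(a), length(b))
      if (ov > 0.5)
        warnings <- c(warnings, sprintf(
          "planted sets %s and %s share %.0f%% of members (confounded design)",
          ids[i], ids[j], 100 * ov))
    }
  }

  # per-feature, per-sample planted effect
  effect <- matrix(0, nf, nTumor, dimnames = list(features, sampleIds))
  for (ps in cfg$plantedSets) {
    members <- sets[[ps$set_id]]
    if (is.null(members)) stop("planted set id not in the collection: ", ps$set_id)
    cols <- switch(ps$scope,
      both = subgroup %in% c("ETANTR", "EBL_MEPL"),
      ETANTR_only = subgroup == "ETANTR",
      EBL_MEPL_only = subgroup == "EBL_MEPL")
    effect[members, cols] <- effect[members, cols] + ps$effect
  }

  signal <- mu + effect                      # feature x sample signal
  prot <- signal + matrix(rnorm(nf * nTumor, sd = cfg$noiseSd), nf, nTumor)

  # reference samples: nReferencePerBatch distinct profiles, each present in
  # every batch as a replicate-like copy with small independent noise
  refIds <- character(); refBatch <- character()
  refValues <- NULL
  if (cfg$nReferencePerBatch > 0L) {
    refProfiles <- mu + matrix(rnorm(nf * cfg$nReferencePerBatch,
                                     sd = cfg$noiseSd),
                               nf, cfg$nReferencePerBatch)
    for (b in seq_len(cfg$nBatches)) {
      ids <- sprintf("REF_B%d_%d", b, seq_len(cfg$nReferencePerBatch))
      refIds <- c(refIds, ids)
      refBatch <- c(refBatch, rep(sprintf("B%d", b), length(ids)))
      refValues <- cbind(refValues,
                         refProfiles + matrix(rnorm(nf * length(ids),
                                                    sd = cfg$refNoiseSd),
                                              nf, length(ids)))
    }
    colnames(refValues) <- refIds
  }

  allValues <- cbind(prot, refValues)
  allBatch <- c(batch, refBatch)
  shift <- cfg$batchShift[as.integer(sub("^B", "", allBatch))]
  scale <- cfg$batchScale[as.integer(sub("^B", "", allBatch))]
  allValues <- sweep(sweep(allValues, 2L, scale, "*"), 2L, shift, "+")
  rownames(allValues) <- features

  annotations <- data.frame(
    sample_id = c(sampleIds, refIds),
    entity = c(entity, rep("MB", length(refIds))),
    subgroup = c(subgroup, rep("none", length(refIds))),
    batch = allBatch,
    pair_id = NA_character_,
    is_reference = c(rep(FALSE, nTumor), rep(TRUE, length(refIds))),
    stringsAsFactors = FALSE)
  rownames(annotations) <- annotations$sample_id

  proteome <- OmicsMatrix(allValues, "proteome", sampleInfo = annotations)

  # transcriptome: attenuated proteome signal, own noise, tumor samples only
  rna <- mu + cfg$rnaAttenuation * effect +
    matrix(rnorm(nf * nTumor, sd = cfg$rnaNoiseSd), nf, nTumor)
  dimnames(rna) <- list(features, sampleIds)
  transcriptome <- OmicsMatrix(rna, "transcriptome",
                               sampleInfo = annotations[sampleIds, ])

  # methylome subset and CpGs
  nMeth <- min(cfg$nMethylomeSamples, nTumor)
  methSamples <- sort(sample(sampleIds, nMeth))
  methylLink <- cfg$methylLink
  if (is.null(methylLink) && length(cfg$plantedSets)) {
    linkGenes <- utils::head(sets[[cfg$plantedSets[[1L]]$set_id]], 12L)
    methylLink <- lapply(linkGenes, function(g)
      list(gene = g, nCpgs = 1L, sign = -1, strength = 0.9))
  }
  cpgRows <- list(); betaRows <- list()
  cpgCounter <- 0L
  newCpg <- function() {
    cpgCounter <<- cpgCounter + 1L
    sprintf("cg%07d", cpgCounter)
  }
  for (ml in methylLink) {
    protLevel <- prot[ml$gene, methSamples]
    z <- as.vector(scale(protLevel))
    for (i in seq_len(ml$nCpgs)) {
      latent <- ml$sign * ml$strength * z +
        sqrt(1 - ml$strength^2) * rnorm(nMeth)
      beta <- plogis(1.5 * latent + rnorm(1, sd = 0.5))
      id <- newCpg()
      cpgRows[[id]] <- data.frame(
        cpg_id = id, gene = ml$gene,
        region = sample(c("TSS200", "TSS1500", "UTR5"), 1L),
        chromosome = sprintf("chr%d", sample.int(22L, 1L)),
        stringsAsFactors = FALSE)
      cpgRows[[id]]$flags <- list(character())
      betaRows[[id]] <- beta
    }
  }
  linkedGenes <- vapply(methylLink, `[[`, "", "gene")
  nBg <- cfg$nCpgsBackground
  bgGenes <- sample(setdiff(features, linkedGenes), nBg, replace = TRUE)
  bgRegion <- sample(c("TSS200", "TSS1500", "UTR5", "body", "other"), nBg,
                     replace = TRUE, prob = c(0.25, 0.2, 0.15, 0.3, 0.1))
  bgFlag <- sample(c("", .PROBE_FLAGS), nBg, replace = TRUE,
                   prob = c(0.85, 0.05, 0.05, 0.05))
  for (i in seq_len(nBg)) {
    id <- newCpg()
    cpgRows[[id]] <- data.frame(
      cpg_id = id, gene = bgGenes[i], region = bgRegion[i],
      chromosome = if (bgFlag[i] == "sex_chromosome") "chrX"
                   else sprintf("chr%d", sample.int(22L, 1L)),
      stringsAsFactors = FALSE)
    cpgRows[[id]]$flags <- list(if (bgFlag[i] == "") character() else bgFlag[i])
    betaRows[[id]] <- plogis(rnorm(1) + rnorm(nMeth))
  }
  cpgAnnotation <- do.call(rbind, cpgRows)
  betaMat <- do.call(rbind, betaRows)
  dimnames(betaMat) <- list(cpgAnnotation$cpg_id, methSamples)
  methylome <- OmicsMatrix(betaMat, "methylome",
                           sampleInfo = annotations[methSamples, ])

  truth <- list(
    plantedSets = cfg$plantedSets,
    setMembers = sets[vapply(cfg$plantedSets, `[[`, "", "set_id")],
    methylLink = methylLink,
    groups = setNames(groups, sampleIds),
    methylomeSamples = methSamples,
    batch = setNames(allBatch, c(sampleIds, refIds)),
    batchShift = cfg$batchShift, batchScale = cfg$batchScale,
    warnings = warnings)

  list(proteome = proteome, transcriptome = transcriptome,
       methylome = methylome, annotations = annotations,
       cpgAnnotation = cpgAnnotation, geneSets = geneSets, truth = truth)
}

#' Generate a synthetic gene-annotated ontology
#'
#' Builds a rooted is_a DAG of \code{nTerms} terms over \code{depth} levels
#' (depth 1 is a star with every term a child of the root). Leaf terms
#' annotate contiguous, mostly disjoint blocks of genes; about one in ten
#' non-leaf attachments gains a second parent so the graph is a genuine DAG.
#' One redundant pair is always planted: an extra term added as child of a
#' leaf, sharing most (> 80 percent) of its genes, so that semantic-
#' redundancy pruning has a known positive.
#'
#' @param nTerms number of terms excluding the planted redundant twin
#'   (>= 3).
#' @param depth levels below the root (>= 1).
#' @param seed integer seed.
#' @param genesPerLeaf genes annotated per leaf term (default 15).
#' @param namespace ontology namespace label.
#' @return an \linkS4class{OntologyDAG}; the planted pair is recorded in
#'   \code{attr(dag, "redundantPair")} (child first, then its parent leaf).
#' @export
generateOntology <- function(nTerms, depth = 2L, seed = 1L,
                             genesPerLeaf = 15L, namespace = "biological_process") {
  if (nTerms < 3L) stop("nTerms must be >= 3")
  if (depth < 1L) stop("depth must be >= 1")
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("T%04d", seq_len(nTerms))
    root <- ids[[1L]]
    rest <- ids[-1L]
    level <- rep(seq_len(depth), length.out = length(rest))
    level <- sort(level)
    parents <- setNames(vector("list", nTerms), ids)
    parents[[root]] <- character()
    for (i in seq_along(rest)) {
      lv <- level[[i]]
      cand <- if (lv == 1L) root else rest[level == lv - 1L]
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      extra <- if (length(cand) > 1L && stats::runif(1) < 0.1)
        sample(setdiff(cand, p), 1L) else character()
      parents[[rest[i]]] <- c(p, extra)
    }
    childrenCount <- table(factor(unlist(parents), levels = ids))
    leaves <- ids[childrenCount == 0L]
    genes <- sprintf("ONT%05d", seq_len(length(leaves) * genesPerLeaf))
    annotations <- list()
    for (i in seq_along(leaves)) {
      block <- genes[seq((i - 1L) * genesPerLeaf + 1L, i * genesPerLeaf)]
      # small spill-over into the neighbour block keeps blocks disjoint-ish
      if (i > 1L && stats::runif(1) < 0.5)
        block <- c(block[-1L], genes[(i - 1L) * genesPerLeaf])
      annotations[[leaves[i]]] <- block
    }
    host <- leaves[[length(leaves)]]
    twin <- sprintf("T%04d", nTerms + 1L)
    hostGenes <- annotations[[host]]
    nShared <- ceiling(0.9 * length(hostGenes))
    annotations[[twin]] <- hostGenes[seq_len(nShared)]
    terms <- data.frame(
      id = c(ids, twin),
      name = c(paste("term", c(ids, twin))),
      namespace = namespace, stringsAsFactors = FALSE)
    parents[[twin]] <- host
    dag <- OntologyDAG(terms, parents, annotations)
    attr(dag, "redundantPair") <- c(twin, host)
    dag
  })
}

#' Generate synthetic viability measurements
#'
#' Draws luminescence responses around a four-parameter logistic curve with
#' multiplicative Gaussian noise: \code{response = 4PL(conc) * (1 + N(0,
#' cv))}, \code{nReps} technical replicates per concentration.
#'
#' @param bottom,top,hill,ic50 true curve parameters (\code{ic50 > 0}).
#' @param concentrations distinct positive concentrations (>= 4).
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param nReps technical replicates per concentration.
#' @param seed integer seed.
#' @param cellLine identifier attached to the table.
#' @return long-format data.frame with columns \code{cell_line},
#'   \code{concentration}, \code{response}.
#' @export
generateViability <- function(bottom, top, hill, ic50, concentrations,
                              cv = 0.05, nReps = 6L, seed = 1L,
                              cellLine = "SIM") {
  if (cv < 0) stop("cv must be >= 0")
  if (ic50 <= 0) stop("ic50 must be positive")
  if (length(unique(concentrations)) < 4L)
    stop("at least 4 distinct concentrations are required")
  withr::with_seed(as.integer(seed), {
    conc <- rep(concentrations, each = nReps)
    mu <- fourPL(conc, bottom, top, hill, ic50)
    resp <- mu * (1 + rnorm(length(conc), sd = cv))
    data.frame(cell_line = cellLine, concentration = conc, response = resp,
               stringsAsFactors = FALSE)
  })
}
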