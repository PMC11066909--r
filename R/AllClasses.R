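#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.ASSAY_KINDS <- c("proteome", "transcriptome", "methylome")
.ENTITIES <- c("ETMR", "ATRT", "MB", "other")
.SUBGROUPS <- c("ETANTR", "EBL_MEPL", "none")
.REGIONS <- c("TSS200", "TSS1500", "UTR5", "body", "other")
.PROBE_FLAGS <- c("sex_chromosome", "snp_at_cpg", "cross_reactive")

#' OmicsMatrix: a feature-by-sample omics assay
#'
#' Container for one omics layer: log2 protein abundance, log2 expression, or
#' methylation beta values, with per-sample annotations in \code{colData}.
#' Extends \linkS4class{SummarizedExperiment}; rows are features identified by
#' gene symbol (proteome/transcriptome) or CpG id (methylome), columns are
#' samples. Methylome values must lie in [0, 1]; missing values are allowed in
#' every layer and are encoded as \code{NA}.
#'
#' @slot assayKind one of \code{"proteome"}, \code{"transcriptome"},
#'   \code{"methylome"}.
#' @aliases OmicsMatrix-class
#' @exportClass OmicsMatrix
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  representation(assayKind = "character")
)

.checkSampleInfo <- function(df) {
  msgs <- character()
  if ("entity" %in% colnames(df)) {
    bad <- setdiff(unique(as.character(df$entity)), .ENTITIES)
    if (length(bad))
      msgs <- c(msgs, sprintf("unknown entity value(s): %s",
                              paste(bad, collapse = ", ")))
  }
  if ("subgroup" %in% colnames(df)) {
    bad <- setdiff(unique(as.character(df$subgroup)), .SUBGROUPS)
    if (length(bad))
      msgs <- c(msgs, sprintf("unknown subgroup value(s): %s",
                              paste(bad, collapse = ", ")))
    if ("entity" %in% colnames(df)) {
      off <- df$subgroup != "none" & df$entity != "ETMR"
      if (any(off, na.rm = TRUE))
        msgs <- c(msgs, "subgroup other than 'none' assigned to a non-ETMR sample")
    }
  }
  if ("pair_id" %in% colnames(df)) {
    pid <- as.character(df$pair_id)
    pid <- pid[!is.na(pid) & pid != ""]
    if (length(pid)) {
      tab <- table(pid)
      if (any(tab != 2))
        msgs <- c(msgs, sprintf("pair_id(s) not occurring exactly twice: %s",
                                paste(names(tab)[tab != 2], collapse = ", ")))
      if ("subgroup" %in% colnames(df)) {
        for (p in unique(pid)) {
          sg <- df$subgroup[!is.na(df$pair_id) & df$pair_id == p]
          if (length(sg) == 2L && sg[1] == sg[2])
            msgs <- c(msgs, sprintf("pair '%s' has two samples of the same subgroup", p))
        }
      }
    }
  }
  msgs
}

setValidity("OmicsMatrix", function(object) {
  msgs <- character()
  if (length(object@assayKind) != 1L || !object@assayKind %in% .ASSAY_KINDS)
    msgs <- c(msgs, sprintf("assayKind must be one of: %s",
                            paste(.ASSAY_KINDS, collapse = ", ")))
  rn <- rownames(object)
  cn <- colnames(object)
  if (nrow(object) > 0L && (is.null(rn) || anyNA(rn)))
    msgs <- c(msgs, "feature ids (rownames) are required")
  else if (anyDuplicated(rn))
    msgs <- c(msgs, sprintf("duplicated feature id(s): %s",
                            paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  if (ncol(object) > 0L && (is.null(cn) || anyNA(cn)))
    msgs <- c(msgs, "sample ids (colnames) are required")
  else if (anyDuplicated(cn))
    msgs <- c(msgs, sprintf("duplicated sample id(s): %s",
                            paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  if (identical(object@assayKind, "methylome") && length(assays(object))) {
    v <- assay(object)
    if (any(v < 0 | v > 1, na.rm = TRUE))
      msgs <- c(msgs, "methylome beta values must lie within [0, 1]")
  }
  msgs <- c(msgs, .checkSampleInfo(as.data.frame(colData(object))))
  if (length(msgs)) msgs else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric feature-by-sample matrix with unique rownames
#'   (feature ids) and colnames (sample ids).
#' @param assayKind \code{"proteome"}, \code{"transcriptome"} or
#'   \code{"methylome"}.
#' @param sampleInfo optional data.frame of per-sample annotations; rows are
#'   matched to the matrix columns by a \code{sample_id} column or rownames.
#' @return an \linkS4class{OmicsMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' OmicsMatrix(m, "proteome")
#' @export
OmicsMatrix <- function(values, assayKind = c("proteome", "transcriptome", "methylome"),
                        sampleInfo = NULL) {
  assayKind <- match.arg(assayKind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sampleInfo)) {
    cd <- DataFrame(row.names = colnames(values))
  } else {
    sampleInfo <- as.data.frame(sampleInfo)
    key <- if ("sample_id" %in% colnames(sampleInfo)) {
      as.character(sampleInfo$sample_id)
    } else {
      rownames(sampleInfo)
    }
    idx <- match(colnames(values), key)
    if (anyNA(idx))
      stop("sampleInfo is missing annotation for sample(s): ",
           paste(colnames(values)[is.na(idx)], collapse = ", "))
    cd <- DataFrame(sampleInfo[idx, , drop = FALSE], row.names = colnames(values))
  }
  se <- SummarizedExperiment(assays = list(values = values), colData = cd)
  new("OmicsMatrix", se, assayKind = assayKind)
}

#' GeneSetCollection: named gene sets
#'
#' A collection of uniquely-identified gene sets (for example GO terms in GMT
#' form). Members are gene symbols, stored de-duplicated; member order is not
#' significant.
#'
#' @slot sets named list of character vectors (members per set id).
#' @slot names named character vector of human-readable descriptions.
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(sets = "list", names = "character")
)

setValidity("GeneSetCollection", function(object) {
  msgs <- character()
  ids <- base::names(object@sets)
  if (length(object@sets)) {
    if (is.null(ids) || any(ids == ""))
      msgs <- c(msgs, "every gene set needs a non-empty id")
    if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicated set id(s): %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(lengths(object@sets) == 0L))
      msgs <- c(msgs, "gene sets must have at least one member")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param names optional named character vector of set descriptions.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, names = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(names)) {
    names <- setNames(base::names(sets), base::names(sets))
  } else {
    names <- setNames(as.character(names)[match(base::names(sets), base::names(names))],
                      base::names(sets))
    names[is.na(names)] <- base::names(sets)[is.na(names)]
  }
  new("GeneSetCollection", sets = sets, names = names)
}

#' OntologyDAG: a rooted is_a ontology with gene annotations
#'
#' Terms connected by \code{is_a} edges (child to parent), one root per
#' namespace, with gene annotations propagated to ancestors and per-term
#' information content IC(t) = -log(n(t) / n(root)) computed from the
#' annotation counts within each namespace. IC of a root is 0 by construction.
#'
#' @slot terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @slot parents named list mapping each term id to its parent ids.
#' @slot annotations named list mapping term id to its propagated gene set.
#' @slot ic named numeric vector of information contents (NA when a term has
#'   no annotated genes).
#' @aliases OntologyDAG-class
#' @exportClass OntologyDAG
setClass("OntologyDAG",
  representation(terms = "data.frame", parents = "list",
                 annotations = "list", ic = "numeric")
)

setValidity("OntologyDAG", function(object) {
  msgs <- character()
  ids <- object@terms$id
  if (anyDuplicated(ids))
    msgs <- c(msgs, "duplicated term ids")
  cyc <- .findCycle(object@parents)
  if (!is.null(cyc))
    msgs <- c(msgs, sprintf("is_a cycle detected involving term '%s'", cyc))
  for (ns in unique(object@terms$namespace)) {
    nsIds <- ids[object@terms$namespace == ns]
    roots <- nsIds[vapply(object@parents[nsIds], length, 1L) == 0L]
    if (length(roots) != 1L)
      msgs <- c(msgs, sprintf("namespace '%s' must have exactly one root (found %d)",
                              ns, length(roots)))
  }
  # propagated annotations: parent is a superset of each child
  for (child in ids) {
    for (parent in object@parents[[child]]) {
      if (!all(object@annotations[[child]] %in% object@annotations[[parent]])) {
        msgs <- c(msgs, sprintf("annotation of '%s' is not a superset of child '%s'",
                                parent, child))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

# Kahn-style cycle detection on a child -> parents adjacency list.
# Returns NULL when acyclic, else the id of one term on a cycle.
.findCycle <- function(parents) {
  ids <- names(parents)
  outdeg <- vapply(parents, function(p) length(intersect(p, ids)), 1L)
  children <- new.env(parent = emptyenv())
  for (ch in ids) for (p in intersect(parents[[ch]], ids)) {
    assign(p, c(get0(p, envir = children, ifnotfound = character()), ch),
           envir = children)
  }
  queue <- ids[outdeg == 0L]
  seen <- 0L
  while (length(queue)) {
    node <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in get0(node, envir = children, ifnotfound = character())) {
      outdeg[[ch]] <- outdeg[[ch]] - 1L
      if (outdeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(ids)) NULL else ids[outdeg > 0L][1L]
}

#' Construct an OntologyDAG
#'
#' Direct annotations are propagated from each term to all of its ancestors
#' before information content is computed, so every term's gene set contains
#' the union of its descendants' sets.
#'
#' @param terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @param parents named list: term id to character vector of parent term ids
#'   (empty for a root).
#' @param annotations named list: term id to character vector of directly
#'   annotated gene symbols.
#' @return an \linkS4class{OntologyDAG}.
#' @export
OntologyDAG <- function(terms, parents, annotations = list()) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "namespace") %in% colnames(terms)))
  terms$id <- as.character(terms$id)
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) intersect(as.character(p), terms$id))
  cyc <- .findCycle(parents)
  if (!is.null(cyc))
    stop("is_a cycle detected involving term '", cyc, "'")
  prop <- .propagateAnnotations(terms$id, parents, annotations)
  ic <- .informationContent(terms, parents, prop)
  new("OntologyDAG", terms = terms, parents = parents,
      annotations = prop, ic = ic)
}

# union direct annotations upward: process terms children-before-parents
.propagateAnnotations <- function(ids, parents, annotations) {
  direct <- lapply(setNames(ids, ids), function(t)
    unique(as.character(annotations[[t]])))
  order <- .topoOrder(ids, parents)      # children first
  prop <- direct
  childrenOf <- .childrenMap(ids, parents)
  for (t in order) {
    kids <- childrenOf[[t]]
    if (length(kids))
      prop[[t]] <- unique(c(prop[[t]], unlist(prop[kids], use.names = FALSE)))
  }
  prop
}

.childrenMap <- function(ids, parents) {
  ch <- setNames(vector("list", length(ids)), ids)
  for (c0 in ids) for (p in parents[[c0]]) ch[[p]] <- c(ch[[p]], c0)
  ch
}

# topological order with leaves (no children) first, roots last
.topoOrder <- function(ids, parents) {
  childrenOf <- .childrenMap(ids, parents)
  ndesc <- vapply(childrenOf, length, 1L)
  queue <- ids[ndesc == 0L]
  out <- character()
  remaining <- ndesc
  while (length(queue)) {
    node <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, node)
    for (p in parents[[node]]) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) queue <- c(queue, p)
    }
  }
  out
}

.informationContent <- function(terms, parents, annotations) {
  ic <- setNames(rep(NA_real_, nrow(terms)), terms$id)
  for (ns in unique(terms$namespace)) {
    nsIds <- terms$id[terms$namespace == ns]
    root <- nsIds[vapply(parents[nsIds], length, 1L) == 0L]
    if (length(root) != 1L)
      stop("namespace '", ns, "' must have exactly one root (found ",
           length(root), ")")
    nRoot <- length(annotations[[root]])
    if (nRoot == 0L) next
    n <- vapply(annotations[nsIds], length, 1L)
    ic[nsIds] <- ifelse(n > 0L, -log(n / nRoot), NA_real_)
  }
  ic
}

#' BatchModel: empirical-Bayes batch adjustment parameters
#'
#' Location (gamma) and scale (delta^2) adjustment parameters per feature and
#' batch, on the standardized scale, together with the standardization used to
#' compute them.
#'
#' @slot gamma feature-by-batch matrix of EB-shrunk location shifts.
#' @slot delta2 feature-by-batch matrix of EB-shrunk variance factors (> 0).
#' @slot grandMean per-feature standardization mean.
#' @slot pooledVar per-feature standardization variance.
#' @slot batches character vector of batch levels.
#' @slot mode estimation mode (parametric empirical Bayes).
#' @slot referenceOnly whether parameters were estimated on reference samples
#'   only.
#' @aliases BatchModel-class
#' @exportClass BatchModel
setClass("BatchModel",
  representation(gamma = "matrix", delta2 = "matrix",
                 grandMean = "numeric", pooledVar = "numeric",
                 batches = "character", mode = "character",
                 referenceOnly = "logical")
)

setValidity("BatchModel", function(object) {
  msgs <- character()
  if (any(object@delta2 <= 0, na.rm = TRUE))
    msgs <- c(msgs, "delta2 must be positive")
  if (!identical(dim(object@gamma), dim(object@delta2)))
    msgs <- c(msgs, "gamma and delta2 must share dimensions")
  if (length(msgs)) msgs else TRUE
})

#' ConsensusResult: Monti consensus clustering output
#'
#' @slot consensus named list (one element per k) of sample-by-sample
#'   consensus matrices with entries in [0, 1], symmetric with unit diagonal.
#' @slot assignments sample-by-k integer matrix of cluster labels.
#' @slot kRange integer vector of evaluated cluster numbers.
#' @slot chosenK the k minimizing the proportion of ambiguous clustering.
#' @slot nResamples number of subsampling iterations.
#' @slot subsampleFrac fraction of samples drawn per iteration.
#' @slot dispersion data.frame per k: mean within-cluster consensus, mean
#'   between-cluster consensus, and PAC (proportion of ambiguous clustering).
#' @aliases ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(consensus = "list", assignments = "matrix",
                 kRange = "integer", chosenK = "integer",
                 nResamples = "integer", subsampleFrac = "numeric",
                 dispersion = "data.frame")
)

setValidity("ConsensusResult", function(object) {
  msgs <- character()
  for (cm in object@consensus) {
    if (any(cm < -1e-12 | cm > 1 + 1e-12, na.rm = TRUE))
      msgs <- c(msgs, "consensus entries must lie in [0, 1]")
    if (max(abs(cm - t(cm))) > 1e-12)
      msgs <- c(msgs, "consensus matrix must be symmetric")
    if (max(abs(diag(cm) - 1)) > 1e-12)
      msgs <- c(msgs, "consensus diagonal must be 1")
  }
  if (length(msgs)) unique(msgs) else TRUE
})

#' DoseResponseFit: four-parameter logistic fit
#'
#' Parameters of the 4PL model
#' \eqn{y = bottom + (top - bottom) / (1 + (x / IC50)^{hill})} fitted by
#' least squares, canonicalized so that \code{top >= bottom}. The reported
#' IC50 is the curve midpoint parameter (relative EC50 convention).
#'
#' @slot bottom,top asymptotic response levels (response units).
#' @slot hill unitless slope.
#' @slot ic50 midpoint concentration (same units as the fitted
#'   concentrations; > 0).
#' @slot sse residual sum of squares.
#' @slot converged whether the optimizer converged.
#' @slot se named numeric vector of parameter standard errors.
#' @slot cellLine identifier of the measured cell line.
#' @aliases DoseResponseFit-class
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  representation(bottom = "numeric", top = "numeric", hill = "numeric",
                 ic50 = "numeric", sse = "numeric", converged = "logical",
                 se = "numeric", cellLine = "character")
)

setValidity("DoseResponseFit", function(object) {
  msgs <- character()
  if (object@converged && !is.na(object@ic50) && object@ic50 <= 0)
    msgs <- c(msgs, "ic50 must be positive")
  if (object@converged && object@top < object@bottom)
    msgs <- c(msgs, "top must be >= bottom after canonicalization")
  if (length(msgs)) msgs else TRUE
})
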