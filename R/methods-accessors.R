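#' @rdname OmicsMatrix
#' @export
setMethod("assayKind", "OmicsMatrix", function(x) x@assayKind)

#' @rdname OmicsMatrix
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) rownames(x))

#' @rdname OmicsMatrix
#' @export
setMethod("sampleIds", "OmicsMatrix", function(x) colnames(x))

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix (%s): %d features x %d samples\n",
              object@assayKind, nrow(object), ncol(object)))
  v <- assay(object)
  cat(sprintf("  missing: %.1f%%; colData columns: %s\n",
              100 * mean(is.na(v)),
              if (ncol(colData(object))) paste(colnames(colData(object)), collapse = ", ")
              else "<none>"))
})

#' @rdname GeneSetCollection
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection
#' @export
setMethod("setIds", "GeneSetCollection", function(x) base::names(x@sets))

#' @rdname GeneSetCollection
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection
#' @param i set id or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat(sprintf("GeneSetCollection: %d sets (sizes %s..%s)\n", length(object@sets),
              if (length(sz)) min(sz) else 0, if (length(sz)) max(sz) else 0))
})

#' @rdname OntologyDAG
#' @export
setMethod("termIds", "OntologyDAG", function(x) x@terms$id)

#' @rdname OntologyDAG
#' @export
setMethod("termIC", "OntologyDAG", function(x) x@ic)

#' @rdname OntologyDAG
#' @export
setMethod("termAnnotations", "OntologyDAG", function(x) x@annotations)

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d terms, %d is_a edges, namespaces: %s\n",
              nrow(object@terms), sum(lengths(object@parents)),
              paste(unique(object@terms$namespace), collapse = ", ")))
})

#' Ancestors of an ontology term
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param term a term id.
#' @param includeSelf include the term itself (default TRUE).
#' @return character vector of ancestor term ids.
#' @export
termAncestors <- function(dag, term, includeSelf = TRUE) {
  if (!term %in% dag@terms$id) stop("unknown term: ", term)
  out <- character()
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(dag@parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  if (includeSelf) unique(c(term, out)) else out
}

setMethod("show", "BatchModel", function(object) {
  cat(sprintf("BatchModel (%s%s): %d features x %d batches\n",
              object@mode, if (object@referenceOnly) ", reference-anchored" else "",
              nrow(object@gamma), length(object@batches)))
})

#' @rdname ConsensusResult
#' @param k cluster number; defaults to the chosen k.
#' @param ... unused.
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x, k = chosenK(x), ...) {
  x@consensus[[as.character(k)]]
})

#' @rdname ConsensusResult
#' @export
setMethod("clusterAssignments", "ConsensusResult", function(x, k = chosenK(x), ...) {
  setNames(x@assignments[, as.character(k)], rownames(x@assignments))
})

#' @rdname ConsensusResult
#' @export
setMethod("chosenK", "ConsensusResult", function(x) x@chosenK)

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d samples, k in {%s}, chosen k = %d (%d resamples, frac %.2f)\n",
              nrow(object@assignments), paste(object@kRange, collapse = ","),
              object@chosenK, object@nResamples, object@subsampleFrac))
})

#' @rdname DoseResponseFit
#' @export
setMethod("ic50", "DoseResponseFit", function(x) x@ic50)

#' @rdname DoseResponseFit
#' @param object a DoseResponseFit.
#' @export
setMethod("coef", "DoseResponseFit", function(object) {
  c(bottom = object@bottom, top = object@top,
    hill = object@hill, ic50 = object@ic50)
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf("DoseResponseFit [%s]: bottom=%.4g top=%.4g hill=%.4g ic50=%.4g (SSE %.4g%s)\n",
              object@cellLine, object@bottom, object@top, object@hill,
              object@ic50, object@sse,
              if (object@converged) "" else ", NOT converged"))
})
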