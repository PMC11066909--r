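#' @importFrom SummarizedExperiment assays assay<-
NULL

#' @rdname OmicsMatrix
#' @param x an object.
#' @export
setGeneric("assayKind", function(x) standardGeneric("assayKind"))

#' @rdname OmicsMatrix
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname OmicsMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GeneSetCollection
#' @param x an object.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @rdname OntologyDAG
#' @param x an object.
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname OntologyDAG
#' @export
setGeneric("termIC", function(x) standardGeneric("termIC"))

#' @rdname OntologyDAG
#' @export
setGeneric("termAnnotations", function(x) standardGeneric("termAnnotations"))

#' Per-sample normalization generics
#'
#' \code{medianCenter} shifts every sample (column) so that its median over
#' non-missing values is 0. \code{medianMadStandardize} additionally scales
#' every sample to a median absolute deviation of 1. Both operate on the log2
#' scale and are idempotent.
#'
#' @param x a numeric matrix or an \linkS4class{OmicsMatrix}.
#' @return an object of the same class as \code{x}.
#' @name normalization
NULL

#' @rdname normalization
#' @export
setGeneric("medianCenter", function(x) standardGeneric("medianCenter"))

#' @rdname normalization
#' @export
setGeneric("medianMadStandardize", function(x) standardGeneric("medianMadStandardize"))

#' @rdname ConsensusResult
#' @param x an object.
#' @export
setGeneric("consensusMatrix", function(x, ...) standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult
#' @export
setGeneric("clusterAssignments", function(x, ...) standardGeneric("clusterAssignments"))

#' @rdname ConsensusResult
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname DoseResponseFit
#' @param x an object.
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))
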