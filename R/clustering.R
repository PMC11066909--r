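#' @importFrom stats hclust cutree dist as.dist
NULL

#' Select the most variant features
#'
#' Picks the \code{n} features with the largest sample variance (missing
#' values ignored), ties broken by feature id, as used to drive proteome
#' consensus clustering.
#'
#' @param x an \linkS4class{OmicsMatrix} or numeric matrix.
#' @param n number of features (default 1000); values above the feature
#'   count return everything with a warning.
#' @return character vector of selected feature ids (in decreasing variance
#'   order).
#' @export
selectTopVariant <- function(x, n = 1000L) {
  v <- if (is(x, "OmicsMatrix")) assay(x) else as.matrix(x)
  if (n > nrow(v)) {
    warning("n (", n, ") exceeds the feature count (", nrow(v),
            "); returning all features")
    n <- nrow(v)
  }
  vars <- apply(v, 1L, var, na.rm = TRUE)
  vars[is.na(vars)] <- -Inf
  ord <- order(-vars, rownames(v))
  rownames(v)[ord][seq_len(n)]
}

.sampleMatrixImputed <- function(x) {
  v <- if (is(x, "OmicsMatrix")) assay(x) else as.matrix(x)
  if (anyNA(v)) {
    med <- apply(v, 1L, median, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[is.na(v)] <- med[idx[, 1L]]
  }
  t(v)    # samples x features
}

#' Ward.D2 hierarchical clustering of samples
#'
#' Agglomerative clustering with the Ward criterion on squared Euclidean
#' distances (\code{stats::hclust}, method \code{"ward.D2"}), cut to
#' \code{k} clusters. Missing values are imputed by the feature median
#' before the distance computation.
#'
#' @param x an \linkS4class{OmicsMatrix} (features x samples) or numeric
#'   matrix.
#' @param k number of clusters (1 <= k <= number of samples).
#' @return named integer vector of cluster labels.
#' @export
wardD2Cluster <- function(x, k) {
  sm <- .sampleMatrixImputed(x)
  if (k < 1L || k > nrow(sm))
    stop("k must lie between 1 and the sample count (", nrow(sm), ")")
  hc <- hclust(dist(sm, method = "euclidean"), method = "ward.D2")
  cutree(hc, k = k)
}

#' Consensus clustering by subsampling
#'
#' Monti-style consensus clustering: in each of \code{nResamples}
#' iterations a fraction of the samples is drawn without replacement and
#' clustered by Ward.D2 on Euclidean distances; the consensus index of a
#' sample pair is the number of times it was co-clustered divided by the
#' number of times it was co-sampled. The final partition for each k cuts a
#' Ward.D2 tree on 1 - consensus as distance. The reported k minimizes the
#' proportion of ambiguous clustering (PAC: the fraction of off-diagonal
#' consensus entries strictly between 0.1 and 0.9).
#'
#' @param x an \linkS4class{OmicsMatrix} or numeric matrix (features x
#'   samples).
#' @param kRange integer vector of cluster numbers within
#'   [2, samples - 1].
#' @param nResamples number of subsampling iterations (default 1000).
#' @param subsampleFrac fraction of samples per iteration (default 0.8).
#' @param seed integer seed (required).
#' @return a \linkS4class{ConsensusResult}.
#' @export
consensusCluster <- function(x, kRange = 2:5, nResamples = 1000L,
                             subsampleFrac = 0.8, seed) {
  if (missing(seed)) stop("a seed is required for the resampling")
  sm <- .sampleMatrixImputed(x)
  ns <- nrow(sm)
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2L) || any(kRange > ns - 1L))
    stop("kRange must lie within [2, ", ns - 1L, "]")
  nSub <- max(2L, round(subsampleFrac * ns))
  coCount <- matrix(0, ns, ns)
  coCluster <- setNames(lapply(kRange, function(k) matrix(0, ns, ns)),
                        as.character(kRange))
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nResamples)) {
      idx <- sort.int(sample.int(ns, nSub))
      coCount[idx, idx] <- coCount[idx, idx] + 1
      hc <- hclust(dist(sm[idx, , drop = FALSE]), method = "ward.D2")
      for (k in kRange) {
        lab <- cutree(hc, k = k)
        same <- outer(lab, lab, "==")
        km <- as.character(k)
        coCluster[[km]][idx, idx] <- coCluster[[km]][idx, idx] + same
      }
    }
  })
  if (any(coCount[upper.tri(coCount)] == 0))
    stop("some sample pair was never co-sampled; increase nResamples")
  consensus <- lapply(coCluster, function(cc) {
    cm <- cc / coCount
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(sm), rownames(sm))
    cm
  })
  assignments <- vapply(as.character(kRange), function(km) {
    hc <- hclust(as.dist(1 - consensus[[km]]), method = "ward.D2")
    cutree(hc, k = as.integer(km))
  }, integer(ns))
  rownames(assignments) <- rownames(sm)
  disp <- do.call(rbind, lapply(as.character(kRange), function(km) {
    cm <- consensus[[km]]
    lab <- assignments[, km]
    within <- outer(lab, lab, "==") & upper.tri(cm)
    between <- outer(lab, lab, "!=") & upper.tri(cm)
    off <- cm[upper.tri(cm)]
    data.frame(k = as.integer(km),
               mean_within = mean(cm[within]),
               mean_between = if (any(between)) mean(cm[between]) else NA_real_,
               pac = mean(off > 0.1 & off < 0.9))
  }))
  chosen <- disp$k[order(disp$pac, disp$k)][1L]
  new("ConsensusResult", consensus = consensus, assignments = assignments,
      kRange = kRange, chosenK = as.integer(chosen),
      nResamples = as.integer(nResamples),
      subsampleFrac = subsampleFrac, dispersion = disp)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (1 for identical
#' partitions up to relabeling, about 0 under independence); delegates to
#' \code{mclust::adjustedRandIndex}.
#'
#' @param labelsA,labelsB cluster label vectors of equal length.
#' @return numeric ARI.
#' @export
adjustedRandIndex <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have equal length")
  mclust::adjustedRandIndex(labelsA, labelsB)
}
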