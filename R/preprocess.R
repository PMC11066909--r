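#' @importFrom stats median mad var
NULL

.colMedians <- function(v) apply(v, 2L, median, na.rm = TRUE)

#' @rdname normalization
#' @export
setMethod("medianCenter", "matrix", function(x) {
  nOk <- colSums(!is.na(x))
  if (any(nOk == 0L))
    stop("sample(s) with all values missing: ",
         paste(colnames(x)[nOk == 0L], collapse = ", "))
  sweep(x, 2L, .colMedians(x), "-")
})

#' @rdname normalization
#' @export
setMethod("medianCenter", "OmicsMatrix", function(x) {
  assay(x) <- medianCenter(assay(x))
  x
})

#' @rdname normalization
#' @export
setMethod("medianMadStandardize", "matrix", function(x) {
  ctr <- medianCenter(x)
  mads <- apply(ctr, 2L, mad, constant = 1, na.rm = TRUE)
  if (any(mads == 0))
    stop("sample(s) with zero median absolute deviation: ",
         paste(colnames(x)[mads == 0], collapse = ", "))
  sweep(ctr, 2L, mads, "/")
})

#' @rdname normalization
#' @export
setMethod("medianMadStandardize", "OmicsMatrix", function(x) {
  assay(x) <- medianMadStandardize(assay(x))
  x
})

# ---- parametric empirical-Bayes location/scale batch model ----------------
#
# Standardization and per-batch moments use unbiased denominators (N - B for
# the pooled residual variance, n_b - 1 within batch), so that two identical
# batches yield gamma_hat = 0 and delta2_hat = 1 exactly and the adjustment
# reduces to the identity. Hyperpriors: normal for gamma (moments gamma_bar,
# t2 across features), inverse-gamma for delta2 (method-of-moments a, b).
# Posterior solved by the usual fixed-point iteration; degenerate priors
# (t2 or the delta2 spread numerically zero) collapse to the prior mean.

.ebFixedPoint <- function(gammaHat, delta2Hat, zc, nb, gammaBar, t2, aPrior, bPrior,
                          tol = 1e-10, maxIter = 200L) {
  gOld <- gammaHat
  dOld <- delta2Hat
  degenerateDelta <- !is.finite(aPrior) || !is.finite(bPrior)
  m <- mean(delta2Hat)
  for (i in seq_len(maxIter)) {
    gNew <- (nb * t2 * gammaHat + dOld * gammaBar) / (nb * t2 + dOld)
    sum2 <- rowSums((zc - gNew)^2)
    dNew <- if (degenerateDelta) rep(m, length(dOld))
            else (0.5 * sum2 + bPrior) / (nb / 2 + aPrior - 1)
    change <- max(abs(gNew - gOld) / pmax(abs(gOld), 1e-12),
                  abs(dNew - dOld) / pmax(abs(dOld), 1e-12))
    gOld <- gNew; dOld <- dNew
    if (change < tol) break
  }
  list(gamma = gOld, delta2 = dOld)
}

# Fit the EB model on `estimateOn` columns only (all columns for plain
# ComBat-style adjustment; reference columns only for reference-anchored
# integration). X must be complete (impute before calling).
.ebBatchFit <- function(X, batch, estimateOn, referenceOnly = FALSE) {
  batch <- as.factor(batch)
  lv <- levels(batch)
  est <- estimateOn
  nb <- vapply(lv, function(b) sum(batch[est] == b), 1L)
  if (any(nb < 2L))
    stop("batch(es) with fewer than 2 estimation samples: ",
         paste(lv[nb < 2L], collapse = ", "))
  N <- sum(nb); B <- length(lv)
  batchMean <- vapply(lv, function(b) rowMeans(X[, est[batch[est] == b], drop = FALSE]),
                      numeric(nrow(X)))
  if (nrow(X) == 1L) batchMean <- matrix(batchMean, nrow = 1L, dimnames = list(rownames(X), lv))
  grand <- as.vector(batchMean %*% (nb / N))
  resid2 <- 0
  for (b in lv)
    resid2 <- resid2 + rowSums((X[, est[batch[est] == b], drop = FALSE] - batchMean[, b])^2)
  pooledVar <- resid2 / (N - B)
  ok <- pooledVar > 1e-24
  gamma <- matrix(0, nrow(X), B, dimnames = list(rownames(X), lv))
  delta2 <- matrix(1, nrow(X), B, dimnames = list(rownames(X), lv))
  for (b in lv) {
    cols <- est[batch[est] == b]
    Z <- (X[ok, cols, drop = FALSE] - grand[ok]) / sqrt(pooledVar[ok])
    gHat <- rowMeans(Z)
    dHat <- apply(Z, 1L, var)
    gammaBar <- mean(gHat)
    t2 <- var(gHat)
    if (!is.finite(t2) || t2 < 1e-12) t2 <- 0
    m <- mean(dHat); s2 <- var(dHat)
    if (!is.finite(s2) || s2 < 1e-12) {
      aPrior <- Inf; bPrior <- Inf
    } else {
      aPrior <- (2 * s2 + m^2) / s2
      bPrior <- (m * s2 + m^3) / s2
    }
    sol <- .ebFixedPoint(gHat, dHat, Z, length(cols), gammaBar, t2, aPrior, bPrior)
    gamma[ok, b] <- sol$gamma
    delta2[ok, b] <- pmax(sol$delta2, 1e-12)
  }
  new("BatchModel", gamma = gamma, delta2 = delta2,
      grandMean = setNames(grand, rownames(X)),
      pooledVar = setNames(pooledVar, rownames(X)),
      batches = lv, mode = "parametric_EB", referenceOnly = referenceOnly)
}

.ebBatchApply <- function(X, batch, model) {
  batch <- as.factor(batch)
  out <- X
  ok <- model@pooledVar > 1e-24
  for (b in model@batches) {
    cols <- which(batch == b)
    if (!length(cols)) next
    Z <- (X[ok, cols, drop = FALSE] - model@grandMean[ok]) / sqrt(model@pooledVar[ok])
    Zadj <- (Z - model@gamma[ok, b]) / sqrt(model@delta2[ok, b])
    out[ok, cols] <- Zadj * sqrt(model@pooledVar[ok]) + model@grandMean[ok]
  }
  out
}

.imputeFeatureMean <- function(v) {
  miss <- is.na(v)
  if (!any(miss)) return(list(values = v, mask = miss))
  fill <- rowMeans(v, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  v[miss] <- fill[idx[, 1L]]
  list(values = v, mask = miss)
}

#' Empirical-Bayes batch adjustment
#'
#' Location/scale batch correction in the parametric empirical-Bayes scheme:
#' features are standardized against the batch-free grand mean and pooled
#' residual variance, per-batch location (gamma) and scale (delta^2)
#' parameters are shrunk toward across-feature hyperpriors (normal and
#' inverse-gamma, method-of-moments), and the adjusted values are restored to
#' the original scale. No covariate design is fitted. A single batch returns
#' the input unchanged; features with zero overall variance are passed
#' through with a warning. Features with missing values are mean-imputed for
#' estimation and re-masked afterwards.
#'
#' @param x an \linkS4class{OmicsMatrix} or numeric matrix.
#' @param batch batch label per sample; defaults to the \code{batch} column
#'   of \code{colData(x)}.
#' @return list with elements \code{corrected} (same class as \code{x}) and
#'   \code{model} (a \linkS4class{BatchModel}, or NULL for a single batch).
#' @export
combatAdjust <- function(x, batch = NULL) {
  v <- if (is(x, "OmicsMatrix")) assay(x) else as.matrix(x)
  if (is.null(batch)) {
    if (!is(x, "OmicsMatrix") || !"batch" %in% colnames(colData(x)))
      stop("no batch labels: supply `batch` or a colData 'batch' column")
    batch <- as.character(colData(x)$batch)
  }
  if (length(batch) != ncol(v)) stop("batch length must equal the sample count")
  batch <- as.factor(as.character(batch))
  if (nlevels(batch) < 2L) {
    message("single batch: no adjustment performed")
    return(list(corrected = x, model = NULL))
  }
  if (any(table(batch) < 2L))
    stop("batch(es) of size 1: ",
         paste(names(which(table(batch) < 2L)), collapse = ", "))
  imp <- .imputeFeatureMean(v)
  vi <- imp$values
  zeroVar <- apply(vi, 1L, var) <= 1e-24
  if (any(zeroVar))
    warning(sum(zeroVar), " zero-variance feature(s) passed through unadjusted")
  model <- .ebBatchFit(vi, batch, seq_len(ncol(vi)))
  adj <- .ebBatchApply(vi, batch, model)
  adj[zeroVar, ] <- v[zeroVar, ]
  adj[imp$mask] <- NA_real_
  if (is(x, "OmicsMatrix")) { assay(x) <- adj; list(corrected = x, model = model) }
  else list(corrected = adj, model = model)
}

#' Reference-anchored integration of two cohorts
#'
#' Harmonizes two cohorts measured in different laboratories/platforms by
#' estimating empirical-Bayes batch parameters (cohort as batch) on shared
#' reference samples only, then applying the adjustment to every sample of
#' each cohort. The merged matrix covers the intersected feature space and
#' excludes the reference samples, which serve purely as anchors.
#'
#' @param cohortA,cohortB \linkS4class{OmicsMatrix} objects whose
#'   \code{colData} carries an \code{is_reference} column (or pass
#'   \code{referenceIdsA}/\code{referenceIdsB}).
#' @param referenceIdsA,referenceIdsB optional explicit reference sample ids
#'   per cohort (>= 2 each).
#' @return an \linkS4class{OmicsMatrix} of all non-reference samples with a
#'   \code{cohort} column added to \code{colData}, plus the fitted
#'   \linkS4class{BatchModel} in \code{metadata(x)$batchModel}.
#' @export
coconutIntegrate <- function(cohortA, cohortB,
                             referenceIdsA = NULL, referenceIdsB = NULL) {
  getRefs <- function(m, ids, label) {
    if (!is.null(ids)) return(intersect(ids, colnames(m)))
    cd <- colData(m)
    if (!"is_reference" %in% colnames(cd))
      stop("cohort ", label, ": no is_reference annotation and no explicit reference ids")
    colnames(m)[as.logical(cd$is_reference)]
  }
  refsA <- getRefs(cohortA, referenceIdsA, "A")
  refsB <- getRefs(cohortB, referenceIdsB, "B")
  if (!length(refsA) || !length(refsB))
    stop("no shared reference samples between the cohorts")
  if (length(refsA) < 2L || length(refsB) < 2L)
    stop("each cohort needs at least 2 reference samples (found ",
         length(refsA), " and ", length(refsB), ")")
  feats <- intersect(rownames(cohortA), rownames(cohortB))
  if (!length(feats)) stop("the cohorts share no features")
  vA <- assay(cohortA)[feats, , drop = FALSE]
  vB <- assay(cohortB)[feats, , drop = FALSE]
  dup <- intersect(setdiff(colnames(vA), refsA), setdiff(colnames(vB), refsB))
  if (length(dup))
    stop("non-reference sample id(s) present in both cohorts: ",
         paste(dup, collapse = ", "))
  ids <- c(colnames(vA), colnames(vB))
  X <- cbind(vA, vB)
  colnames(X) <- make.unique(ids)
  cohort <- rep(c("A", "B"), c(ncol(vA), ncol(vB)))
  isRef <- seq_len(ncol(X)) %in% c(match(refsA, colnames(vA)),
                                   ncol(vA) + match(refsB, colnames(vB)))
  imp <- .imputeFeatureMean(X)
  model <- .ebBatchFit(imp$values, cohort, which(isRef), referenceOnly = TRUE)
  adj <- .ebBatchApply(imp$values, cohort, model)
  adj[imp$mask] <- NA_real_
  keep <- !isRef
  out <- adj[, keep, drop = FALSE]
  cdA <- as.data.frame(colData(cohortA))[colnames(vA), , drop = FALSE]
  cdB <- as.data.frame(colData(cohortB))[colnames(vB), , drop = FALSE]
  commonCols <- intersect(colnames(cdA), colnames(cdB))
  cd <- rbind(cdA[, commonCols, drop = FALSE], cdB[, commonCols, drop = FALSE])
  cd$cohort <- cohort
  cd <- cd[keep, , drop = FALSE]
  rownames(cd) <- colnames(out)
  res <- OmicsMatrix(out, assayKind(cohortA), sampleInfo = cd)
  S4Vectors::metadata(res)$batchModel <- model
  res
}

#' Filter methylation probes
#'
#' Removes probes flagged as lying on a sex chromosome, overlapping a SNP at
#' the CpG site, or cross-reactive, and probes whose detection p-value is at
#' or above the threshold in any sample (when detection p-values are
#' supplied).
#'
#' @param methylome a methylome \linkS4class{OmicsMatrix}.
#' @param cpgAnnotation data.frame as from \code{\link{readCpgAnnotation}};
#'   must cover every probe in the matrix.
#' @param detectionP optional CpG-by-sample matrix of detection p-values.
#' @param detectionPThreshold exclusion threshold; probes with p at or above
#'   it in any sample are dropped (default 0.01).
#' @return the filtered \linkS4class{OmicsMatrix}.
#' @export
filterProbes <- function(methylome, cpgAnnotation, detectionP = NULL,
                         detectionPThreshold = 0.01) {
  probes <- rownames(methylome)
  miss <- setdiff(probes, cpgAnnotation$cpg_id)
  if (length(miss))
    stop("annotation is missing probe(s): ", paste(utils::head(miss, 5), collapse = ", "))
  ann <- cpgAnnotation[match(probes, cpgAnnotation$cpg_id), ]
  keep <- lengths(ann$flags) == 0L
  if (!is.null(detectionP)) {
    dp <- as.matrix(detectionP)
    covered <- intersect(probes, rownames(dp))
    failed <- covered[apply(dp[covered, , drop = FALSE] >= detectionPThreshold, 1L, any)]
    keep <- keep & !(probes %in% failed)
  }
  if (!any(keep)) warning("all probes removed by filtering")
  methylome[keep, ]
}
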