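#' @importFrom stats t.test oneway.test setNames
NULL

#' Welch's two-sample t-test
#'
#' Two-sided Welch test (unequal variances, Welch-Satterthwaite degrees of
#' freedom) via \code{stats::t.test}. When both groups are constant the test
#' is degenerate: the result carries \code{degenerate = TRUE} with p = 1 for
#' equal means and p = 0 (infinite t) otherwise.
#'
#' @param a,b numeric vectors (missing values dropped; >= 2 each).
#' @return list with \code{t}, \code{df}, \code{p}, \code{degenerate}.
#' @export
welchTest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("Welch test needs >= 2 non-missing values per group (got ",
         length(a), " and ", length(b), ")")
  if (var(a) == 0 && var(b) == 0) {
    eq <- mean(a) == mean(b)
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = if (eq) 1 else 0,
                degenerate = TRUE))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), degenerate = FALSE)
}

#' Paired t-test
#'
#' One-sample two-sided t-test on within-pair differences. Pairs with a
#' missing member are dropped. Zero-variance differences are degenerate and
#' return p = 1 with \code{degenerate = TRUE} rather than failing.
#'
#' @param x,y paired numeric vectors of equal length (>= 2 complete pairs).
#' @return list with \code{t}, \code{df}, \code{p}, \code{degenerate}.
#' @export
pairedTest <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  if (length(d) < 2L)
    stop("paired test needs >= 2 complete pairs (got ", length(d), ")")
  if (var(d) == 0)
    return(list(t = 0, df = length(d) - 1, p = 1, degenerate = TRUE))
  ht <- t.test(d)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), degenerate = FALSE)
}

#' Per-feature differential abundance table
#'
#' Runs the chosen test for every feature of a log2-scale matrix, comparing
#' case against control samples. The fold change is the difference of group
#' means on the log2 scale (case minus control), so |fc| > 1 means a two-fold
#' change. For the paired test, \code{caseSamples[i]} is paired with
#' \code{controlSamples[i]}.
#'
#' @param x an \linkS4class{OmicsMatrix} or numeric matrix.
#' @param caseSamples,controlSamples sample ids (or indices) of the two
#'   groups.
#' @param test \code{"welch"} or \code{"paired"}.
#' @return data.frame with columns \code{feature}, \code{fc}, \code{t},
#'   \code{df}, \code{p}, \code{n_case}, \code{n_control}, \code{test},
#'   \code{degenerate}. Features with fewer than 2 usable values per group
#'   get NA statistics.
#' @export
differentialTable <- function(x, caseSamples, controlSamples,
                              test = c("welch", "paired")) {
  test <- match.arg(test)
  v <- if (is(x, "OmicsMatrix")) assay(x) else as.matrix(x)
  a <- v[, caseSamples, drop = FALSE]
  b <- v[, controlSamples, drop = FALSE]
  res <- lapply(seq_len(nrow(v)), function(i) {
    ai <- a[i, ]; bi <- b[i, ]
    fc <- mean(ai, na.rm = TRUE) - mean(bi, na.rm = TRUE)
    ht <- tryCatch(
      if (test == "welch") welchTest(ai, bi) else pairedTest(ai, bi),
      error = function(e) list(t = NA_real_, df = NA_real_, p = NA_real_,
                               degenerate = NA))
    data.frame(fc = fc, t = ht$t, df = ht$df, p = ht$p,
               n_case = sum(!is.na(ai)), n_control = sum(!is.na(bi)),
               degenerate = ht$degenerate)
  })
  out <- do.call(rbind, res)
  out <- cbind(feature = rownames(v), out, test = test)
  rownames(out) <- rownames(v)
  out
}

#' Rank features by one-way ANOVA significance
#'
#' Classic equal-variance one-way ANOVA per feature via
#' \code{stats::oneway.test(var.equal = TRUE)}; features are ordered by
#' ascending p (ties broken by feature id) and the \code{topN} most
#' significant are returned.
#'
#' @param x an \linkS4class{OmicsMatrix} or numeric matrix.
#' @param groups group label per sample (>= 2 groups of >= 2 samples).
#' @param topN number of features to keep; values above the feature count
#'   return everything with a warning.
#' @return data.frame with columns \code{feature}, \code{F}, \code{p},
#'   ordered by significance and trimmed to \code{topN} rows.
#' @export
anovaRankFeatures <- function(x, groups, topN = 1000L) {
  v <- if (is(x, "OmicsMatrix")) assay(x) else as.matrix(x)
  groups <- as.factor(as.character(groups))
  if (length(groups) != ncol(v)) stop("groups length must equal the sample count")
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stop("ANOVA needs >= 2 groups with >= 2 samples each")
  stats <- vapply(seq_len(nrow(v)), function(i) {
    ht <- tryCatch(oneway.test(v[i, ] ~ groups, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ht) || is.na(ht$statistic)) c(0, 1)
    else c(unname(ht$statistic), unname(ht$p.value))
  }, numeric(2))
  out <- data.frame(feature = rownames(v), F = stats[1L, ], p = stats[2L, ])
  out <- out[order(out$p, out$feature), , drop = FALSE]
  if (topN > nrow(out)) {
    warning("topN (", topN, ") exceeds the feature count (", nrow(out),
            "); returning all features")
    topN <- nrow(out)
  }
  rownames(out) <- NULL
  out[seq_len(topN), , drop = FALSE]
}

#' Ranking score: fold change times -log10 p
#'
#' The signed score used to order genes for preranked enrichment:
#' \code{fc * -log10(p)}. A p of exactly 0 is clamped to the smallest
#' representable positive double with a warning.
#'
#' @param fc signed log2 fold change(s).
#' @param p p-value(s) in (0, 1].
#' @return numeric score vector.
#' @examples
#' rankStatistic(1, 0.1)     # 1
#' rankStatistic(2.84, 0.001) # 8.52
#' @export
rankStatistic <- function(fc, p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-value(s) of 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  fc * (-log10(p))
}

#' Combine per-subgroup ranking scores
#'
#' Merges two per-subgroup score maps into a single ranked list. Genes
#' present in only one map are dropped (a message reports how many). With
#' \code{method = "score"} (default) the combined score is the arithmetic
#' mean of the two signed scores; with \code{method = "rank"} it is the
#' negated mean of the two descending rank positions, so that genes ranked
#' high in both subgroups stay on top. Ties are broken by gene id.
#'
#' @param scoresA,scoresB named numeric vectors (gene to score).
#' @param method \code{"score"} or \code{"rank"}.
#' @return named numeric vector sorted in decreasing score order.
#' @export
combineSubgroupRanks <- function(scoresA, scoresB, method = c("score", "rank")) {
  method <- match.arg(method)
  if (!length(scoresA) || !length(scoresB)) stop("both score maps must be non-empty")
  shared <- intersect(names(scoresA), names(scoresB))
  if (!length(shared)) stop("the score maps share no genes")
  dropped <- length(union(names(scoresA), names(scoresB))) - length(shared)
  if (dropped > 0L)
    message(dropped, " gene(s) present in only one subgroup dropped")
  combined <- if (method == "score") {
    (scoresA[shared] + scoresB[shared]) / 2
  } else {
    rA <- rank(-scoresA, ties.method = "average")[shared]
    rB <- rank(-scoresB, ties.method = "average")[shared]
    -(rA + rB) / 2
  }
  combined[order(-combined, shared)]
}

#' Histomorphology-independent feature selection
#'
#' Selects features that pass both the fold-change and significance
#' thresholds in each of two subgroup-stratified differential tables
#' (|fc| > fcThreshold and p <= pThreshold in both) with concordant fold
#' change sign; the shared sign is reported as the direction.
#'
#' @param diffA,diffB data.frames from \code{\link{differentialTable}} over a
#'   shared feature space.
#' @param fcThreshold absolute log2 fold change that must be exceeded
#'   (default 1, i.e. two-fold).
#' @param pThreshold largest admissible p (default 0.05, inclusive).
#' @return data.frame with columns \code{feature}, \code{direction}
#'   ("up"/"down"), \code{fc_a}, \code{fc_b}, \code{p_a}, \code{p_b}, ordered
#'   by feature id.
#' @export
morphologyIndependentSelection <- function(diffA, diffB,
                                           fcThreshold = 1, pThreshold = 0.05) {
  shared <- intersect(diffA$feature, diffB$feature)
  ia <- match(shared, diffA$feature)
  ib <- match(shared, diffB$feature)
  hitA <- abs(diffA$fc[ia]) > fcThreshold & diffA$p[ia] <= pThreshold
  hitB <- abs(diffB$fc[ib]) > fcThreshold & diffB$p[ib] <= pThreshold
  concord <- sign(diffA$fc[ia]) == sign(diffB$fc[ib])
  sel <- which(hitA & hitB & concord & !is.na(hitA) & !is.na(hitB))
  out <- data.frame(
    feature = shared[sel],
    direction = ifelse(diffA$fc[ia[sel]] > 0, "up", "down"),
    fc_a = diffA$fc[ia[sel]], fc_b = diffB$fc[ib[sel]],
    p_a = diffA$p[ia[sel]], p_b = diffB$p[ib[sel]])
  out[order(out$feature), , drop = FALSE]
}
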