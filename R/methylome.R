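#' @importFrom stats cor pt complete.cases
NULL

#' Promoter CpG / measured-protein pairs
#'
#' Pairs every promoter-associated CpG (region TSS200, TSS1500 or 5'UTR)
#' with its gene, restricted to genes measured in the proteome.
#'
#' @param cpgAnnotation data.frame as from \code{\link{readCpgAnnotation}}.
#' @param proteomeFeatures character vector of measured protein gene
#'   symbols.
#' @return data.frame with columns \code{cpg}, \code{gene}, \code{region}.
#' @export
promoterPairs <- function(cpgAnnotation, proteomeFeatures) {
  keep <- cpgAnnotation$region %in% c("TSS200", "TSS1500", "UTR5") &
    cpgAnnotation$gene %in% proteomeFeatures
  data.frame(cpg = cpgAnnotation$cpg_id[keep],
             gene = cpgAnnotation$gene[keep],
             region = cpgAnnotation$region[keep],
             row.names = NULL)
}

# all permutations of seq_len(n) as an n! x n matrix (cached per session)
.permCache <- new.env(parent = emptyenv())
.allPermutations <- function(n) {
  key <- as.character(n)
  hit <- get0(key, envir = .permCache)
  if (!is.null(hit)) return(hit)
  perm <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perm(v[-i]))))
  }
  out <- perm(seq_len(n))
  assign(key, out, envir = .permCache)
  out
}

#' Spearman correlation with small-sample exact permutation p
#'
#' Rank correlation on average ranks (ties averaged). The two-sided p-value
#' uses the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} for
#' n >= 10 and the exact permutation null (all n! orderings of one vector's
#' ranks) for n < 10, where the approximation is unreliable at case-series
#' scale. Constant vectors leave the correlation undefined; a flagged null
#' result is returned instead of an error.
#'
#' @param x,y numeric vectors of equal length; incomplete pairs are dropped
#'   (>= 4 complete pairs required).
#' @return list with \code{rho}, \code{p}, \code{n}, \code{method}
#'   ("exact" or "t_approx"), \code{degenerate}.
#' @export
spearmanCorrelate <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("Spearman correlation needs >= 4 complete pairs (got ", n, ")")
  if (var(x) == 0 || var(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "none",
                degenerate = TRUE))
  rho <- cor(x, y, method = "spearman")
  if (n >= 10L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
    return(list(rho = rho, p = min(p, 1), n = n, method = "t_approx",
                degenerate = FALSE))
  }
  rx <- rank(x); ry <- rank(y)
  rx0 <- rx - mean(rx); ry0 <- ry - mean(ry)
  denom <- sqrt(sum(rx0^2) * sum(ry0^2))
  perms <- .allPermutations(n)
  # rho under each permutation of y's ranks against the fixed x ranks
  rhos <- as.vector(matrix(ry0[perms], nrow(perms)) %*% rx0) / denom
  p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  list(rho = rho, p = p, n = n, method = "exact", degenerate = FALSE)
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up FDR control valid under arbitrary dependence:
#' \eqn{p_{(i)} m c(m) / i} with \eqn{c(m)=\sum_{j=1}^m 1/j}, made monotone
#' and capped at 1 (delegates to \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
byAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BY")
}

#' Promoter methylation / protein abundance correlation table
#'
#' Computes the sample-wise Spearman correlation between each promoter CpG's
#' beta values and its gene's protein abundance across the shared samples,
#' and applies BY adjustment jointly over all tested pairs (the conservative
#' family).
#'
#' @param methylome a methylome \linkS4class{OmicsMatrix}.
#' @param proteome a proteome \linkS4class{OmicsMatrix}.
#' @param cpgAnnotation data.frame as from \code{\link{readCpgAnnotation}}.
#' @param samples optional sample ids restricting the correlation (default:
#'   all samples shared by the two matrices).
#' @return data.frame with columns \code{cpg}, \code{gene}, \code{region},
#'   \code{rho}, \code{n}, \code{pval}, \code{padj} (BY), \code{method}.
#'   Degenerate pairs (constant vectors) carry NA statistics and are
#'   excluded from the adjustment family.
#' @export
promoterCorrelation <- function(methylome, proteome, cpgAnnotation,
                                samples = NULL) {
  shared <- intersect(colnames(methylome), colnames(proteome))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 4L)
    stop("fewer than 4 shared samples between methylome and proteome")
  pairs <- promoterPairs(cpgAnnotation, rownames(proteome))
  pairs <- pairs[pairs$cpg %in% rownames(methylome), , drop = FALSE]
  if (!nrow(pairs)) {
    warning("no promoter CpG/protein pairs to test")
    return(data.frame(cpg = character(), gene = character(),
                      region = character(), rho = numeric(), n = integer(),
                      pval = numeric(), padj = numeric(), method = character()))
  }
  beta <- assay(methylome)[pairs$cpg, shared, drop = FALSE]
  prot <- assay(proteome)[pairs$gene, shared, drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ct <- tryCatch(spearmanCorrelate(beta[i, ], prot[i, ]),
                   error = function(e) list(rho = NA_real_, p = NA_real_,
                                            n = NA_integer_, method = "none"))
    data.frame(cpg = pairs$cpg[i], gene = pairs$gene[i],
               region = pairs$region[i], rho = ct$rho, n = ct$n,
               pval = ct$p, method = ct$method)
  })
  out <- do.call(rbind, res)
  out$padj <- NA_real_
  tested <- !is.na(out$pval)
  out$padj[tested] <- byAdjust(out$pval[tested])
  out[, c("cpg", "gene", "region", "rho", "n", "pval", "padj", "method")]
}

#' Genes with significant promoter-methylation correlation
#'
#' A gene qualifies when at least one of its promoter-associated CpGs has a
#' BY-adjusted p at or below \code{alpha} (inclusive boundary).
#'
#' @param corr data.frame from \code{\link{promoterCorrelation}}.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return sorted character vector of gene symbols.
#' @export
significantGenes <- function(corr, alpha = 0.05) {
  sig <- !is.na(corr$padj) & corr$padj <= alpha
  sort(unique(corr$gene[sig]))
}

#' Over-representation of methylation-correlated proteins
#'
#' Tests gene sets for enrichment of methylation-correlated proteins within
#' the universe of significantly differentially abundant proteins. The
#' over-representation call follows the count rule: at least 2 AND strictly
#' more than 10 percent of the set's within-universe members must correlate
#' significantly. The hypergeometric tail p is computed and reported for
#' transparency but does not drive the call.
#'
#' @param sigGenes methylation-correlated genes (subset of
#'   \code{universe}).
#' @param universe significantly differential proteins.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param minSize,maxSize admitted within-universe set sizes (defaults 5,
#'   150).
#' @param minCount minimum correlated members (default 2).
#' @param minFraction fraction of within-universe members that must be
#'   exceeded (default 0.10, strict).
#' @return data.frame as in \code{\link{oraHypergeometric}} plus a
#'   \code{fraction} column; \code{over_represented} applies the count rule.
#' @export
methylationOra <- function(sigGenes, universe, sets, minSize = 5L,
                           maxSize = 150L, minCount = 2L,
                           minFraction = 0.10) {
  res <- oraHypergeometric(sigGenes, universe, sets, minSize = minSize,
                           maxSize = maxSize)
  res$fraction <- res$k / res$K
  res$over_represented <- res$k >= minCount & res$fraction > minFraction
  res
}

#' Three-way overlap of enriched term sets
#'
#' Partitions term ids enriched in the proteome, transcriptome and methylome
#' analyses into the seven regions of a three-set Venn diagram.
#'
#' @param proteomeTerms,transcriptomeTerms,methylomeTerms character vectors
#'   of term ids.
#' @return list with \code{counts} (named integer vector over the seven
#'   regions) and \code{members} (the corresponding term ids).
#' @export
triomicsOverlap <- function(proteomeTerms, transcriptomeTerms, methylomeTerms) {
  p <- unique(as.character(proteomeTerms))
  t <- unique(as.character(transcriptomeTerms))
  m <- unique(as.character(methylomeTerms))
  members <- list(
    proteome_only = setdiff(p, union(t, m)),
    transcriptome_only = setdiff(t, union(p, m)),
    methylome_only = setdiff(m, union(p, t)),
    proteome_transcriptome = setdiff(intersect(p, t), m),
    proteome_methylome = setdiff(intersect(p, m), t),
    transcriptome_methylome = setdiff(intersect(t, m), p),
    all_three = intersect(intersect(p, t), m))
  members <- lapply(members, sort)
  list(counts = vapply(members, length, 1L), members = members)
}
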