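#' @importFrom stats p.adjust phyper
NULL

# Sort a named score vector into the deterministic ranking order:
# decreasing score, ties broken by gene id.
.prepareRanked <- function(ranked) {
  if (is.data.frame(ranked)) ranked <- setNames(ranked$score, ranked$gene)
  if (is.null(names(ranked)) || anyDuplicated(names(ranked)))
    stop("ranked list needs unique gene names")
  ranked[order(-ranked, names(ranked))]
}

# Weighted-KS enrichment score from the sorted hit positions alone.
# Hits increment the running sum by |score|^weight (normalized to the in-set
# total), misses decrement by 1/(N-K); the extrema of the running sum occur
# adjacent to hits, so O(K) candidates suffice.
.esFromPositions <- function(pos, wAll, N) {
  K <- length(pos)
  w <- wAll[pos]
  NR <- sum(w)
  pHit <- if (NR > 0) cumsum(w) / NR else seq_len(K) / K
  missRate <- if (N > K) 1 / (N - K) else 0
  missBefore <- (pos - seq_len(K)) * missRate
  peak <- pHit - missBefore
  trough <- c(0, pHit[-K]) - missBefore
  # extremum with the larger magnitude wins; an exact tie goes positive
  maxDev <- max(peak)
  minDev <- min(trough, 0)
  es <- if (maxDev >= -minDev - 1e-12) maxDev else minDev
  leadIdx <- if (es >= 0) {
    i <- which.max(peak)
    seq_len(i)
  } else {
    i <- which.min(trough)
    seq(i, K)
  }
  list(es = es, leadIdx = leadIdx)
}

.nullEs <- function(K, wAll, N, nPerm) {
  vapply(seq_len(nPerm), function(i) {
    pos <- sort.int(sample.int(N, K))
    .esFromPositions(pos, wAll, N)$es
  }, numeric(1))
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment of gene sets in a signed-score
#' ranked list. The running sum gains \code{|score|^weight} (normalized to
#' the in-set total) at set members and loses \code{1/(N-K)} elsewhere; the
#' enrichment score ES is the maximum deviation from zero. The null is
#' generated by permuting gene-set membership (uniform draws of K of the N
#' ranked genes) under a fixed seed. NES divides ES by the mean magnitude of
#' same-sign null scores, and the nominal p is the same-sign permutation tail
#' with a +1 pseudocount. BH adjustment is applied across the retained sets
#' of this call. Sets are filtered to \code{[minSize, maxSize]} members after
#' intersection with the ranked genes; skipped sets are reported via
#' \code{message}.
#'
#' @param ranked named numeric score vector (or a data.frame with columns
#'   \code{gene}, \code{score}); sorted internally in decreasing order with
#'   ties broken by gene id.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param minSize,maxSize admitted set size range within the ranked genes
#'   (defaults 10 and 250; use 600 for transcriptome-wide collections).
#' @param weight exponent on |score| for hit increments (1 = standard
#'   weighted statistic; 0 = classic unweighted KS).
#' @param nPerm number of membership permutations (>= 100).
#' @param seed integer seed for the permutation null (required for
#'   reproducibility).
#' @return data.frame with columns \code{set_id}, \code{size}, \code{es},
#'   \code{nes}, \code{pval}, \code{padj}, \code{leadingEdge} (list column)
#'   and \code{n_perm}, ordered by ascending \code{pval}.
#' @export
gseaPreranked <- function(ranked, sets, minSize = 10L, maxSize = 250L,
                          weight = 1, nPerm = 1000L, seed) {
  if (missing(seed)) stop("a seed is required for the permutation null")
  if (nPerm < 100L) stop("nPerm must be >= 100")
  ranked <- .prepareRanked(ranked)
  genes <- names(ranked)
  N <- length(genes)
  wAll <- abs(ranked)^weight
  members <- lapply(geneSets(sets), function(g) which(genes %in% g))
  empty <- names(members)[lengths(members) == 0L]
  if (length(empty))
    message(length(empty), " set(s) with no ranked member skipped: ",
            paste(utils::head(empty, 5), collapse = ", "))
  sizes <- lengths(members)
  keep <- sizes >= minSize & sizes <= maxSize
  if (!any(keep))
    stop("no gene set within the size range [", minSize, ", ", maxSize, "]")
  skippedSize <- sum(!keep & sizes > 0L)
  if (skippedSize)
    message(skippedSize, " set(s) outside the size range skipped")
  members <- members[keep]
  res <- withr::with_seed(as.integer(seed), {
    nulls <- new.env(parent = emptyenv())
    for (K in sort(unique(lengths(members))))
      assign(as.character(K), .nullEs(K, wAll, N, nPerm), envir = nulls)
    lapply(names(members), function(id) {
      pos <- sort.int(members[[id]])
      hit <- .esFromPositions(pos, wAll, N)
      null <- get(as.character(length(pos)), envir = nulls)
      if (hit$es >= 0) {
        same <- null[null >= 0]
        nes <- if (length(same) && mean(same) > 0) hit$es / mean(same) else NA_real_
        p <- (sum(same >= hit$es) + 1) / (length(same) + 1)
      } else {
        same <- null[null < 0]
        nes <- if (length(same)) hit$es / mean(abs(same)) else NA_real_
        p <- (sum(same <= hit$es) + 1) / (length(same) + 1)
      }
      data.frame(set_id = id, size = length(pos), es = hit$es, nes = nes,
                 pval = p,
                 leadingEdge = I(list(genes[pos[hit$leadIdx]])),
                 n_perm = nPerm)
    })
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$pval, method = "BH")
  out <- out[, c("set_id", "size", "es", "nes", "pval", "padj",
                 "leadingEdge", "n_perm")]
  out[order(out$pval, out$set_id), , drop = FALSE]
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test P(X >= k) of a hit list against each gene
#' set, within a detection universe. Set sizes are computed within the
#' universe and filtered to \code{[minSize, maxSize]}. A term is called
#' over-represented when its p-value is below \code{pThreshold} AND at least
#' \code{minCount} hits fall in the set (the "p < .05 and counts higher
#' than 4" reporting rule). BH-adjusted p-values are reported alongside.
#'
#' @param hits character vector of significant genes (must be a subset of
#'   the universe).
#' @param universe character vector of all detected genes.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param minSize,maxSize admitted within-universe set sizes (defaults 10,
#'   250).
#' @param pThreshold significance threshold for the call (default 0.05,
#'   strict).
#' @param minCount minimum overlap for the call (default 5, i.e. counts
#'   higher than 4).
#' @return data.frame with columns \code{term}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{pval}, \code{padj}, \code{over_represented},
#'   \code{members} (list column of overlapping genes), ordered by ascending
#'   \code{pval}.
#' @export
oraHypergeometric <- function(hits, universe, sets, minSize = 10L,
                              maxSize = 250L, pThreshold = 0.05,
                              minCount = 5L) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  out <- setdiff(hits, universe)
  if (length(out))
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  N <- length(universe); n <- length(hits)
  rows <- lapply(setIds(sets), function(id) {
    inUniv <- intersect(sets[[id]], universe)
    K <- length(inUniv)
    if (K < minSize || K > maxSize) return(NULL)
    overlap <- intersect(inUniv, hits)
    k <- length(overlap)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = id, k = k, K = K, n = n, N = N, pval = p,
               over_represented = (p < pThreshold) && (k >= minCount),
               members = I(list(sort(overlap))))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no gene set within the size range after universe intersection")
  res <- do.call(rbind, rows)
  res$padj <- p.adjust(res$pval, method = "BH")
  res <- res[, c("term", "k", "K", "n", "N", "pval", "padj",
                 "over_represented", "members")]
  res[order(res$pval, res$term), , drop = FALSE]
}

#' Single-sample GSEA score
#'
#' Rank-based single-sample enrichment: genes are ordered by decreasing
#' value, the in-set empirical distribution is weighted by
#' \code{rank^alpha} (rank counted from the bottom, so the top gene has the
#' largest weight) and the out-of-set distribution is unweighted; the score
#' is the sum of their differences along the ranking. A set containing every
#' gene scores 0 (the two distributions coincide).
#'
#' @param sampleValues named numeric vector of one sample's values.
#' @param set character vector of member genes (the intersection with the
#'   measured genes must be non-empty).
#' @param alpha rank exponent (default 0.25).
#' @return numeric enrichment score.
#' @export
ssgseaScore <- function(sampleValues, set, alpha = 0.25) {
  if (is.null(names(sampleValues))) stop("sampleValues needs gene names")
  inSet <- names(sampleValues) %in% set
  if (!any(inSet)) stop("the set shares no genes with the sample")
  N <- length(sampleValues)
  K <- sum(inSet)
  if (K == N) return(0)
  ord <- order(-sampleValues, names(sampleValues))
  inSet <- inSet[ord]
  rk <- N - seq_len(N) + 1          # top gene gets rank N
  w <- rk^alpha
  stepIn <- cumsum(ifelse(inSet, w, 0)) / sum(w[inSet])
  stepOut <- cumsum(!inSet) / (N - K)
  sum(stepIn - stepOut)
}

#' Semantic similarity of two ontology terms
#'
#' Information-content similarity in a gene-annotated DAG. With MICA the
#' most informative common ancestor, Resnik similarity is IC(MICA),
#' normalized here by the largest IC in the namespace so that it lies in
#' [0, 1]; Lin similarity is 2 IC(MICA) / (IC(t1) + IC(t2)). Terms whose
#' MICA is the namespace root (IC 0) score 0 on both measures.
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param t1,t2 term ids sharing a namespace; both must be annotated.
#' @return named numeric vector with \code{resnik_normalized} and
#'   \code{lin}.
#' @export
termSimilarity <- function(dag, t1, t2) {
  terms <- dag@terms
  for (t in c(t1, t2)) if (!t %in% terms$id) stop("unknown term: ", t)
  ns1 <- terms$namespace[terms$id == t1]
  ns2 <- terms$namespace[terms$id == t2]
  if (ns1 != ns2)
    stop("terms belong to different namespaces (", ns1, " vs ", ns2, ")")
  ic <- dag@ic
  if (is.na(ic[[t1]]) || is.na(ic[[t2]]))
    stop("information content undefined for unannotated term(s): ",
         paste(c(t1, t2)[is.na(ic[c(t1, t2)])], collapse = ", "))
  common <- intersect(termAncestors(dag, t1), termAncestors(dag, t2))
  icCommon <- ic[common]
  icCommon <- icCommon[!is.na(icCommon)]
  icMica <- if (length(icCommon)) max(icCommon) else 0
  maxIc <- suppressWarnings(max(ic[terms$id[terms$namespace == ns1]], na.rm = TRUE))
  resnik <- if (maxIc > 0) icMica / maxIc else 0
  denom <- ic[[t1]] + ic[[t2]]
  lin <- if (denom > 0) 2 * icMica / denom else 0
  c(resnik_normalized = unname(resnik), lin = unname(lin))
}

#' Prune semantically redundant ontology terms
#'
#' Greedy scan of terms in order of increasing p (ties by term id): a term is
#' dropped when BOTH its normalized Resnik and its Lin similarity to an
#' already-kept term exceed the threshold, so only the most significant
#' representative of each semantic cluster survives. Terms absent from the
#' DAG (or unannotated) cannot be assessed and are kept.
#'
#' @param results data.frame with columns \code{term} and \code{pval} (other
#'   columns pass through).
#' @param dag an \linkS4class{OntologyDAG}.
#' @param threshold similarity cutoff (default 0.4, strict "over 0.4").
#' @return the filtered data.frame, sorted by ascending \code{pval}.
#' @export
redundancyFilter <- function(results, dag, threshold = 0.4) {
  if (!all(c("term", "pval") %in% colnames(results)))
    stop("results needs 'term' and 'pval' columns")
  results <- results[order(results$pval, results$term), , drop = FALSE]
  assessable <- results$term %in% dag@terms$id &
    !is.na(dag@ic[results$term])
  ns <- dag@terms$namespace[match(results$term, dag@terms$id)]
  kept <- logical(nrow(results))
  keptTerms <- character()
  keptNs <- character()
  for (i in seq_len(nrow(results))) {
    t <- results$term[[i]]
    if (!assessable[[i]]) { kept[i] <- TRUE; next }
    redundant <- FALSE
    for (kt in keptTerms[keptNs == ns[[i]]]) {
      sim <- termSimilarity(dag, t, kt)
      if (sim[["resnik_normalized"]] > threshold && sim[["lin"]] > threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) {
      kept[i] <- TRUE
      keptTerms <- c(keptTerms, t)
      keptNs <- c(keptNs, ns[[i]])
    }
  }
  results[kept, , drop = FALSE]
}
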