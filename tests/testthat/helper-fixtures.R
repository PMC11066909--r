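# shared fixture builders and independent oracles

randomMatrix <- function(nr, nc, sd = 1, naFrac = 0, seed = NULL) {
  build <- function() {
    m <- matrix(rnorm(nr * nc, sd = sd), nr, nc,
                dimnames = list(sprintf("F%04d", seq_len(nr)),
                                sprintf("S%03d", seq_len(nc))))
    if (naFrac > 0) m[sample(length(m), round(naFrac * length(m)))] <- NA
    m
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# brute-force weighted-KS enrichment score: full running sum over all genes
bruteEs <- function(ranked, set, weight = 1) {
  ranked <- ranked[order(-ranked, names(ranked))]
  hit <- names(ranked) %in% set
  N <- length(ranked); K <- sum(hit)
  w <- abs(ranked)^weight
  inc <- ifelse(hit, w, 0)
  if (sum(inc) > 0) inc <- inc / sum(inc) else inc <- ifelse(hit, 1 / K, 0)
  dec <- ifelse(hit, 0, if (N > K) 1 / (N - K) else 0)
  rs <- cumsum(inc - dec)
  if (max(rs) >= -min(rs, 0) - 1e-12) max(rs) else min(rs)
}

# exact hypergeometric upper tail by explicit summation
bruteHyperTail <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# independent Welch computation from the textbook formulas
bruteWelch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# independent one-way ANOVA F and p
bruteAnova <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = pf(F, dfb, dfw, lower.tail = FALSE))
}

# Spearman rho on average ranks, directly from the definition
bruteSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all permutations of 1..n (independent of the package's cache)
brutePermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L))
  sub <- brutePermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Benjamini-Yekutieli adjustment straight from the step-up definition
bruteBY <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# closed-form adjusted Rand index from the contingency table
bruteARI <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# tiny 6-term ontology with known annotation counts:
#   root(10 genes) -> A(6) -> C(3), D(2) ; root -> B(4)
toyDag <- function() {
  genes <- sprintf("g%02d", 1:10)
  terms <- data.frame(id = c("root", "A", "B", "C", "D"),
                      name = c("root", "A", "B", "C", "D"),
                      namespace = "bp")
  parents <- list(root = character(), A = "root", B = "root",
                  C = "A", D = "A")
  annotations <- list(root = genes, A = genes[1:6], B = genes[7:10],
                      C = genes[1:3], D = genes[4:5])
  OntologyDAG(terms, parents, annotations)
}
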