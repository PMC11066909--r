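test_that("the enrichment score equals the brute-force running sum", {
  withr::with_seed(14, {
    for (i in 1:60) {
      N <- sample(15:60, 1)
      genes <- sprintf("g%03d", seq_len(N))
      ranked <- setNames(rnorm(N), genes)
      set <- sample(genes, sample(3:10, 1))
      for (w in c(0, 1)) {
        got <- rosetteomics:::.esFromPositions(
          sort(which(names(ranked[order(-ranked, names(ranked))]) %in% set)),
          abs(ranked[order(-ranked, names(ranked))])^w, N)$es
        expect_equal(got, bruteEs(ranked, set, w), tolerance = 1e-12)
      }
    }
  })
})

test_that("a top-K set attains the closed-form unweighted maximum", {
  genes <- sprintf("g%02d", 1:10)
  ranked <- setNames(10:1, genes)
  # K = 3 top genes, weight 0: running sum peaks at 3/3 - 0 = 1 after gene 3
  got <- rosetteomics:::.esFromPositions(1:3, rep(1, 10), 10)$es
  expect_identical(got, 1)
  # uniformly spread set stays near zero and below the top-K score
  spread <- c("g02", "g05", "g08")
  esSpread <- bruteEs(ranked, spread, 0)
  expect_lt(abs(esSpread), abs(got))
})

test_that("permutation p converges to the exhaustive membership null", {
  genes <- sprintf("g%d", 1:8)
  ranked <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3), genes)
  set <- c("g1", "g2", "g4")
  esObs <- bruteEs(ranked, set, 1)
  combs <- combn(8, 3)
  nullEs <- apply(combs, 2, function(idx)
    bruteEs(ranked, genes[idx], 1))
  pos <- nullEs[nullEs >= 0]
  pExact <- sum(pos >= esObs) / length(pos)

  res <- gseaPreranked(ranked, GeneSetCollection(list(S = set)),
                       minSize = 3, maxSize = 8, nPerm = 4000, seed = 2)
  nPos <- 4000 * length(pos) / ncol(combs)   # expected same-sign permutations
  se <- sqrt(pExact * (1 - pExact) / nPos)
  expect_lt(abs(res$pval - pExact), 3 * se + 1 / nPos)
  expect_equal(res$es, esObs, tolerance = 1e-12)
})

test_that("GSEA results keep their structural invariants", {
  fix <- withr::with_seed(3, {
    genes <- sprintf("g%03d", 1:120)
    ranked <- setNames(rnorm(120), genes)
    sets <- lapply(1:8, function(i) sample(genes, 15))
    names(sets) <- sprintf("S%d", 1:8)
    list(ranked = ranked, sets = GeneSetCollection(sets))
  })
  res <- gseaPreranked(fix$ranked, fix$sets, minSize = 5, maxSize = 100,
                       nPerm = 300, seed = 9)
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(sign(res$nes) == sign(res$es)))
  expect_true(all(res$padj >= res$pval - 1e-15))
  # BH monotone: adjusted order respects nominal order
  o <- order(res$pval)
  expect_true(all(diff(res$padj[o]) >= -1e-15))
  # reproducible bit-for-bit under the same seed
  res2 <- gseaPreranked(fix$ranked, fix$sets, minSize = 5, maxSize = 100,
                        nPerm = 300, seed = 9)
  expect_identical(res, res2)
  # sign equivariance: negating every score mirrors the enrichment
  resNeg <- gseaPreranked(-fix$ranked, fix$sets, minSize = 5, maxSize = 100,
                          nPerm = 300, seed = 9)
  m <- match(res$set_id, resNeg$set_id)
  expect_equal(resNeg$es[m], -res$es, tolerance = 1e-12)
  # ES invariant to monotone rescaling at weight 0
  resW0 <- gseaPreranked(fix$ranked, fix$sets, minSize = 5, maxSize = 100,
                         weight = 0, nPerm = 300, seed = 9)
  resW0b <- gseaPreranked(fix$ranked * 3 + 0, fix$sets, minSize = 5,
                          maxSize = 100, weight = 0, nPerm = 300, seed = 9)
  expect_equal(resW0$es, resW0b$es, tolerance = 1e-12)

  expect_error(gseaPreranked(fix$ranked, fix$sets, minSize = 50, maxSize = 60,
                             nPerm = 300, seed = 1), "size range")
  expect_error(gseaPreranked(fix$ranked, fix$sets, nPerm = 300), "seed")
})

test_that("GSEA enrichment scores agree with the fgsea reference", {
  skip_if_not_installed("fgsea")
  fix <- withr::with_seed(21, {
    genes <- sprintf("g%03d", 1:200)
    ranked <- setNames(rnorm(200), genes)
    sets <- lapply(1:10, function(i) sample(genes, sample(10:40, 1)))
    names(sets) <- sprintf("S%02d", 1:10)
    list(ranked = ranked, sets = sets)
  })
  ours <- gseaPreranked(fix$ranked, GeneSetCollection(fix$sets),
                        minSize = 10, maxSize = 250, nPerm = 200, seed = 4)
  ref <- suppressWarnings(
    fgsea::fgsea(fix$sets, fix$ranked, minSize = 10, maxSize = 250,
                 nPermSimple = 200))
  m <- match(ours$set_id, ref$pathway)
  expect_equal(ours$es, ref$ES[m], tolerance = 1e-10)
})

test_that("hypergeometric ORA matches exact enumeration and the call rule", {
  res <- oraHypergeometric(sprintf("h%02d", 1:10),
                           c(sprintf("h%02d", 1:10), sprintf("u%02d", 1:10)),
                           GeneSetCollection(list(S = sprintf("h%02d", 1:5))),
                           minSize = 5, maxSize = 20)
  expect_identical(res$k, 5L)
  expect_equal(res$pval, bruteHyperTail(5, 5, 20, 10), tolerance = 1e-12)

  # hits = universe: every set overlaps completely at p = 1
  u <- sprintf("x%02d", 1:15)
  resFull <- oraHypergeometric(u, u, GeneSetCollection(list(S = u[1:12])),
                               minSize = 5, maxSize = 20)
  expect_identical(resFull$k, 12L)
  expect_equal(resFull$pval, 1)

  expect_error(oraHypergeometric(c("h01", "zz"), u,
                                 GeneSetCollection(list(S = u[1:12]))),
               "outside the universe")

  # the "p < .05 AND counts higher than 4" rule at its boundary
  fix <- withr::with_seed(40, {
    universe <- sprintf("G%03d", 1:200)
    sets <- GeneSetCollection(list(big = universe[1:20], small = universe[21:40]))
    list(universe = universe, sets = sets)
  })
  hits5 <- c(fix$universe[1:5], fix$universe[190:199])
  r5 <- oraHypergeometric(hits5, fix$universe, fix$sets, minSize = 5,
                          maxSize = 50)
  expect_lt(r5$pval[r5$term == "big"], 0.05)
  expect_true(r5$over_represented[r5$term == "big"])     # k = 5 qualifies
  hits4 <- c(fix$universe[1:4], fix$universe[190:199])
  r4 <- oraHypergeometric(hits4, fix$universe, fix$sets, minSize = 5,
                          maxSize = 50)
  expect_lt(r4$pval[r4$term == "big"], 0.05)
  expect_false(r4$over_represented[r4$term == "big"])    # k = 4 does not
})

test_that("ssGSEA scores follow the rank-weighted ECDF definition", {
  vals <- setNames(c(9, 7, 6, 5, 4, 3.5, 3, 2, 1.5, 1), sprintf("g%02d", 1:10))
  set <- c("g01", "g03", "g07")
  # independent direct computation
  ord <- names(sort(vals, decreasing = TRUE))
  inSet <- ord %in% set
  rk <- 10:1
  w <- rk^0.25
  want <- sum(cumsum(ifelse(inSet, w, 0)) / sum(w[inSet]) -
                cumsum(!inSet) / sum(!inSet))
  expect_equal(ssgseaScore(vals, set), want, tolerance = 1e-12)

  expect_identical(ssgseaScore(vals, names(vals)), 0)
  expect_gt(ssgseaScore(vals, "g01"), ssgseaScore(vals, "g10"))
  expect_error(ssgseaScore(vals, c("zz")), "no genes")
})

test_that("Resnik and Lin similarities follow the information content", {
  dag <- toyDag()
  ic <- termIC(dag)
  expect_identical(unname(ic[["root"]]), 0)
  expect_equal(ic[["A"]], -log(6 / 10))
  expect_equal(ic[["C"]], -log(3 / 10))

  # identical non-root terms: lin = 1
  expect_equal(termSimilarity(dag, "C", "C")[["lin"]], 1)
  # MICA is the root: both measures 0
  expect_equal(unname(termSimilarity(dag, "A", "B")), c(0, 0))
  # siblings under A: MICA = A, known counts
  sim <- termSimilarity(dag, "C", "D")
  maxIc <- max(ic, na.rm = TRUE)
  expect_equal(sim[["resnik_normalized"]], -log(6 / 10) / maxIc)
  expect_equal(sim[["lin"]], 2 * -log(6 / 10) / (-log(3 / 10) - log(2 / 10)))
  # ancestor-descendant: MICA is the ancestor
  simAC <- termSimilarity(dag, "A", "C")
  expect_equal(simAC[["lin"]], 2 * ic[["A"]] / (ic[["A"]] + ic[["C"]]))

  terms2 <- data.frame(id = c("r2", "x2"), name = c("r2", "x2"),
                       namespace = "mf")
  dag2 <- OntologyDAG(rbind(dag@terms, terms2),
                      c(dag@parents, list(r2 = character(), x2 = "r2")),
                      c(dag@annotations, list(r2 = "g99", x2 = "g99")))
  expect_error(termSimilarity(dag2, "C", "x2"), "namespaces")
  dag3 <- OntologyDAG(dag@terms, dag@parents,
                      list(root = sprintf("g%02d", 1:10), A = "g01"))
  expect_error(termSimilarity(dag3, "B", "C"), "undefined")
})

test_that("redundancy pruning keeps the most significant representative", {
  dag <- generateOntology(25, depth = 2, seed = 17)
  pair <- attr(dag, "redundantPair")
  res <- data.frame(term = c(pair, "T0002"), pval = c(0.01, 0.001, 0.04))
  kept <- redundancyFilter(res, dag, threshold = 0.4)
  expect_true(pair[2] %in% kept$term)      # smaller p of the redundant pair
  expect_false(pair[1] %in% kept$term)
  expect_true("T0002" %in% kept$term)

  # mutually dissimilar terms (root MICA) pass untouched
  dagToy <- toyDag()
  resAB <- data.frame(term = c("A", "B"), pval = c(0.01, 0.02))
  expect_identical(redundancyFilter(resAB, dagToy)$term, c("A", "B"))

  # two identical annotation sets: only the smaller p survives
  terms <- data.frame(id = c("r", "t1", "t2"), name = c("r", "t1", "t2"),
                      namespace = "bp")
  twins <- OntologyDAG(terms,
                       list(r = character(), t1 = "r", t2 = "t1"),
                       list(r = sprintf("g%02d", 1:20),
                            t1 = sprintf("g%02d", 1:5),
                            t2 = sprintf("g%02d", 1:5)))
  res2 <- data.frame(term = c("t1", "t2"), pval = c(0.03, 0.001))
  expect_identical(redundancyFilter(res2, twins)$term, "t2")
})
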