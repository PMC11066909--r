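test_that("Welch test matches the textbook computation and its symmetries", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  got <- welchTest(a, b)
  want <- bruteWelch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  same <- welchTest(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)

  swapped <- welchTest(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)

  expect_error(welchTest(1, c(1, 2)), ">= 2")

  # two-sided p is twice the one-sided tail, on random instances
  withr::with_seed(5, {
    for (i in 1:50) {
      x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
      ht <- welchTest(x, y)
      expect_equal(ht$p, 2 * pt(-abs(ht$t), ht$df), tolerance = 1e-12)
    }
  })
})

test_that("Welch p-values are uniform under the null", {
  p <- withr::with_seed(99, {
    vapply(seq_len(1500), function(i)
      welchTest(rnorm(10), rnorm(12))$p, numeric(1))
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("paired test matches a one-sample t on differences and flags degeneracy", {
  zero <- pairedTest(c(1, 2, 3), c(1, 2, 3))
  expect_identical(zero$p, 1)
  expect_true(zero$degenerate)
  const <- pairedTest(c(2, 3, 4), c(1, 2, 3))   # differences all 1
  expect_true(const$degenerate)
  expect_identical(const$p, 1)

  withr::with_seed(8, {
    for (i in 1:20) {
      x <- rnorm(10); y <- rnorm(10)
      got <- pairedTest(x, y)
      ref <- t.test(x - y)
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)
    }
  })
  expect_error(pairedTest(1, 2), "pairs")
})

test_that("ANOVA feature ranking recovers a planted group effect", {
  fix <- withr::with_seed(4, {
    m <- randomMatrix(60, 18)
    groups <- rep(c("g1", "g2", "g3"), each = 6)
    m["F0007", groups == "g1"] <- m["F0007", groups == "g1"] + 5
    m["F0031", ] <- 2                     # identical across groups
    list(m = m, groups = groups)
  })
  ranked <- anovaRankFeatures(fix$m, fix$groups, topN = 60)
  expect_identical(ranked$feature[1], "F0007")
  expect_identical(ranked$feature[60], "F0031")
  expect_lt(abs(ranked$F[60]), 1e-20)

  top5 <- anovaRankFeatures(fix$m, fix$groups, topN = 5)
  expect_identical(top5$feature, ranked$feature[1:5])
  expect_warning(all60 <- anovaRankFeatures(fix$m, fix$groups, topN = 100),
                 "exceeds")
  expect_identical(nrow(all60), 60L)

  # per-feature F and p match the direct sums-of-squares computation
  withr::with_seed(12, {
    for (i in 1:30) {
      v <- rnorm(18)
      got <- anovaRankFeatures(matrix(v, 1, dimnames = list("x", NULL)),
                               fix$groups, topN = 1)
      want <- bruteAnova(v, fix$groups)
      expect_equal(got$F, want$F, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
    }
  })
})

test_that("the ranking score is fc times -log10 p with clamped zeros", {
  expect_identical(rankStatistic(1, 0.1), 1)
  expect_identical(rankStatistic(0, 0.42), 0)
  expect_equal(rankStatistic(2.84, 0.001), 8.52, tolerance = 1e-12)
  expect_warning(s <- rankStatistic(1, 0), "clamped")
  expect_true(is.finite(s) && s > 300)
  expect_error(rankStatistic(1, 1.2), "0, 1")

  # sign-preserving in fc, monotone decreasing in p for fixed positive fc
  p <- seq(0.001, 1, length.out = 50)
  s <- rankStatistic(rep(2, 50), p)
  expect_true(all(diff(s) < 0))
  expect_identical(sign(rankStatistic(c(-3, 3), c(0.5, 0.5))), c(-1, 1))
})

test_that("subgroup rank combination averages scores deterministically", {
  a <- c(g1 = 4, g2 = 1, g3 = -2)
  expect_identical(combineSubgroupRanks(a, a), a[order(-a, names(a))])

  b <- c(g1 = -4, g2 = 1, g3 = 2)
  comb <- combineSubgroupRanks(a, b)
  expect_identical(unname(comb[["g1"]]), 0)

  withr::with_seed(6, {
    for (i in 1:20) {
      g <- sprintf("g%02d", 1:30)
      x <- setNames(rnorm(30), g); y <- setNames(rnorm(30), g)
      comb <- combineSubgroupRanks(x, y)
      want <- (x + y) / 2
      want <- want[order(-want, names(want))]
      expect_identical(comb, want)
    }
  })

  expect_message(combineSubgroupRanks(c(g1 = 1, g2 = 2), c(g2 = 1, g3 = 2)),
                 "2 gene")
  expect_error(combineSubgroupRanks(c(g1 = 1), c(g2 = 1)), "share no genes")

  # rank-position mode: genes high in both stay on top
  x <- c(g1 = 10, g2 = 5, g3 = 1)
  y <- c(g1 = 3, g2 = 2, g3 = 1)
  byRank <- combineSubgroupRanks(x, y, method = "rank")
  expect_identical(names(byRank)[1], "g1")
})

test_that("morphology-independent selection keeps exactly the concordant dual hits", {
  mk <- function(fc, p) data.frame(
    feature = sprintf("F%d", seq_along(fc)), fc = fc, t = 0, df = 1, p = p,
    n_case = 5, n_control = 5, test = "welch", degenerate = FALSE)
  # F1 both-subgroup hit; F2 hit in A only; F3 discordant signs;
  # F4 sub-threshold fc; F5 sub-threshold p; F6 null
  dA <- mk(c(1.5, 1.5, 1.5, 0.8, 1.5, 0.1), c(.01, .01, .01, .01, .20, .80))
  dB <- mk(c(1.5, 0.2, -1.5, 0.9, 1.5, 0.0), c(.01, .70, .01, .01, .01, .90))
  sel <- morphologyIndependentSelection(dA, dB)
  expect_identical(sel$feature, "F1")
  expect_identical(sel$direction, "up")

  # symmetric in the two tables, invariant to feature order
  expect_identical(morphologyIndependentSelection(dB, dA)$feature, "F1")
  shuf <- withr::with_seed(2, sample(6))
  expect_identical(
    morphologyIndependentSelection(dA[shuf, ], dB, fcThreshold = 1)$feature,
    "F1")

  # boundary: p == .05 is included, |fc| == 1 is not ("|fc| > 1")
  dC <- mk(c(1.0, 1.01), c(.05, .05))
  sel2 <- morphologyIndependentSelection(dC, dC)
  expect_identical(sel2$feature, "F2")
})

test_that("differentialTable computes log2 mean-difference fold changes", {
  m <- matrix(c(4, 4, 4, 4, 1, 1, 1, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("up", "dn"),
                              c("c1", "c2", "k1", "k2")))
  m["dn", c("k1", "k2")] <- 3
  dt <- differentialTable(m, c("c1", "c2"), c("k1", "k2"))
  expect_identical(dt["up", "fc"], 0)
  expect_identical(dt["dn", "fc"], -2)
  expect_identical(unique(dt$test), "welch")
})
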