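test_that("median centering zeroes every sample median and is idempotent", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ctr <- medianCenter(m)
  expect_equal(ctr[, "s1"], c(a = -1, b = 0, c = 1))
  expect_equal(unname(ctr[, "s2"]), c(0, 0, 0))

  r <- randomMatrix(100, 10, naFrac = 0.1, seed = 1)
  ctr <- medianCenter(r)
  expect_lt(max(abs(apply(ctr, 2, median, na.rm = TRUE))), 1e-12)
  expect_equal(medianCenter(ctr), ctr, tolerance = 1e-12)

  r[, 3] <- NA
  expect_error(medianCenter(r), "S003")
})

test_that("median/MAD standardization reaches median 0, MAD 1, idempotently", {
  m <- matrix(c(0, 1, 2), 3, 1, dimnames = list(letters[1:3], "s1"))
  z <- medianMadStandardize(m)
  expect_equal(median(z), 0)
  expect_equal(mad(z, constant = 1), 1)

  r <- randomMatrix(200, 8, seed = 2)
  z <- medianMadStandardize(r)
  expect_lt(max(abs(apply(z, 2, mad, constant = 1) - 1)), 1e-12)
  expect_equal(medianMadStandardize(z), z, tolerance = 1e-12)

  const <- matrix(1, 5, 2, dimnames = list(letters[1:5], c("s1", "s2")))
  expect_error(medianMadStandardize(const), "s1")
})

test_that("EB batch adjustment removes a planted shift and respects edge cases", {
  # replicate-level technical noise around a shared profile, batch 2 shifted
  fix <- withr::with_seed(10, {
    mu <- rnorm(100)
    X <- mu + matrix(rnorm(100 * 50, sd = 0.15), 100, 50,
                     dimnames = list(sprintf("F%03d", 1:100),
                                     sprintf("S%03d", 1:50)))
    batch <- rep(c("b1", "b2"), each = 25)
    X[, batch == "b2"] <- X[, batch == "b2"] + 2
    list(X = X, batch = batch)
  })
  res <- combatAdjust(fix$X, fix$batch)
  d <- rowMeans(res$corrected[, fix$batch == "b1"]) -
    rowMeans(res$corrected[, fix$batch == "b2"])
  expect_lt(max(abs(d)), 0.1)
  expect_s4_class(res$model, "BatchModel")

  # single batch: identity
  single <- combatAdjust(fix$X, rep("only", 50))
  expect_identical(single$corrected, fix$X)

  # sample order invariance (up to the same permutation)
  perm <- withr::with_seed(1, sample(50))
  res2 <- combatAdjust(fix$X[, perm], fix$batch[perm])
  expect_equal(res2$corrected, res$corrected[, perm], tolerance = 1e-9)

  expect_error(combatAdjust(fix$X, c("a", rep("b", 49))), "size 1")

  # zero-variance feature passes through untouched, with a warning
  X0 <- fix$X; X0[1, ] <- 7
  expect_warning(res0 <- combatAdjust(X0, fix$batch), "zero-variance")
  expect_equal(unname(res0$corrected[1, ]), rep(7, 50))

  # missing values are re-masked after adjustment
  Xna <- fix$X; Xna[2, c(1, 30)] <- NA
  resna <- combatAdjust(Xna, fix$batch)
  expect_true(all(is.na(resna$corrected[2, c(1, 30)])))
  expect_false(anyNA(resna$corrected[-2, ]))
})

test_that("EB adjustment agrees with the sva reference implementation", {
  skip_if_not_installed("sva")
  fix <- withr::with_seed(77, {
    X <- matrix(rnorm(200 * 60), 200, 60,
                dimnames = list(sprintf("F%03d", 1:200), sprintf("S%03d", 1:60)))
    batch <- rep(c("a", "b", "c"), each = 20)
    X[, batch == "b"] <- X[, batch == "b"] + 1.5
    X[, batch == "c"] <- X[, batch == "c"] * 1.4 - 0.5
    list(X = X, batch = batch)
  })
  ours <- combatAdjust(fix$X, fix$batch)$corrected
  ref <- suppressMessages(sva::ComBat(fix$X, fix$batch))
  # same algorithm up to variance-denominator conventions: near-identical output
  expect_gt(cor(as.vector(ours), as.vector(ref)), 0.999)
  expect_lt(max(abs(ours - ref)), 0.2)
  expect_lt(mean(abs(ours - ref)), 0.05)
})

test_that("reference-anchored integration aligns cohorts and drops references", {
  # cohort B is cohort A under a constant platform shift; the 5 reference
  # samples are distinct profiles, each present in both cohorts as a
  # replicate-like copy with small independent measurement noise
  fix <- withr::with_seed(31, {
    mu <- rnorm(120)
    refProfiles <- mu + matrix(rnorm(120 * 5, sd = 0.3), 120, 5)
    tumors <- mu + matrix(rnorm(120 * 12, sd = 0.5), 120, 12)
    makeCohort <- function(prefix, shift) {
      refs <- refProfiles + matrix(rnorm(120 * 5, sd = 0.1), 120, 5)
      v <- cbind(tumors, refs) + shift
      colnames(v) <- c(sprintf("%s_T%02d", prefix, 1:12),
                       sprintf("%s_R%d", prefix, 1:5))
      rownames(v) <- sprintf("F%03d", 1:120)
      ann <- data.frame(sample_id = colnames(v), entity = "MB",
                        subgroup = "none", batch = prefix,
                        is_reference = rep(c(FALSE, TRUE), c(12, 5)))
      OmicsMatrix(v, "proteome", ann)
    }
    list(a = makeCohort("A", 0), b = makeCohort("B", 2))
  })
  # shared references: cohort B is cohort A plus a constant shift, with the
  # same 5 control-pool replicate anchors in both cohorts
  strict <- withr::with_seed(32, {
    mu <- rnorm(120)
    tumors <- mu + matrix(rnorm(120 * 12, sd = 0.5), 120, 12)
    refs <- mu + matrix(rnorm(120 * 5, sd = 0.05), 120, 5)
    mk <- function(prefix, shift) {
      v <- cbind(tumors, refs) + shift
      colnames(v) <- c(sprintf("%s_T%02d", prefix, 1:12),
                       sprintf("%s_R%d", prefix, 1:5))
      rownames(v) <- sprintf("F%03d", 1:120)
      ann <- data.frame(sample_id = colnames(v), entity = "MB",
                        subgroup = "none", batch = prefix,
                        is_reference = rep(c(FALSE, TRUE), c(12, 5)))
      OmicsMatrix(v, "proteome", ann)
    }
    list(a = mk("A", 0), b = mk("B", 2))
  })
  merged <- coconutIntegrate(strict$a, strict$b)
  expect_false(any(colData(merged)$is_reference))
  expect_identical(ncol(merged), 24L)
  co <- colData(merged)$cohort
  d <- rowMeans(assay(merged)[, co == "A"]) - rowMeans(assay(merged)[, co == "B"])
  expect_lt(max(abs(d)), 0.1)

  # replicate-like anchors with independent measurement noise: the shift is
  # still removed almost completely
  noisy <- coconutIntegrate(fix$a, fix$b)
  co2 <- colData(noisy)$cohort
  d2 <- rowMeans(assay(noisy)[, co2 == "A"]) - rowMeans(assay(noisy)[, co2 == "B"])
  expect_lt(mean(abs(d2)), 0.1)
  expect_lt(max(abs(d2)), 0.5)

  # identical cohorts with identical references: non-reference samples unchanged
  annB <- as.data.frame(colData(fix$a))
  annB$sample_id <- paste0(annB$sample_id, "x")
  twin <- OmicsMatrix(`colnames<-`(assay(fix$a), annB$sample_id),
                      "proteome", annB)
  same <- coconutIntegrate(fix$a, twin)
  orig <- assay(fix$a)[, !colData(fix$a)$is_reference]
  expect_lt(max(abs(assay(same)[, colData(same)$cohort == "A"] - orig)), 1e-9)

  reAnnotate <- function(m, refFlags) {
    ann <- as.data.frame(colData(m))
    ann$is_reference <- refFlags
    OmicsMatrix(assay(m), "proteome", ann)
  }
  noRef <- reAnnotate(fix$a, rep(FALSE, 17))
  expect_error(coconutIntegrate(noRef, fix$b), "reference")
  oneRef <- reAnnotate(fix$a, c(TRUE, rep(FALSE, 16)))
  expect_error(coconutIntegrate(oneRef, fix$b), "at least 2")
})

test_that("integration on all-reference cohorts reduces to plain EB adjustment", {
  fix <- withr::with_seed(13, {
    mk <- function(prefix, shift) {
      v <- matrix(rnorm(80 * 8), 80, 8,
                  dimnames = list(sprintf("F%02d", 1:80),
                                  sprintf("%s%d", prefix, 1:8))) + shift
      ann <- data.frame(sample_id = colnames(v), entity = "MB",
                        subgroup = "none", batch = prefix, is_reference = TRUE)
      OmicsMatrix(v, "proteome", ann)
    }
    list(a = mk("A", 0), b = mk("B", 1))
  })
  merged <- coconutIntegrate(fix$a, fix$b)
  model <- S4Vectors::metadata(merged)$batchModel
  combat <- combatAdjust(cbind(assay(fix$a), assay(fix$b)),
                         rep(c("A", "B"), each = 8))
  expect_equal(model@gamma, combat$model@gamma, tolerance = 1e-9)
  expect_equal(model@delta2, combat$model@delta2, tolerance = 1e-9)
  expect_identical(ncol(merged), 0L)   # anchors are never analysed
})

test_that("probe filtering applies the exclusion flags and detection threshold", {
  ann <- data.frame(cpg_id = sprintf("cg%d", 1:5),
                    gene = "TP53",
                    region = c("TSS200", "body", "TSS1500", "UTR5", "TSS200"),
                    chromosome = c("chrX", "chr1", "chr2", "chr3", "chr4"))
  ann$flags <- list("sex_chromosome", character(), "snp_at_cpg",
                    "cross_reactive", character())
  beta <- matrix(0.5, 5, 4, dimnames = list(ann$cpg_id, sprintf("s%d", 1:4)))
  m <- OmicsMatrix(beta, "methylome")
  kept <- filterProbes(m, ann)
  expect_setequal(rownames(kept), c("cg2", "cg5"))

  dp <- matrix(0.001, 5, 4, dimnames = dimnames(beta))
  dp["cg5", 2] <- 0.01       # boundary: "of or above 0.01" is excluded
  kept2 <- filterProbes(m, ann, detectionP = dp)
  expect_identical(rownames(kept2), "cg2")

  ann0 <- ann
  ann0$flags <- rep(list(character()), 5)
  expect_identical(nrow(filterProbes(m, ann0)), 5L)
  annAll <- ann0
  annAll$flags <- rep(list("cross_reactive"), 5)
  expect_warning(filterProbes(m, annAll), "all probes")
})
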