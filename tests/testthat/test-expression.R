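test_that("median-of-ratios size factors match hand-computed cases", {
  m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  expect_equal(unname(sizeFactorsMedianRatio(m)),
               c(1 / sqrt(2), sqrt(2)))
  ident <- cbind(a = c(5, 9), b = c(5, 9), c = c(5, 9))
  expect_equal(unname(sizeFactorsMedianRatio(ident)), c(1, 1, 1))
  single <- rbind(c(4, 16))
  expect_equal(unname(sizeFactorsMedianRatio(single)), c(0.5, 2))
  allZero <- cbind(c(0, 5), c(3, 0))
  expect_error(sizeFactorsMedianRatio(allZero), "pseudocount")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(1)
  m <- matrix(rnbinom(600, mu = 50, size = 5) + 1, ncol = 6)
  # DESeq2 takes the median in log space; with an even number of
  # all-positive features the interpolated middle differs slightly
  expect_equal(unname(sizeFactorsMedianRatio(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-3)
})

test_that("size factors scale with library depth", {
  set.seed(2)
  m <- matrix(rnbinom(500, mu = 100, size = 10) + 1, ncol = 5)
  m2 <- sweep(m, 2, c(1, 2, 4, 1, 0.5), "*")
  sf <- sizeFactorsMedianRatio(m2)
  expect_equal(sf / sf[1], c(1, 2, 4, 1, 0.5), tolerance = 0.15)
})

test_that("BH adjustment matches the step-up construction", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.5, 0.04, 0.9)
  q <- bhAdjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted p
  expect_true(all(q <= 1))
})

test_that("the NB Wald test is self-consistent and recovers effects", {
  sim <- simulateMrnaCounts(nGenes = 400, dispersion = 0.05,
                            log2fc = rep(c(0, 2), times = c(360, 40)),
                            seed = 5)
  de <- nbWaldTest(sim$counts, sim$group)
  eff <- de$log2fc[match(sim$truth$gene[sim$truth$log2fc == 2],
                         de$feature)]
  expect_lt(abs(median(eff, na.rm = TRUE) - 2), 0.3)
  # label swap negates the fold change, p-values unchanged
  de2 <- nbWaldTest(sim$counts, factor(sim$group,
                                       levels = rev(levels(sim$group))))
  expect_equal(de2$log2fc, -de$log2fc, tolerance = 1e-9)
  expect_equal(de2$p_value, de$p_value, tolerance = 1e-9)
  # constant feature with equal means: no signal
  flat <- rbind(rep(50, 8), sim$counts)
  rownames(flat)[1] <- "flatgene"
  deF <- nbWaldTest(flat, sim$group, sizeFactors = rep(1, 8))
  expect_equal(deF$log2fc[deF$feature == "flatgene"], 0)
  expect_gt(deF$p_value[deF$feature == "flatgene"], 0.9)
  # all-zero features are excluded, not tested
  zi <- rbind(rep(0, 8), sim$counts)
  deZ <- nbWaldTest(zi, sim$group)
  expect_equal(attr(deZ, "nExcluded"), 1)
})

test_that("null simulation keeps the false-positive rate near nominal", {
  sim <- simulateMrnaCounts(nGenes = 1000, dispersion = 0.1,
                            log2fc = 0, seed = 13)
  de <- nbWaldTest(sim$counts, sim$group)
  t1 <- mean(de$p_value < 0.05)
  expect_gt(t1, 0.02)
  expect_lt(t1, 0.09)
})

test_that("k-means recovers planted clusters and is reproducible", {
  set.seed(11)
  centers <- matrix(c(0, 0, 6, 0, 0, 6), ncol = 2, byrow = TRUE)
  truth <- rep(1:3, each = 40)
  x <- centers[truth, ] + matrix(rnorm(240, sd = 1), ncol = 2)
  rownames(x) <- paste0("f", seq_len(nrow(x)))
  cl <- kmeansProfiles(x, k = 3, seed = 0)
  expect_gte(adjustedRand(cl$cluster, truth), 0.95)
  cl2 <- kmeansProfiles(x, k = 3, seed = 0)
  expect_identical(cl, cl2)
  # k = 1: inertia equals the total variance around the mean
  one <- kmeansProfiles(x, k = 1)
  expect_equal(attr(one, "inertia"),
               sum(sweep(x, 2, colMeans(x))^2))
  # duplicate rows always share a cluster
  dupIdx <- c(1, 1, 50, 50, 100)
  xd <- x[dupIdx, ]; rownames(xd) <- paste0("r", 1:5)
  cld <- kmeansProfiles(xd, k = 2, seed = 1)
  expect_equal(cld$cluster[1], cld$cluster[2])
  expect_equal(cld$cluster[3], cld$cluster[4])
  expect_error(kmeansProfiles(x, k = 1000), "exceeds")
  # excluded families are left out
  clx <- kmeansProfiles(x, k = 3, exclude = c("f1", "f2"))
  expect_false(any(c("f1", "f2") %in% clx$feature))
})

test_that("PCA separates groups and reports variance fractions", {
  m <- cbind(a1 = c(100, 10, 50), a2 = c(100, 10, 50),
             b1 = c(10, 100, 50), b2 = c(10, 100, 50))
  pc <- pcaQC(m, sizeFactors = rep(1, 4))
  expect_equal(sum(pc$varExplained), 1)
  expect_gt(pc$varExplained[1], 0.99)
  expect_gt(abs(mean(pc$scores[1:2, 1]) - mean(pc$scores[3:4, 1])), 1)
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  pc2 <- pcaQC(m[, perm], sizeFactors = rep(1, 4))
  expect_equal(abs(pc2$scores[, 1]), abs(pc$scores[perm, 1]),
               ignore_attr = TRUE)
  expect_error(pcaQC(m[, 1, drop = FALSE]), ">= 2 samples")
})
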