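twoMirnaCube <- function() {
  # miRNA A: 100 reads, 10 mono-U; miRNA B: 10 reads, 3 mono-U
  makeCube(data.frame(
    sample = "wt_rep1",
    mirna_id = c("mirA", "mirA", "mirB", "mirB"),
    arm = "3p",
    category = c("exact", "nta", "exact", "nta"),
    tail_type = c("none", "U", "none", "U"),
    weight = c(90, 10, 7, 3), stringsAsFactors = FALSE))
}

test_that("profiles compute fractions without dividing by zero", {
  cube <- makeCube(data.frame(
    sample = "wt_rep1", mirna_id = "mirA", arm = "3p",
    category = c("exact", "nta"), tail_type = c("none", "U"),
    weight = c(85, 15), stringsAsFactors = FALSE))
  prof <- buildProfiles(cube, minReads = 10)
  expect_equal(prof$tt_U / prof$total, 0.15)
  expect_equal(sum(prof[, startsWith(names(prof), "tt_")]) / prof$total, 1)
  expect_equal(sum(prof[, startsWith(names(prof), "cat_")]) / prof$total, 1)
})

test_that("unweighted mean and weighted mean ratio are different
          estimators", {
  prof <- buildProfiles(twoMirnaCube(), minReads = 10)
  expect_equal(unname(meanIsomirPercent(prof, "monoU")["wt"]), 20)
  expect_equal(unname(weightedMeanRatio(prof, "monoU")["wt"]), 13 / 110)
  # single miRNA: both collapse to its own fraction
  one <- makeCube(data.frame(sample = "s1", mirna_id = "m", arm = "3p",
                             category = c("exact", "nta"),
                             tail_type = c("none", "U"),
                             weight = c(85, 15)), conditions = "c1")
  p1 <- buildProfiles(one)
  expect_equal(unname(meanIsomirPercent(p1, "monoU")), 15)
  expect_equal(unname(weightedMeanRatio(p1, "monoU")), 0.15)
})

test_that("weighted mean ratio equals the raw-cube computation", {
  cfg <- smallSimConfig(seed = 17, nMirnas = 6, depth = 2500)
  ref <- simulateReference(cfg)
  sim <- simulateReads(cfg, ref)
  calls <- classifyReads(preprocessAll(sim), ref$hairpins)
  cube <- tallyCalls(calls)
  prof <- buildProfiles(cube)
  t <- tallyTable(cube)
  cond <- sampleTable(cube)$condition[match(t$sample,
                                            sampleTable(cube)$sample)]
  for (cd in unique(cond)) {
    direct <- sum(t$weight[cond == cd & t$tail_type == "U"]) /
      sum(t$weight[cond == cd])
    expect_equal(unname(weightedMeanRatio(prof, "monoU")[cd]), direct)
  }
})

test_that("arm stratification separates planted tail placement", {
  cube <- makeCube(data.frame(
    sample = "s1",
    mirna_id = "m", arm = c("5p", "5p", "3p", "3p"),
    category = c("exact", "exact", "exact", "nta"),
    tail_type = c("none", "none", "none", "U"),
    weight = c(50, 10, 45, 15)), conditions = "c1")
  prof <- stratifyByArm(cube)
  u5 <- weightedMeanRatio(prof, "monoU", arm = "5p")
  u3 <- weightedMeanRatio(prof, "monoU", arm = "3p")
  expect_equal(unname(u5), 0)
  expect_equal(unname(u3), 0.25)
  # pooled fraction is the depth-weighted mean of arm fractions
  pooled <- buildProfiles(cube)
  expect_equal(unname(weightedMeanRatio(pooled, "monoU")),
               (60 * 0 + 60 * 0.25) / 120)
})

test_that("the modification filter is strict at the 1% boundary", {
  mk <- function(frac) makeCube(data.frame(
    sample = "s1", mirna_id = "m", arm = "3p",
    category = c("exact", "nta"), tail_type = c("none", "U"),
    weight = c(1000 * (1 - frac), 1000 * frac)), conditions = "c1")
  expect_equal(filterModified(buildProfiles(mk(0.011))), "m")
  expect_equal(length(filterModified(buildProfiles(mk(0.01)))), 0)
  expect_equal(filterModified(buildProfiles(mk(0.005)), threshold = 0), "m")
})

test_that("condition comparison recovers planted fold-change quadrants", {
  mk <- function(u, a, n = 1e5) data.frame(
    category = c("exact", "nta", "nta"), tail_type = c("none", "U", "A"),
    weight = c(n * (1 - u - a), n * u, n * a))
  tal <- rbind(cbind(sample = "wt_rep1", mirna_id = "m", arm = "3p",
                     mk(0.15, 0.12)),
               cbind(sample = "cko_rep1", mirna_id = "m", arm = "3p",
                     mk(0.02, 0.18)))
  prof <- buildProfiles(makeCube(tal))
  cmp <- compareConditions(prof, "wt", "cko")
  expect_equal(cmp$log2fc_u, log2(0.02 / 0.15), tolerance = 1e-3)
  expect_equal(cmp$log2fc_a, log2(0.18 / 0.12), tolerance = 1e-3)
  expect_equal(cmp$quadrant, "downU_upA")
  expect_false(cmp$fivefold_a_gain)

  same <- buildProfiles(makeCube(rbind(
    cbind(sample = "wt_rep1", mirna_id = "m", arm = "3p", mk(0.1, 0.1)),
    cbind(sample = "cko_rep1", mirna_id = "m", arm = "3p", mk(0.1, 0.1)))))
  cmpSame <- compareConditions(same, "wt", "cko")
  expect_equal(cmpSame$log2fc_u, 0)
  expect_equal(cmpSame$quadrant, "unchanged")

  five <- buildProfiles(makeCube(rbind(
    cbind(sample = "wt_rep1", mirna_id = "m", arm = "3p", mk(0.20, 0.01)),
    cbind(sample = "cko_rep1", mirna_id = "m", arm = "3p",
          mk(0.02, 0.06)))))
  expect_true(compareConditions(five, "wt", "cko")$fivefold_a_gain)
})

test_that("arm ratios and switch detection follow the margin rule", {
  mk <- function(cond, w5, w3) data.frame(
    sample = paste0(cond, "_rep1"), mirna_id = "m",
    arm = c("5p", "3p"), category = "exact", tail_type = "none",
    weight = c(w5, w3), stringsAsFactors = FALSE)
  cube <- makeCube(rbind(mk("wt", 1000, 2000), mk("cko", 2000, 1000)))
  ar <- armRatios(cube)
  expect_true(all(ar$ratio > 0))
  expect_equal(ar$dominant[ar$unit == "wt"], "3p")
  expect_equal(ar$dominant[ar$unit == "cko"], "5p")
  sw <- detectArmSwitch(ar, "wt", "cko")
  expect_true(sw$switch)
  expect_equal(sw$direction, "3p->5p")

  # dominant arm unchanged: no switch
  cube2 <- makeCube(rbind(mk("wt", 1000, 2000), mk("cko", 1600, 2000)))
  expect_false(detectArmSwitch(armRatios(cube2), "wt", "cko")$switch)

  # both ratios inside the balanced band: no call
  cube3 <- makeCube(rbind(mk("wt", 900, 1000), mk("cko", 1100, 1000)))
  expect_false(detectArmSwitch(armRatios(cube3), "wt", "cko")$switch)

  # single-arm miRNAs are skipped
  oneArm <- makeCube(data.frame(
    sample = c("wt_rep1", "cko_rep1"), mirna_id = "solo", arm = "3p",
    category = "exact", tail_type = "none", weight = c(100, 100)))
  expect_equal(nrow(armRatios(oneArm)), 0)
})
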