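test_that("hypergeometric enrichment matches exact combinatorics", {
  res <- hypergeomEnrich(paste0("g", 1:5),
                         list(s = paste0("g", c(1:4, 11))),
                         paste0("g", 1:10))
  expect_equal(res$p_value, 6 / 252)
  expect_equal(res[, c("k", "K", "n", "N")],
               data.frame(k = 4, K = 4, n = 5, N = 10))
  # k = 0: the >= 0 tail is certain
  res0 <- hypergeomEnrich(paste0("g", 1:3), list(s = paste0("g", 8:10)),
                          paste0("g", 1:10))
  expect_equal(res0$p_value, 1)
  # saturated query
  resAll <- hypergeomEnrich(paste0("g", 1:10),
                            list(s = paste0("g", 1:4)), paste0("g", 1:10))
  expect_equal(resAll$p_value, 1)
  expect_error(hypergeomEnrich("g1", list(s = "g1"), character()),
               "empty background")
})

test_that("hypergeometric p equals brute-force enumeration of draws", {
  bg <- paste0("g", 1:9)
  annot <- paste0("g", c(2, 3, 5, 7))
  for (n in c(3, 5)) {
    draws <- combn(9, n)
    query <- paste0("g", seq_len(n))
    kObs <- length(intersect(query, annot))
    pBrute <- mean(apply(draws, 2, function(d)
      sum(paste0("g", d) %in% annot) >= kObs))
    res <- hypergeomEnrich(query, list(s = annot), bg)
    expect_equal(res$p_value, pBrute)
  }
})

test_that("anticorrelation edge filtering respects endpoint status", {
  mirnaDE <- data.frame(feature = c("m1", "m2", "m3"),
                        log2fc = c(2, -2, 0.1),
                        q_value = c(0.001, 0.001, 0.5))
  mrnaDE <- data.frame(feature = c("t1", "t2", "t3"),
                       log2fc = c(-1.5, -1.2, 1.1),
                       q_value = c(0.002, 0.004, 0.003))
  edges <- data.frame(mirna_id = c("m1", "m2", "m3", "m1"),
                      mrna_id = c("t1", "t3", "t2", "t9"))
  out <- negativeCorrelationEdges(edges, mirnaDE, mrnaDE)
  expect_setequal(paste(out$negative$mirna_id, out$negative$mrna_id),
                  c("m1 t1", "m2 t3"))
  expect_equal(nrow(out$positive), 0)
  expect_true("m3" %in% out$dropped$mirna_id)    # ns endpoint
  expect_true("t9" %in% out$dropped$mrna_id)     # unknown node
  # same-direction significant pair lands in the positive report
  edges2 <- data.frame(mirna_id = "m2", mrna_id = "t1")  # both down
  out2 <- negativeCorrelationEdges(edges2, mirnaDE, mrnaDE)
  expect_equal(nrow(out2$negative), 0)
  expect_equal(nrow(out2$positive), 1)
  # directional mode
  out3 <- negativeCorrelationEdges(edges, mirnaDE, mrnaDE,
                                   mode = "up_mirna_down_mrna")
  expect_equal(paste(out3$negative$mirna_id, out3$negative$mrna_id),
               "m1 t1")
})

test_that("relative confluency subtracts the baseline and is idempotent", {
  s <- data.frame(time_h = c(0, 2, 4), confluency = c(5, 10, 20))
  r <- relativeConfluency(s)
  expect_equal(r$confluency, c(0, 5, 15))
  expect_equal(relativeConfluency(r)$confluency, r$confluency)
  const <- data.frame(time_h = 0:3, confluency = rep(7, 4))
  expect_equal(relativeConfluency(const)$confluency, rep(0, 4))
  expect_error(relativeConfluency(s[0, ]), "empty")
})

test_that("logistic fitting recovers noise-free parameters", {
  g <- simulateGrowth(100, 0.1, 5, times = seq(0, 72, 2), noiseSd = 0)
  f <- fitLogistic(g)
  expect_true(f$converged)
  expect_lt(abs(f$K - 100) / 100, 1e-4)
  expect_lt(abs(f$r - 0.1) / 0.1, 1e-4)
  expect_lt(abs(f$N0 - 5) / 5, 1e-4)
  expect_lt(f$p_r, 1e-6)
  # fitted curve passes through N0 at t = 0
  expect_equal(logisticCurve(0, f$K, f$r, f$N0), f$N0)
})

test_that("constant series yield the degenerate r = 0 fit", {
  flat <- data.frame(time_h = seq(0, 20, 2), confluency = rep(12, 11))
  f <- fitLogistic(flat)
  expect_true(f$converged)
  expect_equal(f$r, 0)
  expect_equal(f$p_r, 1)
  expect_equal(logisticCurve(c(0, 5, 10), f$K, f$r, f$N0),
               rep(f$N0, 3))
  expect_error(fitLogistic(data.frame(time_h = 0:2,
                                      confluency = c(1, 2, 3))),
               "4 distinct")
})

test_that("the logistic fit is scale-equivariant", {
  g <- simulateGrowth(80, 0.15, 4, times = seq(0, 60, 2), noiseSd = 0.5,
                      seed = 3)
  f1 <- fitLogistic(g)
  g2 <- g; g2$confluency <- g2$confluency * 3
  f2 <- fitLogistic(g2)
  expect_equal(f2$K / f1$K, 3, tolerance = 1e-3)
  expect_equal(f2$N0 / f1$N0, 3, tolerance = 1e-3)
  expect_equal(f2$r, f1$r, tolerance = 1e-3)
})

test_that("growth rate is recovered within 10% under 2% noise", {
  rs <- vapply(1:40, function(i) {
    g <- simulateGrowth(100, 0.1, 5, times = seq(0, 72, 2), noiseSd = 2,
                        seed = 1000 + i)
    fitLogistic(g)$r
  }, 0)
  expect_lt(abs(mean(rs) - 0.1) / 0.1, 0.10)
  expect_gt(mean(abs(rs - 0.1) / 0.1 < 0.10), 0.8)
})
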