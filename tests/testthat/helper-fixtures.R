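# Build a TailCube directly from a compact spec: a data.frame with
# columns sample, mirna_id, arm, category, tail_type, weight.
makeCube <- function(tally, conditions = NULL) {
  sn <- unique(tally$sample)
  if (is.null(conditions))
    conditions <- sub("_rep\\d+$", "", sn)
  new("TailCube", tally = tally,
      samples = data.frame(sample = sn, condition = conditions,
                           stringsAsFactors = FALSE))
}

# Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# Minimal two-condition simulation used by several tests.
smallSimConfig <- function(seed = 3, nMirnas = 10, depth = 4000,
                           errorRate = 0, uWT = 0.15, aWT = 0.12,
                           uKO = 0.02, aKO = 0.18, nReplicates = 1) {
  simConfig(seed = seed, nMirnas = nMirnas,
    conditions = list(
      wt = list(nReplicates = nReplicates, depth = depth, dispersion = 0.1,
                tailRates = c(none = 1 - uWT - aWT, U = uWT, UU = 0,
                              A = aWT, AA = 0, AU = 0, UA = 0, other = 0)),
      cko = list(nReplicates = nReplicates, depth = depth, dispersion = 0.1,
                 tailRates = c(none = 1 - uKO - aKO, U = uKO, UU = 0,
                               A = aKO, AA = 0, AU = 0, UA = 0,
                               other = 0))),
    errorRate = errorRate)
}

preprocessAll <- function(sim, ...) {
  out <- lapply(names(sim$reads), function(sn) {
    r <- preprocessReads(sim$reads[[sn]], ...)$reads
    if (nrow(r)) r$sample <- sn
    r
  })
  do.call(rbind, out[vapply(out, nrow, 1L) > 0])
}
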