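# Brute-force isomiR decomposition oracle, independent of the package's
# vectorised anchor scan: for every arm and 5' offset it enumerates all
# (templated extent, tail) split points of a read and checks the
# constraints directly, then keeps the maximal templated extent per
# anchor and the lexicographically minimal
# (mismatches, |offset5|, tail length) across anchors.
oracleClassify <- function(insert, hs, offset5Range = 2L,
                           maxInternalMismatch = 1L, maxTrim3 = 8L,
                           maxTail = 8L, minMatureCover = 10L) {
  insert <- chartr("Uu", "TT", toupper(insert))
  len <- nchar(insert)
  m <- matureArms(hs)
  seqs <- as.character(hairpinSequences(hs))
  fl <- flank3p(hs)
  cands <- list()
  for (i in seq_len(nrow(m))) {
    tmpl <- paste0(seqs[[m$hairpin_id[i]]], fl[[m$hairpin_id[i]]])
    s0 <- m$start[i]; e0 <- m$end[i]; nArm <- e0 - s0 + 1L
    for (o in seq(-offset5Range, offset5Range)) {
      anchor <- s0 + o
      if (anchor < 1L || anchor > nchar(tmpl)) next
      found <- NULL
      for (t in rev(seq_len(len))) {
        if (anchor + t - 1L > nchar(tmpl)) next
        mm <- 0L; ok <- TRUE
        for (p in seq_len(t)) {
          tpos <- anchor + p - 1L
          if (substr(insert, p, p) != substr(tmpl, tpos, tpos)) {
            if (p == t || tpos < s0 || tpos > e0 ||
                mm + 1L > maxInternalMismatch) { ok <- FALSE; break }
            mm <- mm + 1L
          }
        }
        if (ok) { found <- list(t = t, mm = mm); break }
      }
      if (is.null(found)) next
      t <- found$t
      templated3 <- (anchor + t - 1L) - e0
      tail <- substr(insert, t + 1L, len)
      cover <- min(anchor + t - 1L, e0) - max(anchor, s0) + 1L
      if (t < max(1L, 1L - o)) next
      if (templated3 < -maxTrim3) next
      if (nchar(tail) > maxTail) next
      if (cover < min(minMatureCover, nArm)) next
      cands[[length(cands) + 1L]] <-
        data.frame(mature_id = m$mature_id[i], arm = m$arm[i],
                   offset5 = o, templated3 = templated3, tail = tail,
                   mismatches = found$mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(cands))
    return(data.frame(mature_id = NA_character_, arm = NA_character_,
                      offset5 = NA_integer_, templated3 = NA_integer_,
                      tail = NA_character_, mismatches = NA_integer_,
                      category = "unassigned", stringsAsFactors = FALSE))
  cc <- do.call(rbind, cands)
  score <- cc$mismatches * 1e6 + abs(cc$offset5) * 1e3 + nchar(cc$tail)
  cc <- cc[score == min(score), , drop = FALSE]
  cc$category <- classifyCategory(cc$offset5, cc$templated3, cc$tail,
                                  cc$mismatches)
  cc[order(cc$mature_id), , drop = FALSE]
}

# A fixed toy precursor used across tests: 60-nt hairpin with 20-nt arms.
toyHairpin <- function(flank = "CGACGTACGG") {
  seq <- paste0("TTTT",                          # 5' margin
                "ACGTGCATGGATCGTACGTA",          # 5p arm (5..24)
                "CGCCTGATCCGG",                  # loop (25..36)
                "GTCCATTGCAGTTCAACGGA",          # 3p arm (37..56)
                "CCGG")                          # after 3p arm... (not used)
  # place the 3p arm at the hairpin end so templated extension runs into
  # the flank
  seq <- substr(seq, 1, 56)
  HairpinSet(
    c(toy = seq),
    data.frame(hairpin_id = "toy", mature_id = c("toy-5p", "toy-3p"),
               arm = c("5p", "3p"), start = c(5, 37), end = c(24, 56)),
    flank3p = c(toy = flank))
}

# All substrings/tails enumeration for the oracle-equivalence check.
enumerateToyReads <- function(hs, off5 = -2:2, off3 = -2:2, tailMax = 3) {
  m <- matureArms(hs)
  seqs <- as.character(hairpinSequences(hs))
  fl <- flank3p(hs)
  bases <- c("A", "C", "G", "T")
  tails <- ""
  for (k in seq_len(tailMax))
    tails <- c(tails, apply(expand.grid(rep(list(bases), k)), 1, paste,
                            collapse = ""))
  out <- list()
  for (i in seq_len(nrow(m))) {
    tmpl <- paste0(seqs[[m$hairpin_id[i]]], fl[[m$hairpin_id[i]]])
    for (o5 in off5) for (o3 in off3) {
      s <- m$start[i] + o5; e <- m$end[i] + o3
      if (s < 1 || e > nchar(tmpl) || e <= s) next
      core <- substr(tmpl, s, e)
      out[[length(out) + 1L]] <- data.frame(
        mature_id = m$mature_id[i], arm = m$arm[i], offset5 = o5,
        templated3 = o3, tail = tails,
        read = paste0(core, tails), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
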