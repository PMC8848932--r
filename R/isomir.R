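# One row per annotated mature arm with its full 3' template
# (hairpin followed by the optional genomic flank).
armIndex <- function(hs) {
  m <- hs@mature
  tmpl <- paste0(as.character(hs@sequences)[m$hairpin_id],
                 hs@flank3p[m$hairpin_id])
  data.frame(hairpin_id = m$hairpin_id, mature_id = m$mature_id,
             arm = m$arm, start = m$start, end = m$end,
             matureLen = m$end - m$start + 1L, template = tmpl,
             stringsAsFactors = FALSE)
}

firstTrueCol <- function(X) {
  f <- max.col(X, ties.method = "first")
  f[rowSums(X) == 0L] <- NA_integer_
  f
}

#' Decompose a read 3' end into templated extension and nontemplated tail
#'
#' Greedy maximal-templated rule: starting from the aligned 5' anchor, the
#' templated match is extended base by base along the hairpin and then its
#' 3' genomic flank for as long as bases agree; the remaining suffix is the
#' nontemplated tail. Up to \code{maxInternalMismatch} mismatches are
#' tolerated without stopping the extension, provided they fall inside the
#' mature region and are internal, i.e. followed by a further matching
#' templated base (the last templated base always matches). Bases aligned
#' upstream of the mature start (5' templated extension) must match
#' exactly.
#'
#' @param insert insert sequence (DNA or RNA alphabet).
#' @param template hairpin sequence concatenated with its 3' flank.
#' @param anchorPos 1-based template position the insert's first base
#'   aligns to.
#' @param matureStart,matureEnd 1-based mature interval on the template.
#' @param maxInternalMismatch tolerated internal mismatches in the mature
#'   body (default 1).
#' @return list with \code{templated3} (templated 3' extent minus mature
#'   end), \code{tail} (nontemplated suffix, DNA alphabet),
#'   \code{mismatches}, and \code{valid} (FALSE when a 5'-extension base
#'   mismatches or nothing aligns). Deterministic.
#' @examples
#' # template continues ...AC after the mature 8-mer
#' decompose3p("ACGTACGTAA", "ACGTACGTAC", 1, 1, 8)  # +1 templated, tail "A"
#' @export
decompose3p <- function(insert, template, anchorPos, matureStart,
                        matureEnd, maxInternalMismatch = 1L) {
  insert <- chartr("Uu", "TT", toupper(insert))
  template <- chartr("Uu", "TT", toupper(template))
  len <- nchar(insert)
  lastMatch <- 0L; mmUsed <- 0L; pending <- 0L
  for (p in seq_len(len)) {
    tpos <- anchorPos + p - 1L
    if (tpos > nchar(template)) break
    tb <- substr(template, tpos, tpos)
    ib <- substr(insert, p, p)
    if (ib == tb) {
      mmUsed <- mmUsed + pending; pending <- 0L; lastMatch <- p
    } else if (tpos < matureStart) {
      return(list(templated3 = NA_integer_, tail = NA_character_,
                  mismatches = NA_integer_, valid = FALSE))
    } else if (tpos <= matureEnd &&
               mmUsed + pending < maxInternalMismatch) {
      pending <- pending + 1L
    } else break
  }
  if (lastMatch == 0L)
    return(list(templated3 = NA_integer_, tail = NA_character_,
                mismatches = NA_integer_, valid = FALSE))
  list(templated3 = (anchorPos + lastMatch - 1L) - matureEnd,
       tail = substr(insert, lastMatch + 1L, len),
       mismatches = mmUsed, valid = TRUE)
}

#' Assign an isomiR taxonomy category
#'
#' Nontemplated-tail presence dominates; otherwise the call is placed by
#' its 5' offset and templated 3' offset: canonical (exact), templated 3'
#' extension (lv3pE) or trim (lv3pT), 5' extension (lv5pE) or trim
#' (lv5pT), multilength variant (mv) when both ends move. A call with
#' canonical coordinates but internal mismatches is flagged SNP-like.
#'
#' @param offset5 read start minus mature start (negative = 5' extension).
#' @param templated3 templated 3' extent minus mature end.
#' @param tail nontemplated suffix ("" for none).
#' @param mismatches internal mismatch count.
#' @return character vector of categories.
#' @export
classifyCategory <- function(offset5, templated3, tail, mismatches = 0L) {
  ifelse(!is.na(tail) & tail != "", "nta",
  ifelse(offset5 == 0 & templated3 == 0 & mismatches > 0, "snp_flagged",
  ifelse(offset5 == 0 & templated3 > 0, "lv3pE",
  ifelse(offset5 == 0 & templated3 < 0, "lv3pT",
  ifelse(templated3 == 0 & offset5 < 0, "lv5pE",
  ifelse(templated3 == 0 & offset5 > 0, "lv5pT",
  ifelse(offset5 != 0 & templated3 != 0, "mv", "exact")))))))
}

#' Type a nontemplated tail
#'
#' Maps the named mono/di additions (A, AA, AU, U, UA, UU, plus single G
#' and C), homopolymeric runs of length >= 3 (polyA/polyU), and everything
#' else to "other". "Any length" aggregations of a base cover only its
#' homopolymeric types: \{A, AA, polyA\} and \{U, UU, polyU\}.
#'
#' @param tail character vector of tails (DNA or RNA alphabet; "" = none).
#' @return character vector over
#'   none/A/AA/AU/U/UA/UU/polyA/polyU/G/C/other.
#' @export
classifyTail <- function(tail) {
  t2 <- chartr("Uu", "TT", toupper(tail))
  if (any(grepl("[^ACGT]", t2[!is.na(t2)])))
    stop("tail contains non-ACGU characters")
  named <- c("A" = "A", "AA" = "AA", "AT" = "AU", "T" = "U", "TA" = "UA",
             "TT" = "UU", "G" = "G", "C" = "C")
  out <- ifelse(is.na(t2), NA_character_,
         ifelse(t2 == "", "none",
         ifelse(t2 %in% names(named), named[t2],
         ifelse(grepl("^A{3,}$", t2), "polyA",
         ifelse(grepl("^T{3,}$", t2), "polyU", "other")))))
  unname(out)
}

#' Tail types covered by a selector
#'
#' @param selector one of "monoU", "monoA", "anyU", "anyA", a tail type, or
#'   a vector of tail types.
#' @return character vector of tail types.
#' @export
tailTypesFor <- function(selector) {
  if (length(selector) == 1L) {
    switch(selector,
           monoU = "U", monoA = "A",
           anyU = c("U", "UU", "polyU"),
           anyA = c("A", "AA", "polyA"),
           selector)
  } else selector
}

# Vectorised anchor scan over all (arm, 5' offset) pairs. Returns every
# valid candidate decomposition for each unique insert.
scanAnchors <- function(inserts, hs, offset5Range = 2L,
                        maxInternalMismatch = 1L, maxTrim3 = 8L,
                        maxTail = 8L, minMatureCover = 10L) {
  n <- length(inserts)
  idx <- armIndex(hs)
  if (!n || !nrow(idx))
    return(data.frame(insertIdx = integer(), hairpin_id = character(),
                      mature_id = character(), arm = character(),
                      offset5 = integer(), templated3 = integer(),
                      tail = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  len <- nchar(inserts)
  width <- max(len)
  M <- packSeqMatrix(inserts, width)
  colIdx <- matrix(seq_len(width), n, width, byrow = TRUE)
  out <- vector("list", nrow(idx) * (2L * offset5Range + 1L))
  oi <- 0L
  B <- maxInternalMismatch
  for (ai in seq_len(nrow(idx))) {
    arm <- idx[ai, ]
    tlen <- nchar(arm$template)
    for (o in seq(-offset5Range, offset5Range)) {
      anchorPos <- arm$start + o
      if (anchorPos < 1L || anchorPos > tlen) next
      W <- min(width, tlen - anchorPos + 1L)
      tvec <- utf8ToInt(substr(arm$template, anchorPos,
                               anchorPos + W - 1L))
      Tm <- matrix(tvec, n, W, byrow = TRUE)
      inLen <- colIdx[, seq_len(W), drop = FALSE] <=
        matrix(len, n, W)
      Mb <- M[, seq_len(W), drop = FALSE]
      E <- (Mb == Tm) & inLen
      X <- (Mb != Tm) & inLen
      lo <- max(1L, 1L - o)
      hi <- arm$matureLen - o
      badPre <- if (lo > 1L)
        rowSums(X[, seq_len(lo - 1L), drop = FALSE]) > 0L
      else rep(FALSE, n)
      X2 <- X
      if (lo > 1L) X2[, seq_len(lo - 1L)] <- FALSE
      # first B+1 mismatch columns (at/after the mature start)
      mcols <- matrix(NA_integer_, n, B + 1L)
      Xs <- X2
      for (k in seq_len(B + 1L)) {
        f <- firstTrueCol(Xs)
        mcols[, k] <- f
        ok <- !is.na(f)
        if (!any(ok)) break
        Xs[cbind(which(ok), f[ok])] <- FALSE
      }
      # first mismatch beyond the mature 3' end cannot be crossed
      X3 <- X2
      if (hi >= 1L && hi < W) X3[, seq_len(min(hi, W))] <- FALSE
      else if (hi >= W) X3[] <- FALSE
      q <- firstTrueCol(X3)
      capBudget <- mcols[, B + 1L]
      cap <- pmin(ifelse(is.na(capBudget), W, capBudget - 1L),
                  ifelse(is.na(q), W, q - 1L), len, W)
      Ec <- E & (colIdx[, seq_len(W), drop = FALSE] <=
                   matrix(cap, n, W))
      t <- W + 1L - max.col(Ec[, W:1, drop = FALSE],
                            ties.method = "first")
      t[rowSums(Ec) == 0L] <- 0L
      nmm <- rowSums(!is.na(mcols[, seq_len(B), drop = FALSE]) &
                       mcols[, seq_len(B), drop = FALSE] < t)
      templated3 <- o + t - arm$matureLen
      tailLen <- len - t
      cover <- pmin(t, hi) - lo + 1L
      valid <- !badPre & t >= lo & t >= 1L &
        templated3 >= -maxTrim3 & tailLen <= maxTail &
        cover >= min(minMatureCover, arm$matureLen)
      if (!any(valid)) next
      w <- which(valid)
      oi <- oi + 1L
      out[[oi]] <- data.frame(
        insertIdx = w, hairpin_id = arm$hairpin_id,
        mature_id = arm$mature_id, arm = arm$arm, offset5 = o,
        templated3 = templated3[w],
        tail = substr(inserts[w], t[w] + 1L, len[w]),
        mismatches = as.integer(nmm[w]), stringsAsFactors = FALSE)
    }
  }
  if (!oi) return(scanAnchors(character(0), hs))
  do.call(rbind, c(out[seq_len(oi)], make.row.names = FALSE))
}

#' Resolve multi-mapping candidate assignments
#'
#' Keeps, per insert, the candidates minimising
#' (internal mismatches, |5' offset|, tail length) lexicographically.
#' Surviving ties either share the read weight equally ("split", default)
#' or collapse to the lexicographically smallest mature id ("unique").
#'
#' @param candidates candidate table from the anchor scan.
#' @param mode "split" or "unique".
#' @return the surviving candidates with a \code{weight} column; weights
#'   of one insert sum to 1.
#' @export
resolveMultimap <- function(candidates, mode = c("split", "unique")) {
  mode <- match.arg(mode)
  if (!nrow(candidates)) {
    candidates$weight <- numeric()
    return(candidates)
  }
  score <- candidates$mismatches * 1e6 + abs(candidates$offset5) * 1e3 +
    nchar(candidates$tail)
  best <- stats::ave(score, candidates$insertIdx, FUN = min)
  keep <- candidates[score == best, , drop = FALSE]
  if (mode == "unique") {
    keep <- keep[order(keep$insertIdx, keep$mature_id), , drop = FALSE]
    keep <- keep[!duplicated(keep$insertIdx), , drop = FALSE]
    keep$weight <- 1
  } else {
    ties <- stats::ave(rep(1, nrow(keep)), keep$insertIdx, FUN = sum)
    keep$weight <- 1 / ties
  }
  keep
}

#' Classify processed inserts into isomiR calls
#'
#' Matches each insert against every mature arm at 5' offsets within
#' \code{offset5Range}, decomposes the 3' end by the greedy
#' maximal-templated rule (see \code{\link{decompose3p}}), resolves
#' multi-mapping, and attaches the taxonomy category and tail type. Reads
#' with no acceptable candidate are reported as unassigned.
#'
#' @param reads data.frame with columns \code{insert} and optionally
#'   \code{id}, \code{sample}; or a character vector of inserts.
#' @param hs a \code{\link{HairpinSet-class}}.
#' @param offset5Range maximum |5' offset| (default 2).
#' @param maxInternalMismatch tolerated internal mismatches (default 1).
#' @param maxTrim3 maximum templated 3' trim (default 8).
#' @param maxTail maximum nontemplated tail length (default 8).
#' @param minMatureCover minimum mature bases an insert must cover
#'   (default 10).
#' @param multimap multi-mapper handling, "split" or "unique".
#' @return data.frame with one row per (read, assignment): read id,
#'   sample, miRNA/hairpin id, mature id, arm, offset5, templated3, tail
#'   (RNA alphabet), internal mismatches, category, tail_type, weight.
#'   Weights per read sum to 1.
#' @export
classifyReads <- function(reads, hs, offset5Range = 2L,
                          maxInternalMismatch = 1L, maxTrim3 = 8L,
                          maxTail = 8L, minMatureCover = 10L,
                          multimap = "split") {
  if (is.character(reads))
    reads <- data.frame(id = paste0("read", seq_along(reads)),
                        insert = reads, stringsAsFactors = FALSE)
  if (is.null(reads$id)) reads$id <- paste0("read", seq_len(nrow(reads)))
  if (is.null(reads$sample))
    reads$sample <- rep("sample1", nrow(reads))
  ins <- chartr("Uu", "TT", toupper(reads$insert))
  uniq <- unique(ins)
  cand <- scanAnchors(uniq, hs, offset5Range, maxInternalMismatch,
                      maxTrim3, maxTail, minMatureCover)
  res <- resolveMultimap(cand, multimap)
  res$category <- classifyCategory(res$offset5, res$templated3, res$tail,
                                   res$mismatches)
  res$tail_type <- classifyTail(res$tail)
  # expand unique-insert calls back onto reads
  perIns <- split(seq_len(nrow(res)), res$insertIdx)
  readUniq <- match(ins, uniq)
  rows <- perIns[as.character(readUniq)]
  nAssign <- lengths(rows)
  hasCall <- nAssign > 0L
  repRead <- rep(which(hasCall), nAssign[hasCall])
  callRows <- unlist(rows[hasCall], use.names = FALSE)
  assigned <- data.frame(
    read_id = reads$id[repRead], sample = reads$sample[repRead],
    mirna_id = res$hairpin_id[callRows],
    mature_id = res$mature_id[callRows], arm = res$arm[callRows],
    offset5 = res$offset5[callRows],
    templated3 = res$templated3[callRows],
    tail = chartr("T", "U", res$tail[callRows]),
    internal_mismatches = res$mismatches[callRows],
    category = res$category[callRows],
    tail_type = res$tail_type[callRows],
    weight = res$weight[callRows], stringsAsFactors = FALSE)
  if (any(!hasCall)) {
    un <- data.frame(
      read_id = reads$id[!hasCall], sample = reads$sample[!hasCall],
      mirna_id = NA_character_, mature_id = NA_character_,
      arm = NA_character_, offset5 = NA_integer_,
      templated3 = NA_integer_, tail = NA_character_,
      internal_mismatches = NA_integer_, category = "unassigned",
      tail_type = NA_character_, weight = 1, stringsAsFactors = FALSE)
    assigned <- rbind(assigned, un)
  }
  assigned
}

#' Aggregate isomiR calls into a TailCube
#'
#' Sums assignment weights by (sample, miRNA, arm, category, tail type).
#' Unassigned reads are excluded from the cube and reported via the
#' \code{nUnassigned} attribute of the tally.
#'
#' @param calls call table from \code{\link{classifyReads}}.
#' @param samples optional data.frame with columns \code{sample},
#'   \code{condition}; by default the condition is the sample name with a
#'   trailing "_rep<k>" stripped.
#' @return a \code{\link{TailCube-class}}.
#' @export
tallyCalls <- function(calls, samples = NULL) {
  ok <- calls$category != "unassigned"
  x <- calls[ok, , drop = FALSE]
  key <- paste(x$sample, x$mirna_id, x$arm, x$category, x$tail_type,
               sep = "\r")
  agg <- rowsum(x$weight, key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  tally <- data.frame(sample = parts[, 1], mirna_id = parts[, 2],
                      arm = parts[, 3], category = parts[, 4],
                      tail_type = parts[, 5], weight = as.numeric(agg),
                      stringsAsFactors = FALSE)
  attr(tally, "nUnassigned") <- sum(!ok)
  if (is.null(samples)) {
    sn <- unique(calls$sample)
    samples <- data.frame(sample = sn, condition = sub("_rep\\d+$", "", sn),
                          stringsAsFactors = FALSE)
  }
  new("TailCube", tally = tally, samples = samples)
}
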