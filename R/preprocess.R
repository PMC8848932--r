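# Pack sequences of varying length into an integer matrix (one row per
# read, one column per base, 0 beyond the read end). Used by the adapter
# scanner and the isomiR classifier, where vectorised column comparisons
# beat per-read loops by orders of magnitude.
packSeqMatrix <- function(seqs, width = max(nchar(seqs))) {
  n <- length(seqs)
  padded <- sprintf(sprintf("%%-%ds", width), seqs)   # right-pad w/ spaces
  padded <- substr(padded, 1, width)
  ints <- utf8ToInt(paste(padded, collapse = ""))
  ints[ints == 32L] <- 0L
  matrix(ints, nrow = n, ncol = width, byrow = TRUE)
}

#' Trim the 3' adapter from reads
#'
#' Removes the adapter at the leftmost position where a prefix of the
#' adapter aligns with at most \code{maxMismatchRate} mismatches. The
#' aligned prefix must be at least \code{minOverlap} long, except at the
#' read's 3' terminus where partial prefixes down to 3 nt are accepted
#' (the window runs off the read end). Reads with no acceptable match are
#' flagged \code{no_adapter}.
#'
#' @param seqs character vector of read sequences.
#' @param adapter adapter sequence (default NEXTFlex small RNA 3' adapter).
#' @param minOverlap minimum aligned adapter prefix away from the terminus
#'   (>= 3; default 10).
#' @param maxMismatchRate maximum fraction of mismatching bases in the
#'   aligned prefix (default 0.1).
#' @return list with \code{trimmed} (character, NA where no adapter) and
#'   \code{status} ("kept"/"no_adapter").
#' @export
trimAdapter <- function(seqs, adapter = "TGGAATTCTCGGGTGCCAAGG",
                        minOverlap = 10L, maxMismatchRate = 0.1) {
  stopifnot(nzchar(adapter), minOverlap >= 3)
  n <- length(seqs)
  if (!n) return(list(trimmed = character(), status = character()))
  len <- nchar(seqs)
  width <- max(len)
  M <- packSeqMatrix(seqs, width)
  a <- utf8ToInt(adapter)
  A <- length(a)
  trimPos <- rep(NA_integer_, n)
  for (p in seq_len(width)) {
    open <- is.na(trimPos) & len >= p
    if (!any(open)) break
    w <- min(A, width - p + 1L)
    block <- M[, p:(p + w - 1L), drop = FALSE]
    inLen <- sweep(col(block), 1, len - p + 1L, "<=")
    mm <- rowSums((block != matrix(a[seq_len(w)], n, w, byrow = TRUE)) &
                    inLen)
    overlap <- pmin(A, len - p + 1L)
    valid <- overlap >= 3L &
      (overlap >= minOverlap | (len - p + 1L) <= A)
    hit <- open & valid & mm <= floor(maxMismatchRate * overlap)
    trimPos[hit] <- p
  }
  trimmed <- ifelse(is.na(trimPos), NA_character_,
                    substr(seqs, 1L, trimPos - 1L))
  list(trimmed = trimmed,
       status = ifelse(is.na(trimPos), "no_adapter", "kept"))
}

#' Strip terminal UMIs from adapter-trimmed reads
#'
#' NEXTFlex libraries carry \code{umiLength} random bases at both insert
#' ends; both are removed and retained for deduplication.
#'
#' @param trimmed character vector of adapter-trimmed sequences.
#' @param umiLength UMI length (default 4; 0 is the identity).
#' @return list with \code{umi5}, \code{insert}, \code{umi3} and
#'   \code{status} ("kept"/"too_short"; too short means length <=
#'   2 * umiLength).
#' @export
stripUMIs <- function(trimmed, umiLength = 4L) {
  len <- nchar(trimmed)
  ok <- !is.na(trimmed) & len > 2L * umiLength
  list(umi5 = ifelse(ok, substr(trimmed, 1L, umiLength), NA),
       insert = ifelse(ok, substr(trimmed, umiLength + 1L,
                                  len - umiLength), NA),
       umi3 = ifelse(ok, substr(trimmed, len - umiLength + 1L, len), NA),
       status = ifelse(ok, "kept", "too_short"))
}

#' Collapse PCR duplicates by exact UMI + insert identity
#'
#' Reads with an identical (umi5, insert, umi3) triple collapse to the
#' first-encountered representative. No edit-distance UMI clustering is
#' attempted.
#'
#' @param reads data.frame with columns \code{umi5}, \code{insert},
#'   \code{umi3} (kept reads only).
#' @return list with \code{reads} (deduplicated data.frame) and
#'   \code{report} (nInput, nKept, duplicationRate; rate is 0 for empty
#'   input).
#' @export
dedupUMI <- function(reads) {
  nIn <- nrow(reads)
  if (!nIn)
    return(list(reads = reads,
                report = data.frame(nInput = 0L, nKept = 0L,
                                    duplicationRate = 0)))
  key <- paste(reads$umi5, reads$insert, reads$umi3, sep = "\r")
  keep <- !duplicated(key)
  list(reads = reads[keep, , drop = FALSE],
       report = data.frame(nInput = nIn, nKept = sum(keep),
                           duplicationRate = 1 - sum(keep) / nIn))
}

#' Filter inserts by length
#'
#' @param inserts character vector.
#' @param minLen,maxLen inclusive bounds (defaults 16 and 28 nt, bracketing
#'   mature miRNAs plus tails).
#' @return status vector: "kept"/"too_short"/"too_long".
#' @export
lengthFilter <- function(inserts, minLen = 16L, maxLen = 28L) {
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  len <- nchar(inserts)
  ifelse(len < minLen, "too_short", ifelse(len > maxLen, "too_long", "kept"))
}

#' Preprocess a NEXTFlex small RNA sample
#'
#' Runs adapter trimming, UMI stripping, length filtering and (optionally)
#' UMI deduplication, with a per-status accounting that conserves read
#' counts: kept + no_adapter + too_short + too_long equals the input.
#'
#' @param reads a FASTQ path or a data.frame with columns \code{id},
#'   \code{seq}.
#' @param adapter,minOverlap,maxMismatchRate see \code{\link{trimAdapter}}.
#' @param umiLength see \code{\link{stripUMIs}}.
#' @param minLen,maxLen see \code{\link{lengthFilter}}.
#' @param dedup collapse PCR duplicates (default TRUE).
#' @param discardUntrimmed drop reads without an adapter match (default
#'   TRUE; an insert without adapter has ambiguous 3' UMI placement).
#' @return list with \code{reads} (data.frame id/insert/umi5/umi3 of kept,
#'   deduplicated reads) and \code{qc} (status counts and duplication
#'   report).
#' @export
preprocessReads <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                            minOverlap = 10L, maxMismatchRate = 0.1,
                            umiLength = 4L, minLen = 16L, maxLen = 28L,
                            dedup = TRUE, discardUntrimmed = TRUE) {
  if (is.character(reads) && length(reads) == 1L) reads <- readFastq(reads)
  nIn <- nrow(reads)
  tr <- trimAdapter(reads$seq, adapter, minOverlap, maxMismatchRate)
  status <- tr$status
  um <- stripUMIs(tr$trimmed, umiLength)
  status[status == "kept" & um$status == "too_short"] <- "too_short"
  lf <- rep(NA_character_, nIn)
  sel <- status == "kept"
  lf[sel] <- lengthFilter(um$insert[sel], minLen, maxLen)
  status[sel] <- lf[sel]
  kept <- data.frame(id = reads$id, insert = um$insert, umi5 = um$umi5,
                     umi3 = um$umi3,
                     stringsAsFactors = FALSE)[status == "kept", ,
                                               drop = FALSE]
  dd <- if (dedup) dedupUMI(kept) else
    list(reads = kept, report = data.frame(nInput = nrow(kept),
                                           nKept = nrow(kept),
                                           duplicationRate = 0))
  counts <- c(input = nIn,
              kept = sum(status == "kept"),
              no_adapter = sum(status == "no_adapter"),
              too_short = sum(status == "too_short"),
              too_long = sum(status == "too_long"))
  if (!discardUntrimmed && any(status == "no_adapter"))
    warning("discardUntrimmed = FALSE is not supported for UMI libraries; ",
            "untrimmed reads are still excluded from the insert table")
  list(reads = dd$reads,
       qc = list(statusCounts = counts, dedup = dd$report))
}
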