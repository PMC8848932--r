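#' Construct a HairpinSet
#'
#' Builds and validates a miRNA reference from precursor sequences and a
#' mature-arm coordinate table. Input sequences may be in RNA (U) or DNA
#' (T) alphabet; both are normalised to DNA internally. Coordinates are
#' 1-based inclusive, following the miRBase GFF convention.
#'
#' @param sequences named character vector or \code{DNAStringSet} of
#'   hairpin precursors.
#' @param mature data.frame with columns \code{hairpin_id},
#'   \code{mature_id}, \code{arm}, \code{start}, \code{end}.
#' @param flank3p optional named character of downstream genomic sequence
#'   per hairpin; missing hairpins get "".
#' @param let7 optional data.frame with columns \code{mirna_id},
#'   \code{group}, \code{csd}.
#' @return a validated \code{\link{HairpinSet-class}} object. Hairpins with
#'   no annotated arm are rejected.
#' @examples
#' hs <- HairpinSet(
#'   c(hp1 = "ACGUACGUACGUACGUACGU"),
#'   data.frame(hairpin_id = "hp1", mature_id = c("hp1-5p", "hp1-3p"),
#'              arm = c("5p", "3p"), start = c(1, 13), end = c(8, 20)))
#' loopRegion(hs, "hp1")   # c(9, 12)
#' @export
HairpinSet <- function(sequences, mature, flank3p = NULL, let7 = NULL) {
  if (is.character(sequences)) {
    sequences <- toupper(chartr("Uu", "TT", sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  mature <- as.data.frame(mature, stringsAsFactors = FALSE)
  mature$start <- as.integer(mature$start)
  mature$end <- as.integer(mature$end)
  if (any(is.na(mature$start)) || any(is.na(mature$end)))
    stop("mature intervals must parse as positive integers")
  if (is.null(flank3p)) flank3p <- character()
  flank3p <- toupper(chartr("Uu", "TT", flank3p))
  fl <- setNames(rep("", length(sequences)), names(sequences))
  fl[intersect(names(flank3p), names(fl))] <-
    flank3p[intersect(names(flank3p), names(fl))]
  if (is.null(let7)) {
    let7 <- data.frame(mirna_id = character(), group = character(),
                       csd = character(), stringsAsFactors = FALSE)
  } else {
    let7 <- as.data.frame(let7, stringsAsFactors = FALSE)
  }
  new("HairpinSet", sequences = sequences, mature = mature,
      flank3p = fl, let7 = let7)
}

#' Read a miRNA reference from FASTA plus a coordinate table
#'
#' @param hairpinFasta path to a FASTA of precursor sequences.
#' @param coordsFile path to a TSV with columns \code{hairpin_id},
#'   \code{arm}, \code{start}, \code{end}, \code{mature_id}.
#' @param let7File optional TSV with columns \code{mirna_id},
#'   \code{group}, \code{csd}.
#' @param dropArmless if TRUE (default), FASTA records without any
#'   coordinate row are skipped with a message rather than rejected.
#' @return a \code{\link{HairpinSet-class}}. Ids present in the table but
#'   absent from the FASTA are a hard error.
#' @export
readHairpinSet <- function(hairpinFasta, coordsFile, let7File = NULL,
                           dropArmless = TRUE) {
  seqs <- Biostrings::readDNAStringSet(hairpinFasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  coords <- utils::read.delim(coordsFile, stringsAsFactors = FALSE)
  missing <- setdiff(coords$hairpin_id, names(seqs))
  if (length(missing))
    stop("coordinate table references id absent from FASTA: ", missing[1])
  armless <- setdiff(names(seqs), coords$hairpin_id)
  if (length(armless)) {
    if (!dropArmless)
      stop("hairpin without mature coordinates: ", armless[1])
    message("skipping ", length(armless), " hairpin(s) with no mature arm: ",
            paste(utils::head(armless, 5), collapse = ", "))
    seqs <- seqs[setdiff(names(seqs), armless)]
  }
  let7 <- if (!is.null(let7File))
    utils::read.delim(let7File, stringsAsFactors = FALSE) else NULL
  HairpinSet(as.character(seqs), coords, let7 = let7)
}

#' Write a HairpinSet back to FASTA + coordinate table
#'
#' Inverse of \code{\link{readHairpinSet}}: round-tripping reproduces an
#' identical object (DNA alphabet).
#'
#' @param hs a \code{HairpinSet}.
#' @param fastaFile,coordsFile,let7File output paths (\code{let7File} only
#'   written when annotations are present and a path is given).
#' @return invisibly, the paths written.
#' @export
writeHairpinSet <- function(hs, fastaFile, coordsFile, let7File = NULL) {
  Biostrings::writeXStringSet(hs@sequences, fastaFile)
  cols <- c("hairpin_id", "arm", "start", "end", "mature_id")
  utils::write.table(hs@mature[, cols], coordsFile, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- c(fastaFile, coordsFile)
  if (!is.null(let7File) && nrow(hs@let7)) {
    utils::write.table(hs@let7, let7File, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, let7File)
  }
  invisible(out)
}

#' @describeIn HairpinSet-class hairpin identifiers.
#' @param hs a \code{HairpinSet}.
#' @export
hairpinIds <- function(hs) names(hs@sequences)

#' @describeIn HairpinSet-class the mature-arm coordinate table.
#' @export
matureArms <- function(hs) hs@mature

#' @describeIn HairpinSet-class the let-7-like annotation table.
#' @export
let7Annotation <- function(hs) hs@let7

#' @describeIn HairpinSet-class hairpin sequences as a \code{DNAStringSet}.
#' @export
hairpinSequences <- function(hs) hs@sequences

#' @describeIn HairpinSet-class downstream genomic flank per hairpin.
#' @export
flank3p <- function(hs) hs@flank3p

#' Mature arm sequence
#'
#' @param hs a \code{HairpinSet}.
#' @param hairpinId hairpin identifier.
#' @param arm "5p" or "3p".
#' @return the mature sequence (DNA alphabet) or NA if the arm is absent.
#' @export
matureSequence <- function(hs, hairpinId, arm) {
  m <- hs@mature
  row <- m[m$hairpin_id == hairpinId & m$arm == arm, ]
  if (!nrow(row)) return(NA_character_)
  substr(as.character(hs@sequences[[hairpinId]]), row$start[1], row$end[1])
}

#' Loop region of a precursor
#'
#' The region between the two mature arms, \code{[end(5p)+1, start(3p)-1]}
#' in 1-based hairpin coordinates. Only derivable when both arms are
#' annotated.
#'
#' @param hs a \code{HairpinSet}.
#' @param hairpinId hairpin identifier.
#' @return integer \code{c(start, end)}, or NULL if either arm is missing.
#' @export
loopRegion <- function(hs, hairpinId) {
  m <- hs@mature[hs@mature$hairpin_id == hairpinId, ]
  if (!all(c("5p", "3p") %in% m$arm)) return(NULL)
  c(m$end[m$arm == "5p"][1] + 1L, m$start[m$arm == "3p"][1] - 1L)
}

#' Scan precursors for the LIN28A cold-shock-domain motif
#'
#' Searches for the (U)GAU motif bound by the cold-shock domain of LIN28A,
#' read as U-optional (regex \code{U?GAU}, i.e. any GAU occurrence). By
#' default only the loop region between the two arms is searched; hairpins
#' without a derivable loop are reported as "unknown".
#'
#' @param hs a \code{HairpinSet}.
#' @param region "loop" (default) or "precursor" to search the whole
#'   hairpin.
#' @return named character vector over hairpins with values
#'   "plus"/"minus"/"unknown". Deterministic and invariant under U/T input
#'   alphabet.
#' @export
scanCSDMotif <- function(hs, region = c("loop", "precursor")) {
  region <- match.arg(region)
  ids <- hairpinIds(hs)
  out <- setNames(rep("unknown", length(ids)), ids)
  seqs <- as.character(hs@sequences)
  for (id in ids) {
    if (region == "precursor") {
      target <- seqs[[id]]
    } else {
      lp <- loopRegion(hs, id)
      if (is.null(lp)) next
      target <- substr(seqs[[id]], lp[1], lp[2])
    }
    # U?GAU with U-optional reduces to a GAU (GAT in DNA space) match
    out[id] <- if (grepl("GAT", target, fixed = TRUE)) "plus" else "minus"
  }
  out
}

#' Classify let-7-like precursors into overhang x CSD classes
#'
#' Combines the annotation-supplied Group I/II label (2-nt vs 1-nt 3'
#' overhang after Drosha processing; no folding is attempted) with the CSD
#' motif status. When the annotation marks \code{csd} as "unknown", the
#' motif scan (\code{\link{scanCSDMotif}}) fills it in; an annotated
#' plus/minus is never overridden.
#'
#' @param hs a \code{HairpinSet} carrying a let-7 annotation table.
#' @param region motif search region passed to \code{scanCSDMotif}.
#' @return data.frame with columns \code{mirna_id}, \code{group},
#'   \code{csd}, \code{class} (e.g. "Group II / CSD+"); hairpins absent
#'   from the annotation are returned as "unclassified".
#' @export
classifyLet7 <- function(hs, region = "loop") {
  ann <- hs@let7
  ids <- hairpinIds(hs)
  motif <- scanCSDMotif(hs, region = region)
  out <- data.frame(mirna_id = ids, group = NA_character_,
                    csd = NA_character_, class = "unclassified",
                    stringsAsFactors = FALSE)
  if (!nrow(ann)) return(out)
  idx <- match(out$mirna_id, ann$mirna_id)
  hit <- !is.na(idx)
  out$group[hit] <- ann$group[idx[hit]]
  out$csd[hit] <- ann$csd[idx[hit]]
  fill <- hit & out$csd == "unknown"
  out$csd[fill] <- motif[out$mirna_id[fill]]
  ok <- hit & out$csd %in% c("plus", "minus")
  out$class[ok] <- paste0("Group ", out$group[ok], " / CSD",
                          ifelse(out$csd[ok] == "plus", "+", "-"))
  out
}
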