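#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom stats kmeans median p.adjust phyper pnorm prcomp pt quantile
#'   rbinom rnbinom rnorm rpois runif sd setNames var lm coef ave residuals
#' @importFrom utils read.delim write.table head
NULL

TAIL_TYPES <- c("none", "A", "AA", "AU", "U", "UA", "UU",
                "polyA", "polyU", "G", "C", "other")

ISOMIR_CATEGORIES <- c("exact", "lv5pE", "lv5pT", "lv3pE", "lv3pT", "mv",
                       "nta", "snp_flagged", "unassigned")

#' HairpinSet: miRNA precursors with annotated mature arms
#'
#' Container for a miRNA reference: precursor (hairpin) sequences, the
#' 1-based inclusive coordinates of the mature 5p/3p arms on each hairpin,
#' an optional downstream genomic flank used to extend the 3' template, and
#' an optional let-7-like annotation (Group I/II overhang class and
#' cold-shock-domain motif status).
#'
#' Sequences are stored in the DNA alphabet; U in any input is normalised
#' to T on construction, so motif and tail logic is alphabet-invariant.
#'
#' @slot sequences \code{DNAStringSet} of hairpin precursors.
#' @slot mature \code{data.frame} with columns \code{hairpin_id},
#'   \code{mature_id}, \code{arm} ("5p"/"3p"), \code{start}, \code{end}
#'   (1-based inclusive on the hairpin).
#' @slot flank3p named \code{character}, downstream genomic sequence per
#'   hairpin (possibly "").
#' @slot let7 \code{data.frame} with columns \code{mirna_id},
#'   \code{group} ("I"/"II") and \code{csd} ("plus"/"minus"/"unknown");
#'   may have zero rows.
#'
#' @export
setClass("HairpinSet",
  representation(
    sequences = "DNAStringSet",
    mature    = "data.frame",
    flank3p   = "character",
    let7      = "data.frame"
  )
)

setValidity("HairpinSet", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "hairpin sequences must have unique names")
  m <- object@mature
  need <- c("hairpin_id", "mature_id", "arm", "start", "end")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("mature table must have columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) return(msg)
  bad <- setdiff(m$hairpin_id, ids)
  if (length(bad))
    msg <- c(msg, paste0("mature coordinates reference unknown hairpin id: ",
                         bad[1]))
  if (!all(m$arm %in% c("5p", "3p")))
    msg <- c(msg, "arm must be '5p' or '3p'")
  len <- setNames(Biostrings::width(object@sequences), ids)
  if (any(m$start < 1 | m$end > len[m$hairpin_id] | m$start > m$end))
    msg <- c(msg, "interval out of bounds")
  # every hairpin must carry at least one arm
  if (!all(ids %in% m$hairpin_id))
    msg <- c(msg, "hairpin without any annotated mature arm")
  # if both arms present: 5p strictly upstream of 3p
  for (id in unique(m$hairpin_id[duplicated(m$hairpin_id)])) {
    sub <- m[m$hairpin_id == id, ]
    if (all(c("5p", "3p") %in% sub$arm)) {
      e5 <- sub$end[sub$arm == "5p"]
      s3 <- sub$start[sub$arm == "3p"]
      if (e5 >= s3)
        msg <- c(msg, paste0("5p arm must end before 3p arm starts: ", id))
      if (e5 + 1 > s3 - 1)
        msg <- c(msg, paste0("empty loop region: ", id))
    }
  }
  if (!identical(sort(names(object@flank3p)), sort(ids)))
    msg <- c(msg, "flank3p must be named per hairpin id")
  if (nrow(object@let7)) {
    if (!all(c("mirna_id", "group", "csd") %in% names(object@let7)))
      msg <- c(msg, "let7 table needs mirna_id, group, csd")
    else {
      if (!all(object@let7$mirna_id %in% ids))
        msg <- c(msg, "let7 annotation references unknown hairpin id")
      if (!all(object@let7$group %in% c("I", "II")))
        msg <- c(msg, "let7 group must be 'I' or 'II'")
      if (!all(object@let7$csd %in% c("plus", "minus", "unknown")))
        msg <- c(msg, "let7 csd must be plus/minus/unknown")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HairpinSet", function(object) {
  cat("HairpinSet with", length(object@sequences), "hairpins,",
      nrow(object@mature), "mature arms\n")
  both <- sum(table(object@mature$hairpin_id) == 2)
  cat("  hairpins with both arms:", both, "\n")
  if (nrow(object@let7))
    cat("  let-7-like annotations:", nrow(object@let7), "\n")
})

#' SimConfig: parameters of the synthetic small RNA experiment
#'
#' Describes the generative model of the synthetic-data module: number of
#' precursors, per-condition sequencing depth, negative-binomial dispersion
#' and nontemplated tail-type rates, templated 3'/5' trim-extend rates, arm
#' usage bias, per-base error rate and the NEXTFlex library structure (4-nt
#' UMIs at both insert ends plus a fixed 3' adapter). The whole generator
#' is a pure function of a SimConfig: a fixed seed gives byte-identical
#' output.
#'
#' @slot seed integer master seed; per-sample streams are derived from it.
#' @slot nMirnas number of simulated precursors.
#' @slot hairpinLength precursor length in nt.
#' @slot conditions named list; each element has \code{nReplicates},
#'   \code{depth}, \code{dispersion} and \code{tailRates} (named over
#'   none/U/UU/A/AA/AU/UA/other, summing to 1).
#' @slot armBias per-miRNA 5p usage fraction (scalar recycled).
#' @slot deEffects named numeric, per-miRNA log2 fold change of the second
#'   condition relative to the first (empty = none).
#' @slot trimExtendRates named numeric over
#'   canonical/ext1/ext2/trim1/trim2/shift5m/shift5p, summing to 1.
#' @slot errorRate per-base substitution probability.
#' @slot umiLength UMI length at each insert end.
#' @slot adapter 3' adapter sequence.
#' @slot let7Fraction fraction of precursors flagged let-7-like.
#' @slot csdFraction fraction of let-7-like precursors with a planted
#'   (U)GAU loop motif.
#' @slot gcGuard number of template bases immediately downstream of each
#'   mature 3' end drawn from \{C,G\} so that nontemplated U/A tails on
#'   untrimmed 3' ends cannot mimic the template (0 disables).
#' @slot flankLength length of the simulated downstream genomic flank.
#'
#' @export
setClass("SimConfig",
  representation(
    seed            = "integer",
    nMirnas         = "integer",
    hairpinLength   = "integer",
    conditions      = "list",
    armBias         = "numeric",
    deEffects       = "numeric",
    trimExtendRates = "numeric",
    errorRate       = "numeric",
    umiLength       = "integer",
    adapter         = "character",
    let7Fraction    = "numeric",
    csdFraction     = "numeric",
    gcGuard         = "integer",
    flankLength     = "integer"
  )
)

TAIL_RATE_KEYS <- c("none", "U", "UU", "A", "AA", "AU", "UA", "other")
TRIMEXT_KEYS   <- c("canonical", "ext1", "ext2", "trim1", "trim2",
                    "shift5m", "shift5p")

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nMirnas < 0) msg <- c(msg, "nMirnas must be >= 0")
  if (object@hairpinLength < 50)
    msg <- c(msg, "hairpin too short to host both arms")
  for (nm in names(object@conditions)) {
    cn <- object@conditions[[nm]]
    tr <- cn$tailRates
    if (!setequal(names(tr), TAIL_RATE_KEYS))
      msg <- c(msg, paste0("condition '", nm, "': tailRates must be named ",
                           paste(TAIL_RATE_KEYS, collapse = "/")))
    else if (abs(sum(tr) - 1) > 1e-9 || any(tr < 0))
      msg <- c(msg, paste0("condition '", nm,
                           "': tailRates must be >= 0 and sum to 1"))
    if (is.null(cn$depth) || cn$depth <= 0)
      msg <- c(msg, paste0("condition '", nm, "': depth must be > 0"))
    if (is.null(cn$nReplicates) || cn$nReplicates < 1)
      msg <- c(msg, paste0("condition '", nm, "': nReplicates must be >= 1"))
    if (is.null(cn$dispersion) || cn$dispersion < 0)
      msg <- c(msg, paste0("condition '", nm, "': dispersion must be >= 0"))
  }
  te <- object@trimExtendRates
  if (!setequal(names(te), TRIMEXT_KEYS))
    msg <- c(msg, paste("trimExtendRates must be named",
                        paste(TRIMEXT_KEYS, collapse = "/")))
  else if (abs(sum(te) - 1) > 1e-9 || any(te < 0))
    msg <- c(msg, "trimExtendRates must be >= 0 and sum to 1")
  if (any(object@armBias < 0 | object@armBias > 1))
    msg <- c(msg, "armBias must be in [0,1]")
  if (object@errorRate < 0 || object@errorRate > 0.5)
    msg <- c(msg, "errorRate must be in [0, 0.5]")
  if (object@umiLength < 0) msg <- c(msg, "umiLength must be >= 0")
  if (!nzchar(object@adapter)) msg <- c(msg, "adapter must be non-empty")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nMirnas, "miRNAs,",
      length(object@conditions), "conditions (",
      paste(names(object@conditions), collapse = ", "), ")\n")
  for (nm in names(object@conditions)) {
    cn <- object@conditions[[nm]]
    cat(sprintf("  %s: %d replicates, depth %g, mono-U %.3f, mono-A %.3f\n",
                nm, cn$nReplicates, cn$depth,
                cn$tailRates[["U"]], cn$tailRates[["A"]]))
  }
  cat("  errorRate", object@errorRate, "| seed", object@seed, "\n")
})

#' TailCube: aggregated weighted isomiR call counts
#'
#' Long-format aggregation of per-read isomiR calls: one row per
#' (sample, miRNA, arm, category, tail type) with the summed mapping
#' weight. Produced by \code{\link{tallyCalls}} and consumed by the NTA
#' statistics layer.
#'
#' @slot tally \code{data.frame} with columns \code{sample},
#'   \code{mirna_id}, \code{arm}, \code{category}, \code{tail_type},
#'   \code{weight}.
#' @slot samples \code{data.frame} with columns \code{sample} and
#'   \code{condition}.
#'
#' @export
setClass("TailCube",
  representation(tally = "data.frame", samples = "data.frame")
)

setValidity("TailCube", function(object) {
  msg <- character()
  need <- c("sample", "mirna_id", "arm", "category", "tail_type", "weight")
  if (!all(need %in% names(object@tally)))
    msg <- c(msg, paste("tally must have columns:", paste(need, collapse = ", ")))
  if (!all(c("sample", "condition") %in% names(object@samples)))
    msg <- c(msg, "samples must have columns sample, condition")
  else if (!all(object@tally$sample %in% object@samples$sample))
    msg <- c(msg, "tally contains samples missing from the sample table")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TailCube", function(object) {
  cat("TailCube:", sum(object@tally$weight), "weighted reads,",
      length(unique(object@tally$mirna_id)), "miRNAs,",
      nrow(object@samples), "samples\n")
})

#' @describeIn TailCube-class the aggregated long-format count table.
#' @param x a \code{TailCube}.
#' @export
tallyTable <- function(x) x@tally

#' @describeIn TailCube-class the sample/condition table.
#' @export
sampleTable <- function(x) x@samples
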