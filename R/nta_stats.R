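#' Build per-miRNA tail/category profiles from a TailCube
#'
#' Aggregates weighted counts per analysis unit (condition or sample) and
#' miRNA, optionally stratified by arm, into one row per unit x miRNA
#' (x arm) with one count column per tail type (\code{tt_*}) and per
#' taxonomy category (\code{cat_*}). miRNAs below \code{minReads} total
#' are flagged \code{included = FALSE}: they are excluded from unweighted
#' per-miRNA statistics but still contribute to pooled (weighted)
#' statistics.
#'
#' @param cube a \code{\link{TailCube-class}}.
#' @param scope "condition" (default) or "sample".
#' @param byArm stratify by 5p/3p arm of origin.
#' @param minReads inclusion threshold for per-miRNA statistics
#'   (default 10).
#' @return data.frame of profiles (class \code{ntaProfiles}); fractions of
#'   each row sum to 1 over tail types and over categories.
#' @export
buildProfiles <- function(cube, scope = c("condition", "sample"),
                          byArm = FALSE, minReads = 10) {
  scope <- match.arg(scope)
  t <- tallyTable(cube)
  smp <- sampleTable(cube)
  unit <- if (scope == "condition")
    smp$condition[match(t$sample, smp$sample)] else t$sample
  armCol <- if (byArm) t$arm else rep("both", nrow(t))
  key <- paste(unit, t$mirna_id, armCol, sep = "\r")
  ttM <- tapply(t$weight,
                list(key, factor(t$tail_type, levels = TAIL_TYPES)), sum)
  ttM[is.na(ttM)] <- 0
  cats <- setdiff(ISOMIR_CATEGORIES, "unassigned")
  catM <- tapply(t$weight,
                 list(key, factor(t$category, levels = cats)), sum)
  catM[is.na(catM)] <- 0
  parts <- do.call(rbind, strsplit(rownames(ttM), "\r", fixed = TRUE))
  total <- rowSums(ttM)
  out <- data.frame(unit = parts[, 1], mirna_id = parts[, 2],
                    arm = parts[, 3], total = total,
                    included = total >= minReads,
                    stringsAsFactors = FALSE)
  colnames(ttM) <- paste0("tt_", colnames(ttM))
  colnames(catM) <- paste0("cat_", colnames(catM))
  out <- cbind(out, as.data.frame(ttM), as.data.frame(catM))
  rownames(out) <- NULL
  attr(out, "scope") <- scope
  attr(out, "minReads") <- minReads
  attr(out, "byArm") <- byArm
  class(out) <- c("ntaProfiles", "data.frame")
  out
}

#' Arm-stratified profiles
#'
#' Convenience wrapper computing the same statistics separately for reads
#' assigned to the 5p and the 3p mature arm.
#'
#' @inheritParams buildProfiles
#' @return profiles with an \code{arm} column over "5p"/"3p".
#' @export
stratifyByArm <- function(cube, scope = "condition", minReads = 10) {
  buildProfiles(cube, scope = scope, byArm = TRUE, minReads = minReads)
}

selectorCounts <- function(profiles, selector) {
  cols <- paste0("tt_", tailTypesFor(selector))
  cols <- intersect(cols, names(profiles))
  if (!length(cols)) return(rep(0, nrow(profiles)))
  rowSums(profiles[, cols, drop = FALSE])
}

#' Unweighted mean isomiR percentage
#'
#' The arithmetic mean, over miRNAs passing the inclusion threshold, of
#' the per-miRNA fraction of reads carrying the selected tail, times 100.
#' Contrast with \code{\link{weightedMeanRatio}}, which pools reads.
#'
#' @param profiles output of \code{\link{buildProfiles}}.
#' @param selector tail selector (see \code{\link{tailTypesFor}}), e.g.
#'   "monoU" or "anyA".
#' @param arm restrict to one arm for arm-stratified profiles.
#' @return named numeric, one percentage per unit; NA where no miRNA
#'   qualifies.
#' @export
meanIsomirPercent <- function(profiles, selector, arm = NULL) {
  p <- profiles[profiles$included & profiles$total > 0, , drop = FALSE]
  if (!is.null(arm)) p <- p[p$arm == arm, , drop = FALSE]
  frac <- selectorCounts(p, selector) / p$total
  out <- tapply(frac, p$unit, mean)
  100 * unlist(as.list(out))
}

#' Pooled weighted mean ratio
#'
#' The ratio of reads carrying the selected nontemplated tail to the total
#' number of reads, pooled across all miRNAs (depth-weighted; low-count
#' miRNAs included).
#'
#' @inheritParams meanIsomirPercent
#' @return named numeric fraction per unit; NA where the pooled total is
#'   zero.
#' @export
weightedMeanRatio <- function(profiles, selector, arm = NULL) {
  p <- profiles
  if (!is.null(arm)) p <- p[p$arm == arm, , drop = FALSE]
  num <- tapply(selectorCounts(p, selector), p$unit, sum)
  den <- tapply(p$total, p$unit, sum)
  out <- ifelse(den > 0, num / den, NA_real_)
  setNames(as.numeric(out), names(den))
}

#' Select miRNAs above a terminal-modification frequency
#'
#' Keeps miRNAs whose total nontemplated-addition fraction (tails of any
#' base and length) strictly exceeds the threshold in the given unit.
#'
#' @param profiles output of \code{\link{buildProfiles}}.
#' @param threshold modification-fraction cutoff (default 0.01, i.e. the
#'   ">1\%" filter; the boundary value is excluded).
#' @param unit unit (condition/sample) to evaluate in; default the first.
#' @return character vector of miRNA ids.
#' @export
filterModified <- function(profiles, threshold = 0.01, unit = NULL) {
  if (is.null(unit)) unit <- profiles$unit[1]
  p <- profiles[profiles$unit == unit & profiles$total > 0, , drop = FALSE]
  frac <- p$cat_nta / p$total
  unique(p$mirna_id[frac > threshold])
}

#' Compare tail usage between two conditions
#'
#' Per-miRNA pseudocount-stabilised log2 fold changes of the uridylated
#' and adenylated fractions (homopolymeric tails of any length) between a
#' reference and an alternative condition, with a fold-change quadrant
#' class and a flag for at-least-fivefold adenylation gains.
#'
#' @param profiles condition-scope profiles from
#'   \code{\link{buildProfiles}} containing both conditions.
#' @param ref,alt condition names (reference and alternative).
#' @param pseudocount Haldane-Anscombe style pseudocount in reads
#'   (default 0.5).
#' @param band no-change band on |log2FC| for quadrant assignment
#'   (default 0.25); a quadrant is assigned only when both axes fall
#'   outside it.
#' @param minReads require at least this many reads in both conditions
#'   (default: the profiles' inclusion flag).
#' @return data.frame with per-miRNA fractions, \code{log2fc_u},
#'   \code{log2fc_a}, \code{quadrant} and \code{fivefold_a_gain}.
#' @export
compareConditions <- function(profiles, ref, alt, pseudocount = 0.5,
                              band = 0.25, minReads = NULL) {
  pr <- profiles[profiles$unit == ref, , drop = FALSE]
  pa <- profiles[profiles$unit == alt, , drop = FALSE]
  if (is.null(minReads)) {
    pr <- pr[pr$included, , drop = FALSE]
    pa <- pa[pa$included, , drop = FALSE]
  } else {
    pr <- pr[pr$total >= minReads, , drop = FALSE]
    pa <- pa[pa$total >= minReads, , drop = FALSE]
  }
  ids <- intersect(pr$mirna_id, pa$mirna_id)
  pr <- pr[match(ids, pr$mirna_id), , drop = FALSE]
  pa <- pa[match(ids, pa$mirna_id), , drop = FALSE]
  pc <- pseudocount
  lfc <- function(cRef, tRef, cAlt, tAlt)
    log2((cAlt + pc) / (tAlt + 2 * pc)) -
    log2((cRef + pc) / (tRef + 2 * pc))
  uR <- selectorCounts(pr, "anyU"); uA <- selectorCounts(pa, "anyU")
  aR <- selectorCounts(pr, "anyA"); aA <- selectorCounts(pa, "anyA")
  l2u <- lfc(uR, pr$total, uA, pa$total)
  l2a <- lfc(aR, pr$total, aA, pa$total)
  dirU <- ifelse(l2u <= -band, "downU", ifelse(l2u >= band, "upU", ""))
  dirA <- ifelse(l2a <= -band, "downA", ifelse(l2a >= band, "upA", ""))
  quadrant <- ifelse(dirU == "" | dirA == "", "unchanged",
                     paste(dirU, dirA, sep = "_"))
  data.frame(mirna_id = ids,
             u_frac_ref = uR / pr$total, u_frac_alt = uA / pa$total,
             a_frac_ref = aR / pr$total, a_frac_alt = aA / pa$total,
             log2fc_u = l2u, log2fc_a = l2a, quadrant = quadrant,
             fivefold_a_gain = l2a >= log2(5), stringsAsFactors = FALSE)
}

#' 5p/3p arm expression ratios
#'
#' Pseudocount-stabilised ratio of 5p to 3p weighted read counts per
#' miRNA and unit. miRNAs observed from a single arm only are skipped
#' unless a \code{HairpinSet} says both arms are annotated.
#'
#' @param cube a \code{\link{TailCube-class}}.
#' @param scope "condition" or "sample".
#' @param eps pseudocount (default 0.5).
#' @param threshold dominance threshold on the ratio (default 1).
#' @param hs optional \code{HairpinSet} used to decide which miRNAs have
#'   both arms annotated.
#' @return data.frame with \code{unit}, \code{mirna_id}, \code{count5p},
#'   \code{count3p}, \code{ratio}, \code{dominant} ("5p"/"3p"/"balanced").
#' @export
armRatios <- function(cube, scope = c("condition", "sample"), eps = 0.5,
                      threshold = 1, hs = NULL) {
  scope <- match.arg(scope)
  t <- tallyTable(cube)
  smp <- sampleTable(cube)
  unit <- if (scope == "condition")
    smp$condition[match(t$sample, smp$sample)] else t$sample
  key <- paste(unit, t$mirna_id, t$arm, sep = "\r")
  agg <- rowsum(t$weight, key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  w <- data.frame(unit = parts[, 1], mirna_id = parts[, 2],
                  arm = parts[, 3], weight = as.numeric(agg),
                  stringsAsFactors = FALSE)
  if (is.null(hs)) {
    two <- names(which(tapply(w$arm, w$mirna_id,
                              function(a) length(unique(a))) == 2))
  } else {
    m <- matureArms(hs)
    two <- names(which(table(unique(m[, c("hairpin_id", "arm")])$hairpin_id)
                       == 2))
  }
  w <- w[w$mirna_id %in% two, , drop = FALSE]
  if (!nrow(w))
    return(data.frame(unit = character(), mirna_id = character(),
                      count5p = numeric(), count3p = numeric(),
                      ratio = numeric(), dominant = character()))
  ukey <- paste(w$unit, w$mirna_id, sep = "\r")
  g5 <- rowsum(ifelse(w$arm == "5p", w$weight, 0), ukey)
  g3 <- rowsum(ifelse(w$arm == "3p", w$weight, 0), ukey)
  parts <- do.call(rbind, strsplit(rownames(g5), "\r", fixed = TRUE))
  ratio <- (as.numeric(g5) + eps) / (as.numeric(g3) + eps)
  data.frame(unit = parts[, 1], mirna_id = parts[, 2],
             count5p = as.numeric(g5), count3p = as.numeric(g3),
             ratio = ratio,
             dominant = ifelse(ratio > threshold, "5p",
                               ifelse(ratio < threshold, "3p", "balanced")),
             stringsAsFactors = FALSE)
}

#' Detect 5p/3p arm switching between conditions
#'
#' A switch is called when the dominant arm differs between the two
#' conditions and both ratios sit clearly outside the balanced band: one
#' above \code{margin}, the other below \code{1/margin}.
#'
#' @param ratios output of \code{\link{armRatios}} (condition scope).
#' @param ref,alt condition names.
#' @param margin fold margin defining the balanced band (default 1.5).
#' @return data.frame with per-miRNA ratios, \code{switch} flag and
#'   \code{direction} ("3p->5p", "5p->3p" or "").
#' @export
detectArmSwitch <- function(ratios, ref, alt, margin = 1.5) {
  rr <- ratios[ratios$unit == ref, , drop = FALSE]
  ra <- ratios[ratios$unit == alt, , drop = FALSE]
  ids <- intersect(rr$mirna_id, ra$mirna_id)
  rr <- rr[match(ids, rr$mirna_id), ]
  ra <- ra[match(ids, ra$mirna_id), ]
  to5p <- rr$ratio < 1 / margin & ra$ratio > margin
  to3p <- rr$ratio > margin & ra$ratio < 1 / margin
  data.frame(mirna_id = ids, ratio_ref = rr$ratio, ratio_alt = ra$ratio,
             switch = to5p | to3p,
             direction = ifelse(to5p, "3p->5p", ifelse(to3p, "5p->3p", "")),
             stringsAsFactors = FALSE)
}
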