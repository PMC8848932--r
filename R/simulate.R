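# Per-sample RNG streams are derived from (seed, index) so that adding
# samples never perturbs earlier ones; all values stay below 2^31.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %%
               2147483629)
}

randomBases <- function(n, alphabet = c("A", "C", "G", "T")) {
  sample(alphabet, n, replace = TRUE)
}

#' Create a synthetic-experiment configuration
#'
#' Returns a validated \code{\link{SimConfig-class}}. The defaults describe
#' a two-condition small RNA experiment patterned on a TUT4/7
#' loss-of-function comparison: a wild-type-like condition with mono-U
#' tails at 15\% and mono-A at 12\% of reads, and a knockout-like condition
#' where uridylation collapses (mono-U 2\%) and adenylation rises (mono-A
#' 18\%), each with three replicates at 1e5 reads. Templated trim/extend
#' rates put most mass on the canonical 3' end and templated extensions,
#' with smaller trimmed and 5'-shifted fractions.
#'
#' @param seed master seed (integer).
#' @param nMirnas number of precursors.
#' @param hairpinLength precursor length (nt).
#' @param conditions named list of condition specs; each needs
#'   \code{nReplicates}, \code{depth}, \code{dispersion}, \code{tailRates}.
#' @param armBias per-miRNA 5p usage fraction (scalar or length
#'   \code{nMirnas}).
#' @param deEffects named numeric of per-miRNA log2 fold changes applied to
#'   the non-reference condition.
#' @param trimExtendRates named numeric over
#'   canonical/ext1/ext2/trim1/trim2/shift5m/shift5p.
#' @param errorRate per-base substitution probability.
#' @param umiLength,adapter NEXTFlex library structure.
#' @param let7Fraction,csdFraction let-7-like subset and planted-motif
#'   fraction.
#' @param gcGuard template bases downstream of each mature 3' end drawn
#'   from \{C,G\} (see \code{SimConfig-class}).
#' @param flankLength simulated downstream genomic flank length.
#' @return a \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      nMirnas = 50L,
                      hairpinLength = 70L,
                      conditions = list(
                        wt = list(nReplicates = 3L, depth = 1e5,
                                  dispersion = 0.1,
                                  tailRates = c(none = 0.62, U = 0.15,
                                                UU = 0.04, A = 0.12,
                                                AA = 0.04, AU = 0.005,
                                                UA = 0.005, other = 0.02)),
                        cko = list(nReplicates = 3L, depth = 1e5,
                                   dispersion = 0.1,
                                   tailRates = c(none = 0.721, U = 0.02,
                                                 UU = 0.005, A = 0.18,
                                                 AA = 0.05, AU = 0.002,
                                                 UA = 0.002, other = 0.02))),
                      armBias = 0.5,
                      deEffects = numeric(),
                      trimExtendRates = c(canonical = 0.45, ext1 = 0.25,
                                          ext2 = 0.10, trim1 = 0.10,
                                          trim2 = 0.03, shift5m = 0.035,
                                          shift5p = 0.035),
                      errorRate = 0.001,
                      umiLength = 4L,
                      adapter = "TGGAATTCTCGGGTGCCAAGG",
                      let7Fraction = 0.2,
                      csdFraction = 0.5,
                      gcGuard = 4L,
                      flankLength = 10L) {
  new("SimConfig",
      seed = as.integer(seed), nMirnas = as.integer(nMirnas),
      hairpinLength = as.integer(hairpinLength), conditions = conditions,
      armBias = as.numeric(armBias), deEffects = deEffects,
      trimExtendRates = trimExtendRates, errorRate = errorRate,
      umiLength = as.integer(umiLength), adapter = adapter,
      let7Fraction = let7Fraction, csdFraction = csdFraction,
      gcGuard = as.integer(gcGuard), flankLength = as.integer(flankLength))
}

#' Simulate a miRNA reference with known ground truth
#'
#' Generates random precursor hairpins with non-overlapping 5p/3p arms
#' (arm lengths drawn from 20--23 nt), a downstream genomic flank, and a
#' let-7-like subset with planted (U)GAU loop motifs (CSD+) or motif-free
#' loops (CSD-). The \code{gcGuard} template bases immediately after each
#' mature 3' end are drawn from \{C,G\}. Deterministic under the config
#' seed.
#'
#' @param config a \code{\link{SimConfig-class}}.
#' @return list with elements \code{hairpins}
#'   (\code{\link{HairpinSet-class}}) and \code{truth} (per-miRNA
#'   data.frame: abundance weight, 5p arm bias, planted log2FC, let-7
#'   flags).
#' @export
simulateReference <- function(config) {
  validObject(config)
  n <- config@nMirnas
  ids <- if (n) sprintf("sim-mir-%03d", seq_len(n)) else character()
  if (n == 0) {
    hs <- HairpinSet(setNames(character(), character()),
                     data.frame(hairpin_id = character(),
                                mature_id = character(), arm = character(),
                                start = integer(), end = integer()))
    return(list(hairpins = hs,
                truth = data.frame(mirna_id = character())))
  }
  set.seed(deriveSeed(config@seed, 0))
  L <- config@hairpinLength
  g <- config@gcGuard
  margin5 <- 4L
  l5 <- sample(20:23, n, replace = TRUE)
  l3 <- sample(20:23, n, replace = TRUE)
  s5 <- rep(margin5 + 1L, n); e5 <- s5 + l5 - 1L
  e3 <- rep(L, n); s3 <- e3 - l3 + 1L
  loopLen <- s3 - e5 - 1L
  if (any(loopLen < g + 6L))
    stop("hairpin too short to host both arms")

  nLet7 <- round(n * config@let7Fraction)
  isLet7 <- seq_len(n) %in% sample(n, nLet7)
  csdPlus <- isLet7 & (runif(n) < config@csdFraction)
  group <- ifelse(runif(n) < 0.5, "I", "II")

  seqs <- character(n)
  flanks <- character(n)
  for (i in seq_len(n)) {
    sq <- randomBases(L)
    # identifiability guard downstream of the 5p mature end (loop start)
    if (g > 0) sq[(e5[i] + 1):(e5[i] + g)] <- randomBases(g, c("C", "G"))
    lo <- e5[i] + 1L; hi <- s3[i] - 1L
    if (isLet7[i]) {
      loop <- sq[lo:hi]
      # scrub any GAT so the motif state is exactly the planted one
      loopStr <- paste(loop, collapse = "")
      while (grepl("GAT", loopStr, fixed = TRUE))
        loopStr <- sub("GAT", "GCT", loopStr, fixed = TRUE)
      loop <- strsplit(loopStr, "")[[1]]
      if (csdPlus[i]) loop[(g + 1):(g + 4)] <- c("T", "G", "A", "T")
      sq[lo:hi] <- loop
    }
    fl <- randomBases(config@flankLength)
    if (g > 0) fl[seq_len(min(g, length(fl)))] <-
        randomBases(min(g, length(fl)), c("C", "G"))
    seqs[i] <- paste(sq, collapse = "")
    flanks[i] <- paste(fl, collapse = "")
  }
  names(seqs) <- ids; names(flanks) <- ids

  mature <- data.frame(
    hairpin_id = rep(ids, each = 2),
    mature_id = as.vector(rbind(paste0(ids, "-5p"), paste0(ids, "-3p"))),
    arm = rep(c("5p", "3p"), n),
    start = as.vector(rbind(s5, s3)),
    end = as.vector(rbind(e5, e3)),
    stringsAsFactors = FALSE)

  let7 <- data.frame(mirna_id = ids[isLet7], group = group[isLet7],
                     csd = ifelse(csdPlus[isLet7], "plus", "minus"),
                     stringsAsFactors = FALSE)
  hs <- HairpinSet(seqs, mature, flank3p = flanks, let7 = let7)

  w <- exp(rnorm(n, 0, 1)); w <- w / sum(w)
  bias <- rep(config@armBias, length.out = n)
  lfc <- setNames(rep(0, n), ids)
  if (length(config@deEffects)) {
    hit <- intersect(names(config@deEffects), ids)
    lfc[hit] <- config@deEffects[hit]
  }
  truth <- data.frame(mirna_id = ids, abundanceWeight = w,
                      armBias5p = bias, log2fc = as.numeric(lfc),
                      isLet7 = isLet7, group = group,
                      csd = ifelse(isLet7,
                                   ifelse(csdPlus, "plus", "minus"), NA),
                      stringsAsFactors = FALSE)
  list(hairpins = hs, truth = truth)
}

TAIL_STRINGS <- c(none = "", U = "T", UU = "TT", A = "A", AA = "AA",
                  AU = "AT", UA = "TA")
VARIANT_OFF5 <- c(canonical = 0L, ext1 = 0L, ext2 = 0L, trim1 = 0L,
                  trim2 = 0L, shift5m = -1L, shift5p = 1L)
VARIANT_T3   <- c(canonical = 0L, ext1 = 1L, ext2 = 2L, trim1 = -1L,
                  trim2 = -2L, shift5m = 0L, shift5p = 0L)

generativeCategory <- function(offset5, templated3, tail) {
  ifelse(tail != "", "nta",
  ifelse(offset5 == 0 & templated3 > 0, "lv3pE",
  ifelse(offset5 == 0 & templated3 < 0, "lv3pT",
  ifelse(templated3 == 0 & offset5 < 0, "lv5pE",
  ifelse(templated3 == 0 & offset5 > 0, "lv5pT",
  ifelse(offset5 != 0 & templated3 != 0, "mv", "exact"))))))
}

#' Simulate NEXTFlex small RNA reads with a truth manifest
#'
#' For every sample (condition x replicate), per-miRNA read counts are
#' drawn from a negative binomial with condition fold changes applied;
#' each read picks an arm by the 5p bias, a templated trim/extend variant,
#' and a nontemplated tail by the condition tail rates. Tail bases are
#' appended after the templated variant is chosen, so a tail may coincide
#' with the next template base; the manifest always records the generative
#' label. Reads are wrapped as UMI + insert + UMI + adapter with constant
#' "I" qualities. One RNG stream per sample is derived from (seed, sample
#' index), and a fixed seed gives byte-identical output.
#'
#' @param config a \code{\link{SimConfig-class}}.
#' @param reference output of \code{\link{simulateReference}} (or a bare
#'   \code{HairpinSet}, in which case uniform abundances are used).
#' @param dir if non-NULL, a directory where one FASTQ per sample is
#'   written.
#' @return list with \code{samples} (sample sheet incl. FASTQ paths),
#'   \code{reads} (per-sample data.frames of id/sequence kept in memory),
#'   \code{manifest} (per-read truth: miRNA, arm, offsets, tail, category)
#'   and \code{perMirna} (per-miRNA expected abundance per condition and
#'   generative rates).
#' @export
simulateReads <- function(config, reference, dir = NULL) {
  validObject(config)
  if (is(reference, "HairpinSet")) {
    hs <- reference
    ids <- hairpinIds(hs)
    truth <- data.frame(mirna_id = ids,
                        abundanceWeight = rep(1 / max(1, length(ids)),
                                              length(ids)),
                        armBias5p = rep(config@armBias,
                                        length.out = length(ids)),
                        log2fc = 0, stringsAsFactors = FALSE)
  } else {
    hs <- reference$hairpins
    truth <- reference$truth
  }
  ids <- truth$mirna_id
  n <- length(ids)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)

  m <- hs@mature
  template <- setNames(paste0(as.character(hs@sequences), hs@flank3p[hairpinIds(hs)]),
                       hairpinIds(hs))
  key <- paste(m$hairpin_id, m$arm)
  armStart <- setNames(m$start, key)
  armEnd <- setNames(m$end, key)
  hasArm <- function(arm) paste(ids, arm) %in% key

  condNames <- names(config@conditions)
  samples <- data.frame()
  readsList <- list()
  manifest <- list()
  perMirna <- list()
  sampleIndex <- 0L
  for (ci in seq_along(condNames)) {
    cond <- condNames[ci]
    cn <- config@conditions[[cond]]
    mu <- cn$depth * truth$abundanceWeight *
      ifelse(rep(ci > 1, n), 2^truth$log2fc, 1)
    if (n > 0)
      perMirna[[cond]] <- data.frame(mirna_id = ids, condition = cond,
                                     expectedReads = mu,
                                     armBias5p = truth$armBias5p,
                                     log2fc = truth$log2fc,
                                     t(replicate(n, cn$tailRates)),
                                     stringsAsFactors = FALSE)
    for (r in seq_len(cn$nReplicates)) {
      sampleIndex <- sampleIndex + 1L
      sname <- sprintf("%s_rep%d", cond, r)
      set.seed(deriveSeed(config@seed, sampleIndex))
      counts <- if (cn$dispersion > 0)
        rnbinom(n, mu = mu, size = 1 / cn$dispersion)
      else rpois(n, mu)
      N <- sum(counts)
      if (N == 0) {
        readsList[[sname]] <- data.frame(id = character(),
                                         seq = character())
        samples <- rbind(samples,
                         data.frame(sample = sname, condition = cond,
                                    replicate = r, nReads = 0L,
                                    fastq = NA_character_))
        next
      }
      mirna <- rep(ids, counts)
      bias <- rep(truth$armBias5p, counts)
      # fall back to the annotated arm when only one exists
      has5 <- rep(hasArm("5p"), counts); has3 <- rep(hasArm("3p"), counts)
      arm <- ifelse(runif(N) < bias, "5p", "3p")
      arm[!has5] <- "3p"; arm[arm == "3p" & !has3] <- "5p"
      variant <- sample(TRIMEXT_KEYS, N, replace = TRUE,
                        prob = config@trimExtendRates[TRIMEXT_KEYS])
      off5 <- VARIANT_OFF5[variant]
      t3 <- VARIANT_T3[variant]
      tailKey <- sample(TAIL_RATE_KEYS, N, replace = TRUE,
                        prob = cn$tailRates[TAIL_RATE_KEYS])
      tail <- TAIL_STRINGS[tailKey]
      tail[tailKey == "other"] <- sample(c("G", "C"),
                                         sum(tailKey == "other"),
                                         replace = TRUE)
      k <- paste(mirna, arm)
      insert <- substr(template[mirna], armStart[k] + off5, armEnd[k] + t3)
      insert <- paste0(insert, tail)
      if (config@errorRate > 0) {
        ilen <- nchar(insert)
        nerr <- rbinom(N, ilen, config@errorRate)
        for (j in which(nerr > 0)) {
          pos <- sample(ilen[j], nerr[j])
          for (p in pos) {
            old <- substr(insert[j], p, p)
            substr(insert[j], p, p) <-
              sample(setdiff(c("A", "C", "G", "T"), old), 1)
          }
        }
      }
      u5 <- apply(matrix(randomBases(config@umiLength * N),
                         nrow = config@umiLength), 2, paste, collapse = "")
      u3 <- apply(matrix(randomBases(config@umiLength * N),
                         nrow = config@umiLength), 2, paste, collapse = "")
      if (config@umiLength == 0) { u5 <- rep("", N); u3 <- rep("", N) }
      readSeq <- paste0(u5, insert, u3, config@adapter)
      readId <- sprintf("%s_r%06d", sname, seq_len(N))
      readsList[[sname]] <- data.frame(id = readId, seq = readSeq,
                                       stringsAsFactors = FALSE)
      fq <- NA_character_
      if (!is.null(dir)) {
        fq <- file.path(dir, paste0(sname, ".fastq"))
        writeFastq(readId, readSeq, fq)
      }
      manifest[[sname]] <- data.frame(
        sample = sname, read_id = readId, mirna_id = mirna, arm = arm,
        offset5 = as.integer(off5), templated3 = as.integer(t3),
        tail = chartr("T", "U", tail), tail_key = tailKey,
        insert = insert,
        category = generativeCategory(off5, t3, tail),
        stringsAsFactors = FALSE)
      samples <- rbind(samples,
                       data.frame(sample = sname, condition = cond,
                                  replicate = r, nReads = N, fastq = fq,
                                  stringsAsFactors = FALSE))
    }
  }
  list(samples = samples, reads = readsList,
       manifest = do.call(rbind, c(manifest, make.row.names = FALSE)),
       perMirna = do.call(rbind, c(perMirna, make.row.names = FALSE)))
}

#' Write reads as 4-line FASTQ with constant qualities
#' @noRd
writeFastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)), path, format = "fastq",
    qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a FASTQ file into an id/sequence data.frame
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet(format="fastq")};
#' gzip transparent.
#' @param path FASTQ file.
#' @return data.frame with columns \code{id}, \code{seq}.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE)
}

#' Simulate an mRNA count table with planted effects
#'
#' Negative-binomial counts per gene and sample for a two-group design,
#' with per-gene baseline means drawn log-normally and a planted log2 fold
#' change applied to the second group.
#'
#' @param nGenes number of genes.
#' @param nPerGroup integer length-2 vector of replicates per group.
#' @param meanExpression median baseline mean count.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param log2fc scalar or per-gene vector of planted effects.
#' @param libSizes optional per-sample relative depths (must be > 0).
#' @param seed RNG seed.
#' @return list with \code{counts} (matrix genes x samples), \code{group}
#'   (factor) and \code{truth} (per-gene log2fc).
#' @export
simulateMrnaCounts <- function(nGenes = 2000, nPerGroup = c(4, 4),
                               meanExpression = 100, dispersion = 0.1,
                               log2fc = 0, libSizes = NULL, seed = 1) {
  nPerGroup <- rep(as.integer(nPerGroup), length.out = 2)
  ns <- sum(nPerGroup)
  if (is.null(libSizes)) libSizes <- rep(1, ns)
  if (any(libSizes <= 0)) stop("libSizes must be > 0 (zero-depth sample)")
  set.seed(deriveSeed(seed, 1))
  base <- exp(rnorm(nGenes, log(meanExpression), 1))
  lfc <- rep(log2fc, length.out = nGenes)
  group <- factor(rep(c("A", "B"), nPerGroup))
  mu <- base %o% rep(1, ns)
  mu[, group == "B"] <- mu[, group == "B"] * 2^lfc
  mu <- sweep(mu, 2, libSizes, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = nGenes)
  dimnames(counts) <- list(sprintf("gene%04d", seq_len(nGenes)),
                           paste0(rep(c("A", "B"), nPerGroup), "_rep",
                                  c(seq_len(nPerGroup[1]),
                                    seq_len(nPerGroup[2]))))
  list(counts = counts, group = group,
       truth = data.frame(gene = rownames(counts), log2fc = lfc))
}

#' Simulate a logistic confluency time series
#'
#' Evaluates the logistic growth model
#' \deqn{N(t) = K / (1 + e^{-rt}(K - N_0)/N_0)}
#' at the given times and adds Gaussian noise.
#'
#' @param K carrying capacity (percent confluency).
#' @param r growth rate per hour.
#' @param N0 initial confluency (> 0, < K).
#' @param times hours.
#' @param noiseSd Gaussian noise sd (percent confluency).
#' @param seed RNG seed (only used when noiseSd > 0).
#' @return data.frame with columns \code{time_h}, \code{confluency}.
#' @export
simulateGrowth <- function(K, r, N0, times, noiseSd = 0, seed = 1) {
  if (N0 <= 0) stop("N0 must be > 0")
  if (K <= N0) stop("K must exceed N0")
  y <- logisticCurve(times, K, r, N0)
  if (noiseSd > 0) {
    set.seed(deriveSeed(seed, 2))
    y <- y + rnorm(length(times), 0, noiseSd)
  }
  data.frame(time_h = times, confluency = y)
}
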