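writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the isomiR profiling pipeline end to end
#'
#' Orchestrates the stages in dependency order: simulate (reference +
#' reads; skipped when real inputs are given), preprocess, classify,
#' ntastats, de (+ clustering and PCA when there are enough features) and
#' growth (when a confluency table is supplied). Every output directory
#' receives the result tables as TSV, a machine-readable JSON summary of
#' global statistics, and a frozen copy of the resolved configuration;
#' reruns with an identical configuration are byte-identical.
#'
#' @param config a list or a YAML file path. Recognised blocks:
#'   \code{sim} (arguments to \code{\link{simConfig}}),
#'   \code{reference} (\code{fasta}, \code{coords}, optional \code{let7}),
#'   \code{samples} (data.frame/TSV with \code{sample}, \code{condition},
#'   \code{fastq}), \code{preprocess}, \code{classify}, \code{ntastats},
#'   \code{de} parameter blocks, and \code{growth} (TSV with \code{well},
#'   \code{time_h}, \code{value}).
#' @param outdir output directory (created).
#' @param stages character subset of
#'   c("simulate","preprocess","classify","ntastats","de","growth") or
#'   "all".
#' @param seed overrides the config seed.
#' @return invisibly, a list with the in-memory results and an output
#'   file manifest.
#' @export
runPipeline <- function(config = list(), outdir, stages = "all",
                        seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  allStages <- c("simulate", "preprocess", "classify", "ntastats", "de",
                 "growth")
  if (identical(stages, "all")) stages <- allStages
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  res <- list()
  manifest <- character()

  simulateRequested <- "simulate" %in% stages && is.null(config$samples)
  if (!is.null(seed)) config$sim$seed <- seed
  cfgPath <- file.path(outdir, "config_frozen.yaml")
  yaml::write_yaml(config, cfgPath)
  manifest <- c(manifest, cfgPath)

  hs <- NULL
  if (!is.null(config$reference)) {
    hs <- readHairpinSet(config$reference$fasta, config$reference$coords,
                         config$reference$let7)
  }
  samples <- NULL
  readsList <- NULL
  if (simulateRequested) {
    sc <- do.call(simConfig, config$sim %||% list())
    ref <- simulateReference(sc)
    hs <- ref$hairpins
    simDir <- file.path(outdir, "simulated")
    sim <- simulateReads(sc, ref, dir = simDir)
    writeHairpinSet(hs, file.path(simDir, "hairpins.fa"),
                    file.path(simDir, "mature_coords.tsv"),
                    file.path(simDir, "let7_annotation.tsv"))
    manifest <- c(manifest,
                  writeTsv(sim$manifest[, setdiff(names(sim$manifest),
                                                  "insert")],
                           file.path(simDir, "truth_manifest.tsv")),
                  writeTsv(sim$samples, file.path(simDir, "samples.tsv")))
    samples <- sim$samples
    readsList <- sim$reads
    res$sim <- sim
    res$reference <- ref
  } else if (!is.null(config$samples)) {
    samples <- config$samples
    if (is.character(samples)) samples <- utils::read.delim(samples)
  }

  if ("preprocess" %in% stages) {
    if (is.null(samples)) stop("preprocess needs samples; run simulate ",
                               "or provide a sample sheet")
    pp <- list()
    qc <- list()
    for (i in seq_len(nrow(samples))) {
      sn <- samples$sample[i]
      rd <- if (!is.null(readsList)) readsList[[sn]] else
        readFastq(samples$fastq[i])
      args <- c(list(reads = rd), config$preprocess %||% list())
      out <- do.call(preprocessReads, args)
      out$reads$sample <- sn
      pp[[sn]] <- out$reads
      qc[[sn]] <- data.frame(sample = sn,
                             t(out$qc$statusCounts),
                             duplicationRate = out$qc$dedup$duplicationRate)
    }
    res$processed <- do.call(rbind, c(pp, make.row.names = FALSE))
    qcTab <- do.call(rbind, c(qc, make.row.names = FALSE))
    manifest <- c(manifest,
                  writeTsv(qcTab, file.path(outdir, "preprocess_qc.tsv")))
    res$preprocessQC <- qcTab
  }

  if ("classify" %in% stages) {
    if (is.null(res$processed)) stop("classify needs preprocess output")
    if (is.null(hs)) stop("classify needs a reference (simulate or ",
                          "config$reference)")
    args <- c(list(reads = res$processed, hs = hs),
              config$classify %||% list())
    calls <- do.call(classifyReads, args)
    cube <- tallyCalls(calls,
                       samples[, c("sample", "condition"), drop = FALSE])
    res$calls <- calls
    res$cube <- cube
    manifest <- c(manifest,
                  writeTsv(calls, file.path(outdir, "isomir_calls.tsv")),
                  writeTsv(tallyTable(cube),
                           file.path(outdir, "tail_cube.tsv")))
  }

  if ("ntastats" %in% stages) {
    if (is.null(res$cube)) stop("ntastats needs classify output")
    ns <- config$ntastats %||% list()
    prof <- buildProfiles(res$cube, minReads = ns$minReads %||% 10)
    conds <- unique(sampleTable(res$cube)$condition)
    res$profiles <- prof
    manifest <- c(manifest,
                  writeTsv(prof, file.path(outdir, "nta_profiles.tsv")))
    summaryStats <- list(
      meanMonoUPercent = as.list(meanIsomirPercent(prof, "monoU")),
      meanMonoAPercent = as.list(meanIsomirPercent(prof, "monoA")),
      weightedMeanRatioU = as.list(weightedMeanRatio(prof, "anyU")),
      weightedMeanRatioA = as.list(weightedMeanRatio(prof, "anyA")))
    if (length(conds) >= 2) {
      cmp <- compareConditions(prof, conds[1], conds[2])
      ar <- armRatios(res$cube, hs = hs)
      sw <- detectArmSwitch(ar, conds[1], conds[2])
      res$comparison <- cmp
      res$armRatios <- ar
      res$armSwitches <- sw
      manifest <- c(manifest,
                    writeTsv(cmp, file.path(outdir, "tail_comparison.tsv")),
                    writeTsv(ar, file.path(outdir, "arm_ratios.tsv")),
                    writeTsv(sw, file.path(outdir, "arm_switches.tsv")))
      summaryStats$nFivefoldAGain <- sum(cmp$fivefold_a_gain)
      summaryStats$quadrants <- as.list(table(cmp$quadrant))
      summaryStats$nArmSwitches <- sum(sw$switch)
    }
    jsonlite::write_json(summaryStats,
                         file.path(outdir, "nta_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- c(manifest, file.path(outdir, "nta_summary.json"))
  }

  if ("de" %in% stages) {
    if (is.null(res$cube)) stop("de needs classify output")
    t <- tallyTable(res$cube)
    key <- paste(t$mirna_id, t$arm, sep = "-")
    counts <- tapply(t$weight, list(key, t$sample), sum)
    counts[is.na(counts)] <- 0
    smp <- sampleTable(res$cube)
    counts <- counts[, smp$sample, drop = FALSE]
    conds <- unique(smp$condition)
    if (length(conds) >= 2 && nrow(counts) >= 2) {
      sel <- smp$condition %in% conds[1:2]
      deArgs <- config$de %||% list()
      de <- nbWaldTest(round(counts[, sel, drop = FALSE]),
                       factor(smp$condition[sel], levels = conds[1:2]),
                       alpha = deArgs$alpha %||% 0.01)
      res$de <- de
      manifest <- c(manifest,
                    writeTsv(de, file.path(outdir, "de_mirna.tsv")))
      pca <- pcaQC(round(counts))
      res$pca <- pca
      manifest <- c(manifest,
                    writeTsv(data.frame(sample = rownames(pca$scores),
                                        pca$scores),
                             file.path(outdir, "pca_scores.tsv")))
    }
  }

  if ("growth" %in% stages && !is.null(config$growth)) {
    g <- config$growth
    if (is.character(g)) g <- utils::read.delim(g)
    names(g)[names(g) == "value"] <- "confluency"
    fits <- lapply(split(g, g$well), function(sg) {
      f <- fitLogistic(sg)
      data.frame(well = sg$well[1], K = f$K, r = f$r, N0 = f$N0,
                 rss = f$rss, p_r = f$p_r, converged = f$converged)
    })
    gf <- do.call(rbind, c(fits, make.row.names = FALSE))
    res$growthFits <- gf
    manifest <- c(manifest,
                  writeTsv(gf, file.path(outdir, "growth_fits.tsv")))
  }

  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
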