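# miRTails

IsomiR and nontemplated 3′ tail profiling for small RNA sequencing.

## The problem

Mature miRNAs are not a single sequence: reads from one locus differ at
the 5′ end, at the 3′ end (templated trimming or extension against the
precursor), and by **nontemplated 3′ additions (NTA)** — most prominently
uridylation (by the terminal uridylyl transferases TUT4/7) and
adenylation. Shifts between uridylated and adenylated isomiR populations,
and shifts in which precursor arm (5p vs 3p) dominates, carry biological
signal, e.g. in comparisons of TUT4/7 catalytic knockouts against
wild-type cancer cell lines.

miRTails implements that analysis as a tested, reusable R package, for
small RNA bioinformaticians who want the tail-calling logic itself rather
than a black-box web service:

* **Preprocessing** of NEXTFlex-style libraries: 3′ adapter
  (`TGGAATTCTCGGGTGCCAAGG`) trimming, removal of the 4-nt random bases at
  both insert ends, and exact UMI-based PCR deduplication.
* **IsomiR calling**: each insert is anchored to a mature arm (5′ offset
  window ±2, ≤1 internal mismatch) and its 3′ end is decomposed by a
  *greedy maximal-templated* rule — the templated match is extended along
  the hairpin and its genomic flank as far as bases agree; the remaining
  suffix is the nontemplated tail. Calls get a taxonomy category (exact,
  lv3pE/lv3pT, lv5pE/lv5pT, mv, nta, SNP-flagged) and a tail type (A, AA,
  AU, U, UA, UU, polyA/polyU, G, C, other).
* **NTA statistics**: per-miRNA tail fractions, the unweighted *mean
  isomiR percentage* vs the pooled *weighted mean ratio*
  (Σ tailed reads / Σ total reads), 5p/3p stratification, the >1%
  modification filter, per-miRNA log2 fold-change quadrants
  (↓U/↑A, …) with a five-fold adenylation-gain flag, and arm-switch
  detection from pseudocount-stabilised 5p/3p ratios.
* **Expression analysis**: median-of-ratios normalisation, a
  negative-binomial Wald test with BH-FDR (default FDR < 0.01), k-means
  (k = 15, k-means++ seeding) clustering of log2 fold-change profiles,
  and PCA QC.
* **Downstream**: hypergeometric set enrichment, miRNA–mRNA
  negative-correlation edge filtering, and logistic growth-curve fitting
  `N(t) = K / (1 + e^{-rt}(K - N0)/N0)` for confluency time series.
* **A synthetic-data generator** that emulates the whole experiment
  (NB abundances, condition-specific tail rates, templated trim/extend
  mixtures, UMIs, adapters, sequencing error) with a per-read truth
  manifest, so every stage is validated end to end without any download.

## Worked example

```r
library(miRTails)

cfg <- simConfig(seed = 11, nMirnas = 50, errorRate = 0.001,
  conditions = list(
    wt  = list(nReplicates = 3, depth = 1e5, dispersion = 0.1,
               tailRates = c(none = 0.73, U = 0.15, UU = 0, A = 0.12,
                             AA = 0, AU = 0, UA = 0, other = 0)),
    cko = list(nReplicates = 3, depth = 1e5, dispersion = 0.1,
               tailRates = c(none = 0.80, U = 0.02, UU = 0, A = 0.18,
                             AA = 0, AU = 0, UA = 0, other = 0))))
ref   <- simulateReference(cfg)
sim   <- simulateReads(cfg, ref)
reads <- do.call(rbind, lapply(names(sim$reads), function(sn) {
  r <- preprocessReads(sim$reads[[sn]])$reads; r$sample <- sn; r
}))
calls <- classifyReads(reads, ref$hairpins)
prof  <- buildProfiles(tallyCalls(calls))

round(weightedMeanRatio(prof, "monoU"), 4)
#>    cko     wt
#> 0.0195 0.1439
round(weightedMeanRatio(prof, "monoA"), 4)
#>    cko     wt
#> 0.1764 0.1188

cmp <- compareConditions(prof, "wt", "cko")
mean(cmp$quadrant == "downU_upA")
#> [1] 1
```

The recovered pooled mono-U ratios (14.4% in the wild-type-like
condition, 2.0% in the knockout-like condition) sit within sampling and
template-ambiguity error of the configured generative rates (15% and
2%), and every miRNA lands in the planted "uridylation down, adenylation
up" quadrant. The small downward bias on the wild-type ratio is real and
expected: a nontemplated tail on a trimmed 3′ end that happens to match
the next template base is — correctly, under the greedy rule — absorbed
as templated (see the methods vignette).

`runPipeline()` (or `inst/scripts/mirtails.R` from a shell) chains the
stages and writes TSV/JSON outputs plus a frozen config; the same
function consumes real FASTQ files and a miRBase-style reference (FASTA +
mature coordinate TSV) via the `samples` and `reference` config blocks.

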