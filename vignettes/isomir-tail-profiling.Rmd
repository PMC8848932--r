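---
title: "Methods: isomiR and nontemplated 3' tail profiling"
author: "miRTails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR and nontemplated 3' tail profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, and the design decisions taken where the
underlying methodology leaves choices open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# The data model

A **precursor** (`HairpinSet`) is a hairpin sequence carrying 1-based
inclusive coordinates for the mature 5p and/or 3p arm, an optional
downstream genomic flank, and an optional let-7-like annotation. The
1-based inclusive convention follows miRBase GFF files; internally all
interval arithmetic is done on those coordinates directly. U and T are
treated as the same base: every input is normalised to the DNA alphabet
once at construction, so all downstream logic is alphabet-invariant
(tails are reported back in U-space).

A **read call** assigns an insert to a mature arm with a 5' offset
(read start minus mature start; negative means 5' templated extension),
a templated 3' offset, a nontemplated tail string, an internal mismatch
count, a taxonomy category and a tail type. A **TailCube** aggregates
call weights by sample x miRNA x arm x category x tail type and is the
interface between classification and statistics.

# Preprocessing (NEXTFlex dialect)

Reads are adapter-trimmed, stripped of the 4-nt random bases at both
insert ends, length-filtered and UMI-deduplicated.

* **Adapter rule.** The adapter (`TGGAATTCTCGGGTGCCAAGG`) is removed at
  the *leftmost* position where an adapter prefix aligns with at most a
  10% mismatch rate. Away from the read's 3' terminus the aligned prefix
  must be at least `minOverlap` (default 10) long; at the terminus,
  where the window runs off the read, partial prefixes down to 3 nt are
  accepted. The 3-nt terminal floor prevents single coincidental bases
  from being "trimmed" while still recovering reads whose adapter is
  clipped by the read length — the same compromise short-read trimmers
  make with their default minimum overlap.
* **Untrimmed reads are discarded** by default: without the adapter
  boundary the 3' UMI position is ambiguous, so the insert cannot be
  recovered reliably.
* **Deduplication** collapses exact (umi5, insert, umi3) triples to the
  first representative. No edit-distance UMI clustering is attempted;
  with 4+4 random bases the collision space is 65,536 keys per insert,
  so the residual collision loss is small at the depths considered and
  deterministic clustering would add a tunable error model we cannot
  validate here. This is noted as future work.
* **Length filter** defaults to 16–28 nt, bracketing mature miRNAs plus
  tails; it is a package choice, configurable, and counted explicitly in
  the QC report (kept + no_adapter + too_short + too_long = input).

# 3' end decomposition

The heart of the package is the split of a read's 3' end into a
templated part and a nontemplated tail. Given a candidate anchor
(arm, 5' offset), the templated match is extended base by base along
the hairpin and then along the 3' genomic flank (default: whatever
flank the reference provides; without one, extension past the hairpin
end is nontemplated) **as far as bases agree**; the remaining suffix is
the tail. This *greedy maximal-templated* rule is conservative for NTA
calling: whenever a suffix could be either templated or a tail, it is
called templated, so e.g. an `AA` suffix over a template continuing
`AC` is decomposed as +1 templated plus tail `A`, never tail `AA`.

Two refinements:

* Up to one mismatch inside the mature body is tolerated without
  stopping the extension, and is recorded as an internal mismatch
  (SNP/editing-like, flagged but not called as a tail). "Internal" is
  read strictly: a tolerated mismatch must be followed by a further
  matching templated base, i.e. the last templated base always matches.
  Without this restriction a trimmed read with a 1-nt tail
  (`mature[1..n-1] + U`) would always be absorbed as a SNP-like call
  and the entire tail-rate analysis would collapse; with it, only a
  genuine interior substitution is flagged.
* Bases aligned upstream of the mature start (5' templated extension)
  must match exactly; a mismatch there invalidates the candidate.

Candidates are generated for all arms at 5' offsets within ±2 (larger
multilength variants are rare and ambiguous and are left unassigned),
and multi-mapping reads keep the candidates minimising
(mismatches, |5' offset|, tail length) lexicographically, splitting
weight equally among ties (or resolving to the lexicographically
smallest mature id in "unique" mode). A vectorised anchor scan
implements this; the test suite checks it against an independent
brute-force oracle that enumerates every split point of every read, on
a fully enumerated toy precursor (all 5'/3' offsets in ±2, all tails up
to length 3) — agreement is required on 100% of reads.

**Tail typology.** Named types A, AA, AU, U, UA, UU, single G and C;
homopolymeric runs of length ≥ 3 become polyA/polyU; everything else is
"other". "Any length" aggregations of a base (used for the fold-change
analyses) cover only homopolymeric tails of that base — mixed tails
such as `AAU` are not force-fitted into either base's total. Whether
mixed tails ending in U should count toward uridylation is genuinely
underdetermined; the homopolymer-only reading is adopted and applied
consistently.

# NTA statistics

Two deliberately different estimators are exposed:

* `meanIsomirPercent()`: the unweighted arithmetic mean of per-miRNA
  tail fractions (each miRNA one vote), over miRNAs with at least
  `minReads` (default 10) reads — the "mean isomiR percentage".
* `weightedMeanRatio()`: pooled tailed reads over pooled total reads,
  all miRNAs included — the "weighted mean ratio". On the example
  {10/100, 3/10} these give 20% and 13/110 ≈ 11.8%; tests pin both.

Condition comparisons use pseudocount-stabilised log2 fold changes of
the any-length uridylation and adenylation fractions
(`log2((c+0.5)/(t+1)) − log2(...)`, Haldane–Anscombe style, avoiding
±∞ at zero counts). A quadrant (↓U↑A etc.) is assigned only when both
axes clear a no-change band of 0.25 log2 units — the quadrant picture
is drawn without a stated band in the literature this mirrors, so the
band is a package convention, as is the ≥ log2 5 threshold for the
"five-fold adenylation gain" flag (that one follows directly from the
fold-change definition). The >1% modification filter is strict
(exactly 1% is excluded).

Arm ratios are (w5p + 0.5)/(w3p + 0.5) per condition; an arm switch is
called only when the dominant arm flips *and* both ratios sit outside a
1.5-fold balanced band. The margin keeps noise around ratio 1 from
producing spurious switch calls; miRNAs with a single annotated arm are
skipped.

# Differential expression

The DE stage is a documented negative-binomial Wald approximation, not
a reimplementation of any published package's estimators:

1. median-of-ratios size factors (linear-space median over features
   non-zero in all samples);
2. per-feature method-of-moments dispersion from the pooled excess
   variance over Poisson, shrunk toward a fitted `a0 + a1/mean` trend
   with a prior weight of 8 residual-df equivalents (per-feature
   moments at n = 4+4 are too noisy to use raw; full shrinkage would
   erase genuine dispersion differences — the blend is the usual
   compromise);
3. Wald z on the pseudocount-stabilised log2 fold change with the
   delta-method variance under `Var = mu/s + alpha*mu^2`, two-sided
   normal p-values, BH adjustment, significance at FDR < 0.01 by
   default.

Its acceptance is *calibration*: on null simulations (2,000 features,
4 vs 4, dispersion 0.1) the empirical type-I error at p < 0.05 must lie
in [0.03, 0.08], and planted 4-fold effects at dispersion 0.05 must be
detected at q < 0.01 with power ≥ 0.9. Both are recomputed by the test
suite and the acceptance script. Outlier handling (Cook's-style) and
multi-factor designs are out of scope.

Clustering of per-contrast log2 fold-change vectors uses Euclidean
k-means with k-means++ seeding, best of 25 restarts by inertia, fixed
seed 0 by default, k = 15 by default, with let-7 family rows excluded
when an annotation is supplied. The fold-change matrix is used as-is
(no row standardisation) — fold changes are already on a common scale,
and standardising would equate strong and weak responders; this is a
package choice, configurable upstream of the call.

# Downstream analyses

* **Enrichment** is an upper-tail hypergeometric test per set with BH
  across sets. The background defaults to the detected features, not
  the annotation universe: inference is conditioned on detection, and
  this is recorded in the output columns (N is always reported).
* **Negative-correlation edges** require both endpoints significant at
  the configured FDR and in opposite directions; same-direction
  significant pairs are reported separately (positive correlation does
  occur, e.g. through shared targets), and edges touching unknown or
  non-significant nodes are dropped with a report.
* **Growth curves** fit `N(t) = K/(1 + e^{-rt}(K - N0)/N0)` by
  nonlinear least squares (Levenberg–Marquardt), initialised at
  K = 1.1·max(N), N0 = first positive value, r = early-phase log-linear
  slope. The p-value of r is a Wald t-test on the estimate with n − 3
  df — the literature this follows does not describe its p-value
  construction, so a growthcurver-style Wald test is used and named as
  such. Near-constant series return the degenerate r = 0 fit (K is then
  unidentifiable) instead of erroring; non-convergence sets
  `converged = FALSE` without an exception. Confluency series are first
  baselined by subtracting the t = 0 value. Wound-width series are
  consumed by the same relative/descriptive summaries only; no closure
  model is fitted.

# The synthetic-data generator

`simulateReference()` + `simulateReads()` emulate the statistical
structure of a two-condition small RNA experiment: log-normal relative
abundances with NB replicate noise (dispersion 0.1), condition-specific
tail-type rates, a templated trim/extend mixture (canonical 45%,
+1/+2 extensions 35%, −1/−2 trims 13%, 5' shifts 7% — weighted toward
canonical and 3'-extended forms as observed in real isomiR
distributions), per-miRNA 5p/3p arm bias, per-base substitution error
(default 0.001), and the NEXTFlex wrapper (4-nt UMIs both sides,
adapter, constant "I" qualities). The default condition presets — mono-U
15% → 2%, mono-A 12% → 18%, with small di-nucleotide and other-tail
rates — are inspired by published wild-type vs TUT4/7-knockout
summaries; they are presets of the generator, not asserted generative
truths about any real dataset. One RNG stream per sample is derived
from (seed, sample index), so adding samples never perturbs earlier
ones and the whole generator is a pure function of its config.

Two design points deserve emphasis:

* **Tails are drawn after the templated variant**, so a tail can
  coincide with the next template base. The manifest stores the
  generative label, and such template-mimicking tails are *expected,
  enumerable misclassifications* for any maximal-templated classifier —
  the oracle predicts exactly which reads they are, and the
  classifier-accuracy tests exclude only those.
* **A GC identifiability guard**: by default the 4 template bases
  immediately downstream of each mature 3' end are drawn from {C, G}
  (`gcGuard = 4`, disableable). Without it, a quarter of all U/A tails
  on canonical or extended 3' ends would mimic the template and be
  (correctly) absorbed, shifting every recovered tail rate by several
  percentage points and making parameter recovery impossible for *any*
  classifier — an artifact of fully uniform random templates rather
  than a property of the method. Real loci are not uniform either.
  Mimicry remains possible on trimmed 3' ends (mature-internal bases
  are unconstrained), which keeps the ambiguity the classifier genuinely
  faces in the simulation; the residual bias this causes (a few tenths
  of a percentage point at default trim rates) is visible in the
  recovered wild-type mono-U ratio.

What the generator does **not** emulate: ligation bias, PCR duplication
beyond exact copies, indel errors, quality-score structure (qualities
are constant by design; quality-aware filtering is out of scope),
A-to-I editing, and genuine multi-locus families beyond what duplicate
arm sequences produce. Passing the recovery tests therefore shows the
pipeline's internal consistency under a realistic abundance/tail/error
model — not robustness to every artefact of real libraries.

# Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by design: the
oracle enumeration covers ~3,400 unique reads of a toy precursor; the
end-to-end recovery uses 50 miRNAs x 2 conditions x 3 replicates at 1e5
reads per sample; DE calibration uses 2,000 features at 4 vs 4;
clustering recovery uses 150 profiles in 3 planted groups. Headline
percentages from the real deposited dataset the design mirrors are
summaries of that dataset and are not reproducible from simulation;
the package therefore validates property recovery (rates, quadrants,
calibration, identities) rather than any published point estimate.

Tolerance and tie-break choices not already covered: rate maps must sum
to 1 within 1e-9; profile fraction identities are exact by
construction; k-means ties in seeding are resolved by the seeded RNG;
duplicate k-means++ centers are dropped before Lloyd iterations; BH
uses `stats::p.adjust`; the hypergeometric tail uses `stats::phyper`.

# Known limitations

* No probabilistic/quality-aware tail calling; a single substitution
  error at the 3' terminus becomes a 1-nt tail of the wrong base.
* No A-to-I editing calls: interior mismatches are flagged, not typed.
* No de novo miRNA discovery and no secondary-structure folding; Group
  I/II overhang classes are annotation-driven.
* The NB test approximates, and is validated as, a calibrated Wald
  test; it will not reproduce another tool's per-gene numbers
  bit-for-bit.
* Arm-switch detection is descriptive (ratio + margin), with no
  per-miRNA inference attached.
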