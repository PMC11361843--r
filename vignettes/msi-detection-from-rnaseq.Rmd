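---
title: "Detecting microsatellite instability from RNA-seq repeat lengths"
author: "msirna authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microsatellite instability from RNA-seq repeat lengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msirna)
```

## The problem

Microsatellites are tandem repeats of short (here 1-4 bp) motifs.  When
the DNA mismatch-repair machinery fails, replication slippage at these
tracts goes uncorrected and tumors accumulate somatic repeat-length
changes: microsatellite instability (MSI).  MSI-high (MSI-H) status
predicts response to immune checkpoint blockade, so calling it reliably
matters clinically.  Most sequencing-based callers work on DNA; msirna
calls MSI directly from RNA-seq alignments, which are often the only
sequencing data available for a sample.

RNA complicates matters in two ways.  First, observed repeat lengths in
RNA can vary for reasons unrelated to MSI (expression-linked effects,
splicing, coverage); second, most RNA-seq tumors have no matched normal.
The pipeline answers both: it restricts analysis to loci whose length is
*invariable* across a cohort of normals, and it synthesizes a *reference
normal* from those normals where no matched normal exists.

## The pipeline

1. **Catalog** (`readCatalog`): a BED-derived list of exonic
   microsatellite loci with motif and genic-region annotation (CDS,
   5'UTR, 3'UTR).  Coordinates are BED (0-based, half-open) on disk and
   ordinary 1-based GRanges inside the package.
2. **Length profiling** (`profileSample`): for every read overlapping a
   locus, the CIGAR is walked to locate the read bases aligned
   immediately 5' and 3' of the tract.  A read contributes one length
   observation -- the number of read bases strictly between those
   anchors -- only if its aligned span covers the tract plus 2 bp on
   each side, the 2 bp of read sequence abutting the tract equal the
   reference flanks exactly, and no deletion or splice crosses a
   flank/tract boundary.  Observations shorter than 5 bases are
   discarded.  The per-locus multiset of lengths is the sample's
   "length list".
3. **Invariable loci and the reference normal** (`selectInvariable`,
   `buildReferenceNormal`): a locus is invariable when strictly more
   than 95% of informative normals (at least 5 reads) share the same
   modal length.  The reference normal repeats each invariable locus's
   consensus modal length *m* times, where *m* is the per-locus median,
   across informative normals, of the read count at each sample's modal
   length (rounded half-up, floored at 5).
4. **Unstable loci** (`callUnstable`): per locus with at least 5 reads
   on both sides, a two-sample Kolmogorov-Smirnov test compares the
   tumor length distribution with the normal's;
   p-values are Benjamini-Hochberg adjusted across all tested loci of
   the sample, and loci with q below 0.05 are unstable.  Group
   differences in per-sample unstable counts are assessed with the
   two-sided Wilcoxon rank-sum test.
5. **Classification** (`trainClassifier`, `crossValidate`,
   `predictProbability`): each sample is encoded by its unstable-locus
   count in a region stratum; a 100-tree random forest (or
   gradient-boosted ensemble) is trained on a balanced resample -- 80%
   of MSI-H samples plus an equal number of MSS samples -- and evaluated
   on the held-out rest by AUC, repeated 10 times.  The reported MSI-H
   probability of a random forest is the fraction of trees voting
   MSI-H.

## Statistical choices

**KS on discrete data.**  Tract lengths are small integers, so ties are
the rule.  The statistic D is the exact sup-difference of the two
empirical CDFs evaluated on the merged support.  The default p-value
uses the asymptotic Kolmogorov distribution at
$\sqrt{n_x n_y/(n_x+n_y)}\,D$; under heavy ties this is conservative
(it understates significance), which errs toward fewer unstable calls.
`detectionConfig(test = "ks_exact_smalln")` switches small loci (both
sides at most `exactNCap` reads) to the exact conditional null
distribution given the pooled tie pattern (`stats::psmirnov`).

**Reference-normal degeneracy.**  The reference normal at a locus is a
single length repeated *m* times -- zero variance by construction.  We
deliberately do not inflate it: the comparison is then "does the tumor
put probability mass away from the consensus length", and the KS D
reduces to the tumor's off-consensus mass, with the replication count
*m* only entering the effective sample size.  This is the construction
the reference-normal definition implies, kept exactly.

**FDR scope.**  Adjustment is per sample, across all tested loci of the
sample's analysis set; when a region-restricted model is built, the
count features are taken from the same per-sample adjustment (no
re-correction within region).  Benjamini-Hochberg is the default;
Benjamini-Yekutieli is available where dependence-robustness is wanted.

**"Minimum length of five"** is read as 5 *bases*, not 5 repeat units;
for the mononucleotides that dominate MSI signal the two readings
coincide, and bases is the stricter reading for longer motifs.  It is
configurable (`profilerConfig(minTractLen=)`).

**"Over 95% of normal samples"** is read over *informative* normals
(depth at least `minReads`): counting low-coverage normals as
disagreement would conflate coverage with instability.  The inequality
is strict -- 19 agreeing samples out of 20 (exactly 95%) do not qualify.
A locus additionally needs `minNormals` (default 10) informative
normals before it can qualify at all; the cohort-level median of
modal-length frequencies is computed per locus (not globally), matching
the per-locus construction of the reference normal.

**Read filters.**  Duplicate, secondary, supplementary and QC-fail
reads are dropped; MAPQ below 20 is rejected by default (set
`minMapq = 0` to disable -- no base-quality filtering is applied
anywhere).  Soft-clipped bases never provide flank or tract evidence,
spliced alignments whose skip touches the locus window are rejected as
non-spanning, and a deletion that swallows a boundary-anchor base
rejects the read rather than guessing where the tract begins.  Every
rejection is tallied per locus by reason (`not_spanning`,
`flank_mismatch`, `boundary_indel`, `low_mapq`, `filtered_flag`, plus
`short_tract` for sub-5-base observations), so accepted plus rejected
always equals the overlapping reads seen -- useful for auditing why a
locus is quiet.

**Ties in modal lengths** (two lengths with equal read counts) break
toward the smaller length, everywhere, so results are deterministic.
Non-integer medians of replication counts round half-up.

**Cross-validation semantics.**  "Repeated cross-validation" here means
independent balanced resampling repetitions, not a k-fold partition:
the split rule (80% of MSI-H plus an equal number of MSS) is a
resampling scheme and cannot tile the data into folds.  Per-repeat
seeds derive deterministically from the configured seed.

## The simulator

`generateReference` and `simulateCohort` build the test bed every other
module is validated against: synthetic contigs carrying perfect tandem
repeats (5-15 units of 1-4 bp motifs; class mix 29/16/34/21% mono to
tetra and region mix 40/13/47% CDS/5'UTR/3'UTR, mirroring exome-wide
microsatellite composition) inside random non-repetitive flanks whose
edge bases provably cannot extend the tract.  Reads are single-end 100
bp, placed uniformly among positions that span tract plus flanks, with
Poisson(30) spanning depth per locus.

Two noise/effect processes act on each read's observed tract length:

* **Stutter**: with probability 0.02 a read slips by
  $1 + \mathrm{Geom}(0.8)$ whole motif units; the slip direction is
  symmetric by default (`stutterBias = 0.5`; set it toward 1 to model
  the contraction bias of PCR stutter).
* **Somatic shift** (MSI-H samples only): each eligible locus
  independently acquires, with probability 0.3, a fixed shift of 1-3
  motif units (random sign); each read then samples the shifted allele
  with probability 0.7 (tumor purity).  Eligible loci default to the
  3'UTR stratum, emulating the concentration of MSI events in 3'
  untranslated regions that motivates region-stratified models; the
  CDS stratum then provides a built-in negative control, and the
  expected ordering AUC(3'UTR model) >= AUC(CDS model) is literally
  constructible and tested.

The CIGAR of every simulated read encodes its indel exactly, so the
profiler can be held to zero error on noise-free data.  What the
simulator does *not* model: expression-level variation across genes and
samples (the invariable-locus filtration is the pipeline's mechanism
for that, and exercising it would require an expression model), paired
ends, alignment artifacts (clips, low MAPQ, splices are produced only
by dedicated test fixtures), and sequencing base errors outside the
tract.  Passing tests therefore demonstrate correctness of the
measurement and decision machinery under a clean generative model, not
robustness to aligner pathologies on real tissue.

One emergent behavior worth knowing: a large *contraction* shift can
push observations below the 5-base recording floor, silently dropping
the shifted allele and making a destabilized locus look stable
(allele dropout).  This is faithful to how the minimum-length rule
behaves on real data.

## Problem sizes and reproducibility

The shipped end-to-end checks simulate 30 normals + 30 MSS + 30 MSI-H
samples over 500 loci -- large enough that the invariable-recovery,
sensitivity (planted shifts of at least 2 bases at depth at least 20),
FDR and AUC properties are stable across seeds, and small enough to run
comfortably on a laptop.  Unit tests use a 120-locus, 24-sample cohort.
All randomness flows from explicit seeds: the same configuration and
seed reproduce identical catalogs, truth tables and profiles.

## Known limitations

* The asymptotic KS p-value is conservative under the extreme ties of
  degenerate reference normals; the exact mode is the audit path.
* A single scalar count feature means the classifier reduces to a
  threshold family; this is the faithful default, and
  `stratifyFeatures = TRUE` provides the per-class refinement.
* Matched-normal mode applies the same invariable-locus restriction as
  reference mode, for comparability; loci outside that set are never
  tested even when the matched normal covers them.
* Region labels come from the catalog; the package does no GTF-based
  annotation of its own, and liftover between genome builds is out of
  scope (catalogs must match the alignment build).
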