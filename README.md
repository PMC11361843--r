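# msirna

Microsatellite instability (MSI) detection from RNA-seq alignments by
direct comparison of repeat tract lengths.

## What it does, and for whom

Tumors with deficient DNA mismatch repair accumulate replication
slippage at microsatellites (tandem repeats of 1–4 bp motifs).  The
resulting MSI-high (MSI-H) phenotype is a clinically actionable
biomarker, but most sequencing-based MSI callers need DNA data and a
matched normal.  `msirna` is for analysts who have RNA-seq BAMs: it
measures microsatellite tract lengths inside reads, compares tumor
length distributions against a cohort-derived reference normal, and
classifies samples MSI-H vs. microsatellite stable (MSS).

The pipeline, per sample:

1. **Profile** — for every read overlapping a cataloged locus, walk the
   CIGAR to the read bases aligned immediately 5′ and 3′ of the tract;
   accept the read only if it spans tract + 2 bp flanks and the 2 bp of
   read sequence on each side equal the reference flanks exactly.  The
   observed length is the read-base count between the anchors
   (reference length + insertions − deletions inside the tract); lengths
   < 5 bases are discarded.
2. **Invariable loci** — a locus qualifies when strictly more than 95 %
   of informative normals (≥ 5 reads) share its modal length.
3. **Reference normal** — each invariable locus's consensus modal
   length repeated *m* times, *m* = per-locus median of the normals'
   modal-length read counts.
4. **Unstable loci** — per locus with ≥ 5 reads on both sides, the
   two-sample Kolmogorov–Smirnov statistic
   D = sup |F_tumor − F_normal| on the merged discrete support;
   Benjamini–Hochberg adjustment across the sample's tested loci;
   unstable ⇔ q < 0.05.
5. **Classify** — encode each sample by its unstable-locus count in a
   genic-region stratum (3′UTR carries the most signal), train a
   100-tree random forest (or gradient-boosted ensemble) on a balanced
   resample (80 % of MSI-H + equally many MSS), evaluate by AUC over 10
   repeats; the reported probability is the fraction of trees voting
   MSI-H.

A fully seeded simulator (`generateReference`, `simulateCohort`)
produces synthetic genomes, catalogs, and aligned reads with per-read
stutter noise and per-locus somatic shifts, plus truth tables — every
stage of the pipeline is validated against it.

## Worked example

```r
library(msirna)

cfg <- simulationConfig(nLoci = 120, seed = 20260925)
ref <- generateReference(cfg)
coh <- simulateCohort(ref$seqs, ref$catalog, cfg,
                      nNormal = 12, nMss = 6, nMsih = 6)

profs <- lapply(seq_len(nrow(coh$sheet)), function(i)
  profileSample(coh$sheet$bam[i], ref$catalog,
                sampleId = coh$sheet$sample_id[i]))
names(profs) <- coh$sheet$sample_id

normals <- profs[coh$sheet$status == "normal"]
inv <- selectInvariable(normals, detectionConfig())
rn  <- buildReferenceNormal(normals, inv$invariable, detectionConfig())
rn
#> ReferenceNormal over 120 invariable loci
#>   median replication count: 30

res <- callUnstable(profs[["msih001"]], rn, ref$catalog,
                    loci = inv$invariable)
res
#> InstabilityResult for sample msih001
#>   loci tested:   120
#>   loci unstable: 12 (FDR < 0.05)

s <- instabilitySummary(res)
s[s$class == "ALL" & s$region != "ALL", c("region", "n_tested", "n_unstable")]
#>    region n_tested n_unstable
#> 21    CDS       48          0
#> 22   UTR5       16          0
#> 23   UTR3       56         12
#> 24  OTHER        0          0
```

All 120 loci were recovered as invariable (the normals carry no somatic
shifts), and the MSI-H sample's unstable loci sit exclusively in the
3′UTR — where the simulator plants somatic shifts (~30 % of 3′UTR loci,
1–3 motif units, at 0.7 tumor purity).  MSS samples typically show 0
unstable loci, so the unstable count separates the classes; a random
forest on the 3′UTR count reaches a cross-validated mean AUC of 1.0 on
this toy cohort.

A command-line wrapper covering the same stages ships as
`inst/scripts/msirna` (subcommands `simulate`, `profile`, `refnormal`,
`detect`, `train`, `cv`, `predict`), e.g.

```sh
msirna profile --bam tumor.bam --catalog ms.bed --genome ref.fa \
       --out tumor.profile.tsv
```

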