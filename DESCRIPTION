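Package: msirna
Title: Microsatellite Instability Detection from RNA-seq by Repeat Length
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects microsatellite instability (MSI) from RNA-seq
    alignments by measuring microsatellite tract lengths inside reads at a
    catalog of exonic repeat loci, building a synthetic reference normal
    from invariable loci of a normal cohort, calling unstable loci with a
    per-locus two-sample Kolmogorov-Smirnov test under Benjamini-Hochberg
    FDR control, and classifying tumors as MSI-high versus microsatellite
    stable from unstable-locus counts with region-specific tree-ensemble
    models.  Includes a read-level simulator with a parameterized stutter
    and somatic-shift model that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    data.table,
    randomForest,
    xgboost,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
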