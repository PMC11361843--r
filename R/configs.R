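#' Profiler configuration
#'
#' Controls read-level filtering and tract measurement in
#' \code{\link{profileSample}}.
#'
#' @param minTractLen Minimum observed tract length, in bases, for a read
#'   observation to be recorded (default 5).  Shorter measurements are
#'   tallied but not added to the length profile.
#' @param flankLen Number of read bases on each side of the tract that must
#'   match the reference flanks exactly (default 2).
#' @param minMapq Minimum mapping quality (default 20; set to 0 to disable).
#' @param dropDuplicates,dropSecondary,dropSupplementary,dropQcfail Drop
#'   reads carrying the corresponding SAM flag (all default \code{TRUE}).
#' @return A list of class \code{ProfilerConfig}.
#' @examples
#' profilerConfig(minMapq = 0)
#' @export
profilerConfig <- function(minTractLen = 5L, flankLen = 2L, minMapq = 20L,
                           dropDuplicates = TRUE, dropSecondary = TRUE,
                           dropSupplementary = TRUE, dropQcfail = TRUE) {
  .assertScalarNumber(minTractLen, "minTractLen", lo = 1)
  .assertScalarNumber(flankLen, "flankLen", lo = 1)
  .assertScalarNumber(minMapq, "minMapq", lo = 0)
  structure(list(minTractLen = as.integer(minTractLen),
                 flankLen = as.integer(flankLen),
                 minMapq = as.integer(minMapq),
                 dropDuplicates = isTRUE(dropDuplicates),
                 dropSecondary = isTRUE(dropSecondary),
                 dropSupplementary = isTRUE(dropSupplementary),
                 dropQcfail = isTRUE(dropQcfail)),
            class = c("ProfilerConfig", "msirnaConfig"))
}

#' Detection configuration
#'
#' Thresholds for invariable-locus selection and unstable-locus calling.
#'
#' @param minReads Minimum reads required at a locus on \emph{each} side of
#'   the tumor/normal comparison, and for a normal sample to count as
#'   informative at a locus (default 5).
#' @param fdrAlpha FDR threshold: a locus is unstable when its BH-adjusted
#'   q-value is below this (default 0.05).
#' @param agreementThreshold A locus is invariable when \emph{strictly more}
#'   than this fraction of informative normals share its modal length
#'   (default 0.95).
#' @param minNormals Minimum number of informative normal samples a locus
#'   needs before it can be considered invariable (default 10).
#' @param test \code{"ks_asymptotic"} (default) or \code{"ks_exact_smalln"}:
#'   the exact small-sample KS p-value is used when both sides have at most
#'   \code{exactNCap} reads.
#' @param exactNCap Sample-size cap for the exact KS path (default 30).
#' @param fdrMethod \code{"BH"} (default) or \code{"BY"} for a
#'   dependence-robust correction.
#' @return A list of class \code{DetectionConfig}.
#' @examples
#' detectionConfig(fdrAlpha = 0.01)
#' @export
detectionConfig <- function(minReads = 5L, fdrAlpha = 0.05,
                            agreementThreshold = 0.95, minNormals = 10L,
                            test = c("ks_asymptotic", "ks_exact_smalln"),
                            exactNCap = 30L, fdrMethod = c("BH", "BY")) {
  .assertScalarNumber(minReads, "minReads", lo = 1)
  .assertScalarNumber(fdrAlpha, "fdrAlpha", lo = 1e-12, hi = 1 - 1e-12)
  .assertScalarNumber(agreementThreshold, "agreementThreshold", lo = 0, hi = 1)
  .assertScalarNumber(minNormals, "minNormals", lo = 1)
  structure(list(minReads = as.integer(minReads),
                 fdrAlpha = fdrAlpha,
                 agreementThreshold = agreementThreshold,
                 minNormals = as.integer(minNormals),
                 test = match.arg(test),
                 exactNCap = as.integer(exactNCap),
                 fdrMethod = match.arg(fdrMethod)),
            class = c("DetectionConfig", "msirnaConfig"))
}

#' Training configuration for MSI classifiers
#'
#' @param trainFraction Fraction of MSI-H samples drawn into the training
#'   set; an equal number of MSS samples is drawn to balance it
#'   (default 0.8).
#' @param nRepeats Number of independent resampling repetitions in
#'   \code{\link{crossValidate}} (default 10).
#' @param nTrees Ensemble size (default 100).
#' @param modelType \code{"random_forest"} (default) or
#'   \code{"gradient_boosted"}.
#' @param region Locus stratum the model is trained on: one of
#'   \code{"CDS"}, \code{"UTR5"}, \code{"UTR3"}, \code{"ALL"}.
#' @param stratifyFeatures If \code{TRUE}, use one unstable-count feature
#'   per repeat class within the region plus the total; default is the
#'   single scalar count (\code{FALSE}).
#' @param seed Integer seed controlling sampling and model fitting.
#' @return A list of class \code{TrainingConfig}.
#' @examples
#' trainingConfig(region = "UTR3", seed = 1)
#' @export
trainingConfig <- function(trainFraction = 0.8, nRepeats = 10L, nTrees = 100L,
                           modelType = c("random_forest", "gradient_boosted"),
                           region = c("ALL", "CDS", "UTR5", "UTR3"),
                           stratifyFeatures = FALSE, seed = 1L) {
  .assertScalarNumber(trainFraction, "trainFraction", lo = 1e-9, hi = 1 - 1e-9)
  .assertScalarNumber(nRepeats, "nRepeats", lo = 1)
  .assertScalarNumber(nTrees, "nTrees", lo = 1)
  .assertScalarNumber(seed, "seed")
  structure(list(trainFraction = trainFraction,
                 nRepeats = as.integer(nRepeats),
                 nTrees = as.integer(nTrees),
                 modelType = match.arg(modelType),
                 region = match.arg(region),
                 stratifyFeatures = isTRUE(stratifyFeatures),
                 seed = as.integer(seed)),
            class = c("TrainingConfig", "msirnaConfig"))
}

#' Simulation configuration
#'
#' Parameters of the synthetic test bed: a toy genome carrying
#' microsatellite loci, and aligned single-end reads with PCR/sequencing
#' stutter noise plus, for MSI-H samples, somatic repeat-length shifts.
#'
#' @param nLoci Number of loci in the synthetic catalog (default 500).
#' @param regionMix Named proportions over \code{CDS}, \code{UTR5},
#'   \code{UTR3}.  Defaults follow the genic-region composition of an
#'   exome-wide microsatellite catalog (40\% CDS, 13\% 5'UTR, 47\% 3'UTR).
#' @param classMix Named proportions over \code{mono}, \code{di},
#'   \code{tri}, \code{tetra} repeat classes (defaults 0.29/0.16/0.34/0.21,
#'   again mirroring exome-wide composition).
#' @param flankLenRef Reference (non-repetitive) flank length per locus, in
#'   bases (default 60).
#' @param tractUnits Integer range of true repeat units per locus
#'   (default \code{c(5, 15)}).
#' @param coverageMean Mean spanning-read depth per locus; depths are
#'   Poisson (default 30).
#' @param readLen Read length in bases (default 100).
#' @param stutterRate Per-read probability that the observed tract slips by
#'   one or more whole motif units (default 0.02).
#' @param stutterGeom Geometric success parameter for the slip size in
#'   motif units: slip = 1 + Geom(\code{stutterGeom}) (default 0.8).
#' @param stutterBias Probability that a slip is a contraction rather than
#'   an expansion (default 0.5, i.e. symmetric; 1 models the deletion bias
#'   of PCR stutter).
#' @param destabilizedFraction Per-locus probability that an eligible locus
#'   carries a somatic length shift in an MSI-H sample (default 0.3).
#' @param destabilizedRegions Genic regions eligible for somatic shifts in
#'   MSI-H samples (default \code{"UTR3"}, emulating the concentration of
#'   MSI events in 3' untranslated regions).
#' @param shiftUnits Integer range of somatic shift magnitudes in motif
#'   units (default \code{c(1, 3)}); the sign is random.
#' @param tumorPurity Fraction of reads at a destabilized locus drawn from
#'   the shifted allele (default 0.7).
#' @param lociPerContig Loci laid side by side per synthetic contig
#'   (default 50).
#' @param seed Master seed for reproducible generation.
#' @return A list of class \code{SimulationConfig}.
#' @examples
#' simulationConfig(nLoci = 50, seed = 7)
#' @export
simulationConfig <- function(nLoci = 500L,
                             regionMix = c(CDS = 0.40, UTR5 = 0.13, UTR3 = 0.47),
                             classMix = c(mono = 0.29, di = 0.16,
                                          tri = 0.34, tetra = 0.21),
                             flankLenRef = 60L,
                             tractUnits = c(5L, 15L),
                             coverageMean = 30,
                             readLen = 100L,
                             stutterRate = 0.02,
                             stutterGeom = 0.8,
                             stutterBias = 0.5,
                             destabilizedFraction = 0.3,
                             destabilizedRegions = "UTR3",
                             shiftUnits = c(1L, 3L),
                             tumorPurity = 0.7,
                             lociPerContig = 50L,
                             seed = 1L) {
  .assertScalarNumber(nLoci, "nLoci", lo = 1)
  stopifnot(setequal(names(regionMix), c("CDS", "UTR5", "UTR3")),
            setequal(names(classMix), c("mono", "di", "tri", "tetra")))
  if (abs(sum(regionMix) - 1) > 1e-6 || abs(sum(classMix) - 1) > 1e-6)
    stop("regionMix and classMix must each sum to 1", call. = FALSE)
  if (any(regionMix < 0) || any(classMix < 0))
    stop("mix proportions must be non-negative", call. = FALSE)
  .assertScalarNumber(stutterRate, "stutterRate", lo = 0, hi = 1)
  .assertScalarNumber(stutterGeom, "stutterGeom", lo = 1e-6, hi = 1)
  .assertScalarNumber(stutterBias, "stutterBias", lo = 0, hi = 1)
  .assertScalarNumber(destabilizedFraction, "destabilizedFraction", 0, 1)
  .assertScalarNumber(tumorPurity, "tumorPurity", lo = 0, hi = 1)
  stopifnot(length(tractUnits) == 2L, tractUnits[1] >= 1,
            tractUnits[1] <= tractUnits[2],
            length(shiftUnits) == 2L, shiftUnits[1] >= 1,
            shiftUnits[1] <= shiftUnits[2],
            all(destabilizedRegions %in% c("CDS", "UTR5", "UTR3")))
  .assertScalarNumber(seed, "seed")
  structure(list(nLoci = as.integer(nLoci),
                 regionMix = regionMix[c("CDS", "UTR5", "UTR3")],
                 classMix = classMix[c("mono", "di", "tri", "tetra")],
                 flankLenRef = as.integer(flankLenRef),
                 tractUnits = as.integer(tractUnits),
                 coverageMean = coverageMean,
                 readLen = as.integer(readLen),
                 stutterRate = stutterRate,
                 stutterGeom = stutterGeom,
                 stutterBias = stutterBias,
                 destabilizedFraction = destabilizedFraction,
                 destabilizedRegions = destabilizedRegions,
                 shiftUnits = as.integer(shiftUnits),
                 tumorPurity = tumorPurity,
                 lociPerContig = as.integer(lociPerContig),
                 seed = as.integer(seed)),
            class = c("SimulationConfig", "msirnaConfig"))
}

#' @export
print.msirnaConfig <- function(x, ...) {
  cat(class(x)[1], ":\n", sep = "")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat("  ", nm, " = ",
        if (length(v) > 1L) paste(v, collapse = ", ") else format(v),
        "\n", sep = "")
  }
  invisible(x)
}
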