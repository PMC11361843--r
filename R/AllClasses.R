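#' Microsatellite locus catalog
#'
#' An \code{MsCatalog} is a \code{\link[GenomicRanges]{GRanges}} whose
#' ranges are microsatellite tracts (1-based, inclusive, as usual for
#' GRanges; BED input/output converts at the file boundary) and whose
#' metadata columns carry, per locus:
#' \describe{
#'   \item{\code{locus_id}}{unique stable key.}
#'   \item{\code{motif}}{repeat unit over \{A,C,G,T\}, 1-4 bases.}
#'   \item{\code{region}}{genic region: \code{CDS}, \code{UTR5},
#'     \code{UTR3} or \code{OTHER}.}
#'   \item{\code{gene}}{gene symbol (may be empty).}
#'   \item{\code{flank5}, \code{flank3}}{reference flanks recorded during
#'     genome validation (\code{NA} before validation).}
#'   \item{\code{perfect}}{\code{TRUE} when the reference tract is an exact
#'     (whole or partial) tandem of the motif; imperfect tracts are kept
#'     but flagged, and excluded by the default pipeline.}
#' }
#'
#' @seealso \code{\link{readCatalog}}, \code{\link{filterCatalog}},
#'   \code{\link{classifyMotif}}
#' @export
setClass("MsCatalog", contains = "GRanges")

.validMsCatalog <- function(object) {
  msgs <- character()
  mc <- S4Vectors::mcols(object)
  need <- c("locus_id", "motif", "region", "gene")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(mc$locus_id))
    msgs <- c(msgs, "locus_id values must be unique")
  bad <- grepl("[^ACGT]", mc$motif) | nchar(mc$motif) < 1L | nchar(mc$motif) > 4L
  if (any(bad))
    msgs <- c(msgs, sprintf("%d motif(s) outside {A,C,G,T}^1..4", sum(bad)))
  if (!all(mc$region %in% c("CDS", "UTR5", "UTR3", "OTHER")))
    msgs <- c(msgs, "region labels must be CDS/UTR5/UTR3/OTHER")
  if (any(GenomicRanges::width(object) < 1L))
    msgs <- c(msgs, "tract widths must be >= 1")
  if (length(msgs)) msgs else TRUE
}
setValidity("MsCatalog", .validMsCatalog)

#' Per-sample microsatellite length profile
#'
#' The "length list" of one sample: for every cataloged locus with at least
#' one accepted spanning read, the multiset of observed tract lengths.
#' Stored long: one row per (locus, length) with the number of supporting
#' reads.  Rejected reads are tallied per locus and reason so that
#' accepted + rejected reconstructs the number of overlapping reads seen.
#'
#' @slot sampleId Sample identifier.
#' @slot counts \code{data.frame} with columns \code{locus_id},
#'   \code{length} (bases), \code{count} (reads, positive integer).
#' @slot rejections \code{data.frame} with columns \code{locus_id},
#'   \code{reason}, \code{n}.
#' @seealso \code{\link{profileSample}}, \code{\link{readProfile}},
#'   \code{\link{writeProfile}}
#' @export
setClass("LengthProfile",
         representation(sampleId = "character",
                        counts = "data.frame",
                        rejections = "data.frame"))

.validLengthProfile <- function(object) {
  msgs <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msgs <- c(msgs, "sampleId must be a single string")
  cnt <- object@counts
  if (!all(c("locus_id", "length", "count") %in% names(cnt)))
    msgs <- c(msgs, "counts needs columns locus_id, length, count")
  else {
    if (nrow(cnt) && (any(cnt$count < 1) || any(cnt$count != floor(cnt$count))))
      msgs <- c(msgs, "read counts must be strictly positive integers")
    if (nrow(cnt) && any(cnt$length < 1))
      msgs <- c(msgs, "tract lengths must be >= 1 base")
    if (anyDuplicated(cnt[c("locus_id", "length")]))
      msgs <- c(msgs, "duplicate (locus_id, length) rows")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("LengthProfile", .validLengthProfile)

#' Synthetic reference normal
#'
#' Stands in for a matched normal when none exists: at every invariable
#' locus the cohort-consensus modal length, replicated a median-frequency
#' number of times.  The implied length multiset at a locus is
#' \code{ref_length} repeated \code{ref_count} times.
#'
#' @slot table \code{data.frame} with columns \code{locus_id},
#'   \code{ref_length} (bases), \code{ref_count} (reads).
#' @seealso \code{\link{buildReferenceNormal}}, \code{\link{callUnstable}}
#' @export
setClass("ReferenceNormal", representation(table = "data.frame"))

.validReferenceNormal <- function(object) {
  tb <- object@table
  if (!all(c("locus_id", "ref_length", "ref_count") %in% names(tb)))
    return("table needs columns locus_id, ref_length, ref_count")
  if (anyDuplicated(tb$locus_id)) return("duplicate locus_id")
  if (nrow(tb) && any(tb$ref_count < 1)) return("ref_count must be >= 1")
  TRUE
}
setValidity("ReferenceNormal", .validReferenceNormal)

#' Per-sample instability result
#'
#' Output of \code{\link{callUnstable}}: one KS test per tested locus plus
#' the per-sample summary of unstable-locus counts stratified by genic
#' region and repeat class.
#'
#' @slot sampleId Tumor sample identifier.
#' @slot calls \code{data.frame} with columns \code{locus_id},
#'   \code{region}, \code{class}, \code{n_tumor}, \code{n_normal},
#'   \code{D}, \code{p}, \code{q}, \code{unstable}.
#' @slot summary \code{data.frame} with columns \code{region},
#'   \code{class}, \code{n_tested}, \code{n_unstable}; includes
#'   \code{ALL} marginals.
#' @slot config The \code{DetectionConfig} used.
#' @export
setClass("InstabilityResult",
         representation(sampleId = "character",
                        calls = "data.frame",
                        summary = "data.frame",
                        config = "list"))

#' Trained MSI status classifier
#'
#' A fitted tree ensemble (random forest or gradient-boosted trees) mapping
#' unstable-locus counts to an MSI-H probability, together with everything
#' needed to reproduce it: config, feature schema and seed.
#'
#' @slot modelType \code{"random_forest"} or \code{"gradient_boosted"}.
#' @slot region Locus stratum the model was trained on.
#' @slot fit The underlying fitted model object.
#' @slot featureNames Feature column names expected at prediction time.
#' @slot config The \code{TrainingConfig} used.
#' @export
setClass("MSIModel",
         representation(modelType = "character",
                        region = "character",
                        fit = "ANY",
                        featureNames = "character",
                        config = "list"))
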