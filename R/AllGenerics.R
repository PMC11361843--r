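#' @name msirna-accessors
#' @title Accessors for msirna classes
#' @description Small accessor generics: prefer these over direct slot
#'   access.
#' @param x An msirna object.
#' @return The corresponding slot or derived vector.
NULL

#' @rdname msirna-accessors
#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))

#' @rdname msirna-accessors
#' @export
setGeneric("motifs", function(x) standardGeneric("motifs"))

#' @rdname msirna-accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname msirna-accessors
#' @export
setGeneric("repeatClass", function(x) standardGeneric("repeatClass"))

#' @rdname msirna-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname msirna-accessors
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname msirna-accessors
#' @export
setGeneric("rejectionTallies", function(x) standardGeneric("rejectionTallies"))

#' @rdname msirna-accessors
#' @export
setGeneric("locusDepths", function(x) standardGeneric("locusDepths"))

#' @rdname msirna-accessors
#' @export
setGeneric("refTable", function(x) standardGeneric("refTable"))

#' @rdname msirna-accessors
#' @export
setGeneric("instabilityCalls", function(x) standardGeneric("instabilityCalls"))

#' @rdname msirna-accessors
#' @export
setGeneric("instabilitySummary",
           function(x) standardGeneric("instabilitySummary"))

# ---- MsCatalog ----

#' @rdname msirna-accessors
#' @export
setMethod("locusIds", "MsCatalog", function(x) mcols(x)$locus_id)

#' @rdname msirna-accessors
#' @export
setMethod("motifs", "MsCatalog", function(x) mcols(x)$motif)

#' @rdname msirna-accessors
#' @export
setMethod("regions", "MsCatalog", function(x) mcols(x)$region)

#' @rdname msirna-accessors
#' @export
setMethod("repeatClass", "MsCatalog", function(x) classifyMotif(motifs(x)))

setMethod("show", "MsCatalog", function(object) {
  cls <- table(factor(classifyMotif(mcols(object)$motif),
                      levels = c("mono", "di", "tri", "tetra")))
  reg <- table(factor(mcols(object)$region,
                      levels = c("CDS", "UTR5", "UTR3", "OTHER")))
  cat("MsCatalog with", length(object), "loci on",
      length(unique(as.character(seqnames(object)))), "sequence(s)\n")
  cat("  repeat classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
  cat("  regions:      ",
      paste(sprintf("%s=%d", names(reg), reg), collapse = " "), "\n")
  if ("perfect" %in% colnames(mcols(object)))
    cat("  imperfect-tract flagged:", sum(!mcols(object)$perfect), "\n")
})

# ---- LengthProfile ----

#' @rdname msirna-accessors
#' @export
setMethod("sampleId", "LengthProfile", function(x) x@sampleId)

#' @rdname msirna-accessors
#' @export
setMethod("profileCounts", "LengthProfile", function(x) x@counts)

#' @rdname msirna-accessors
#' @export
setMethod("rejectionTallies", "LengthProfile", function(x) x@rejections)

#' @rdname msirna-accessors
#' @export
setMethod("locusIds", "LengthProfile",
          function(x) unique(x@counts$locus_id))

#' @rdname msirna-accessors
#' @export
setMethod("locusDepths", "LengthProfile", function(x) {
  if (!nrow(x@counts)) return(setNames(integer(0), character(0)))
  agg <- tapply(x@counts$count, x@counts$locus_id, sum)
  setNames(as.integer(agg), names(agg))
})

setMethod("show", "LengthProfile", function(object) {
  d <- locusDepths(object)
  cat("LengthProfile for sample", object@sampleId, "\n")
  cat("  loci with accepted reads:", length(d), "\n")
  cat("  total accepted reads:    ", sum(d), "\n")
  if (nrow(object@rejections))
    cat("  rejected reads:          ", sum(object@rejections$n), "\n")
})

# ---- ReferenceNormal ----

#' @rdname msirna-accessors
#' @export
setMethod("refTable", "ReferenceNormal", function(x) x@table)

#' @rdname msirna-accessors
#' @export
setMethod("locusIds", "ReferenceNormal", function(x) x@table$locus_id)

#' @rdname msirna-accessors
#' @export
setMethod("locusDepths", "ReferenceNormal", function(x)
  setNames(as.integer(x@table$ref_count), x@table$locus_id))

setMethod("show", "ReferenceNormal", function(object) {
  cat("ReferenceNormal over", nrow(object@table), "invariable loci\n")
  if (nrow(object@table))
    cat("  median replication count:", median(object@table$ref_count), "\n")
})

# ---- InstabilityResult ----

#' @rdname msirna-accessors
#' @export
setMethod("sampleId", "InstabilityResult", function(x) x@sampleId)

#' @rdname msirna-accessors
#' @export
setMethod("instabilityCalls", "InstabilityResult", function(x) x@calls)

#' @rdname msirna-accessors
#' @export
setMethod("instabilitySummary", "InstabilityResult", function(x) x@summary)

setMethod("show", "InstabilityResult", function(object) {
  tot <- object@summary[object@summary$region == "ALL" &
                          object@summary$class == "ALL", ]
  cat("InstabilityResult for sample", object@sampleId, "\n")
  cat("  loci tested:  ", tot$n_tested, "\n")
  cat("  loci unstable:", tot$n_unstable,
      sprintf("(FDR < %g)\n", object@config$fdrAlpha))
})

# ---- MSIModel ----

setMethod("show", "MSIModel", function(object) {
  cat("MSIModel (", object@modelType, ", region ", object@region, ")\n",
      sep = "")
  cat("  trees:   ", object@config$nTrees, "\n")
  cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
})
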