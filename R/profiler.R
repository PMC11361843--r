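# Per-read tract measurement and per-sample length profiling.
#
# The measurement itself (CIGAR walk, anchor location, flank comparison)
# lives in src/measure_tract.cpp; this file provides the user-facing
# wrapper and the BAM iteration.

.REJECT_REASONS <- c("filtered_flag", "low_mapq", "not_spanning",
                     "flank_mismatch", "boundary_indel", "short_tract")

.reasonFromCode <- function(code) {
  # codes from the C++ kernel: -1 not_spanning, -2 flank_mismatch,
  # -3 boundary_indel
  c("not_spanning", "flank_mismatch", "boundary_indel")[-code]
}

#' Measure the observed tract length of one aligned read at one locus
#'
#' Locates, via the read's CIGAR, the read bases aligned to the reference
#' positions immediately 5' and 3' of the microsatellite tract.  The read
#' is rejected unless its aligned (non-clipped, non-spliced) span covers
#' the tract plus \code{flankLen} bases on each side, and the
#' \code{flankLen} read bases abutting the tract equal the reference
#' flanks exactly (case-insensitive; an N in the read flank rejects).  A
#' deletion swallowing either boundary-anchor base rejects the read rather
#' than guessing the boundary.  The measured length is the number of read
#' bases strictly between the two anchors: the reference tract length plus
#' insertions minus deletions inside the tract.
#'
#' @param read A list with elements \code{pos} (1-based leftmost mapped
#'   position), \code{cigar}, \code{seq}, and optionally \code{mapq} and
#'   \code{flag}.
#' @param locus A single-locus \code{\linkS4class{MsCatalog}}, or a list
#'   with 0-based half-open \code{start} and \code{end}.
#' @param flanks Character vector \code{c(flank5, flank3)} of reference
#'   flanks; taken from the catalog metadata when omitted.
#' @param cfg A \code{\link{profilerConfig}}.
#' @return A list with \code{accepted} (logical), \code{length} (bases, or
#'   \code{NA}), and \code{reason} (one of \code{filtered_flag},
#'   \code{low_mapq}, \code{not_spanning}, \code{flank_mismatch},
#'   \code{boundary_indel}, \code{short_tract}, or \code{NA} when
#'   accepted).
#' @examples
#' loc <- msCatalog(data.frame(chrom = "c", start = 10, end = 20,
#'                             motif = "A", region = "UTR3", gene = "g"))
#' read <- list(pos = 1, cigar = "30M",
#'              seq = paste0("GGGGGGGG", "CT", "AAAAAAAAAA", "GT",
#'                           "GGGGGGGG"))
#' measureTractLength(read, loc, flanks = c("CT", "GT"))$length  # 10
#' @export
measureTractLength <- function(read, locus, flanks = NULL,
                               cfg = profilerConfig()) {
  if (methods::is(locus, "MsCatalog")) {
    stopifnot(length(locus) == 1L)
    start0 <- GenomicRanges::start(locus) - 1L
    end0 <- GenomicRanges::end(locus)
    if (is.null(flanks)) {
      mc <- S4Vectors::mcols(locus)
      flanks <- c(mc$flank5, mc$flank3)
    }
  } else {
    start0 <- locus$start
    end0 <- locus$end
  }
  if (is.null(flanks) || any(is.na(flanks)))
    stop("reference flanks are required (validate the catalog against ",
         "a genome or pass 'flanks')", call. = FALSE)

  flag <- read$flag %||% 0L
  dropBits <- sum(c(1024L, 256L, 2048L, 512L) *
                    c(cfg$dropDuplicates, cfg$dropSecondary,
                      cfg$dropSupplementary, cfg$dropQcfail))
  if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, dropBits) != 0L)
    return(list(accepted = FALSE, length = NA_integer_,
                reason = "filtered_flag"))
  mapq <- read$mapq %||% 255L
  if (!is.na(mapq) && mapq < cfg$minMapq)
    return(list(accepted = FALSE, length = NA_integer_, reason = "low_mapq"))

  code <- .measure_tract_cpp(as.integer(read$pos), as.character(read$cigar),
                             as.character(read$seq), as.integer(start0),
                             as.integer(end0), flanks[1], flanks[2],
                             cfg$flankLen)
  if (code < 0L)
    return(list(accepted = FALSE, length = NA_integer_,
                reason = .reasonFromCode(code)))
  if (code < cfg$minTractLen)
    return(list(accepted = FALSE, length = as.integer(code),
                reason = "short_tract"))
  list(accepted = TRUE, length = as.integer(code), reason = NA_character_)
}

#' Profile microsatellite tract lengths of one sample
#'
#' Iterates the reads overlapping every cataloged locus in a
#' coordinate-sorted, indexed BAM (a SAM file is converted on the fly),
#' measures each read's observed tract length
#' (\code{\link{measureTractLength}}) and accumulates the per-locus length
#' multiset -- the sample's "length list".  Rejected reads are tallied per
#' locus and reason, so accepted + rejected equals the number of
#' overlapping reads seen.
#'
#' @param file BAM or SAM file.  A missing BAM index is created; SAM input
#'   is converted to a temporary sorted BAM.
#' @param catalog An \code{\linkS4class{MsCatalog}}, genome-validated (so
#'   that reference flanks are recorded) unless \code{genome} is given.
#' @param cfg A \code{\link{profilerConfig}}.
#' @param genome Optional reference passed to catalog validation when the
#'   catalog lacks flank annotations.
#' @param sampleId Sample identifier (default: file name without
#'   extension).
#' @return A \code{\linkS4class{LengthProfile}}.
#' @seealso \code{\link{writeProfile}}, \code{\link{readProfile}}
#' @export
profileSample <- function(file, catalog, cfg = profilerConfig(),
                          genome = NULL, sampleId = NULL) {
  stopifnot(methods::is(catalog, "MsCatalog"))
  if (is.null(sampleId))
    sampleId <- sub("\\.(bam|sam)$", "", basename(file), ignore.case = TRUE)

  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(file, ".bai"))) {
    Rsamtools::indexBam(file)
  }

  mc <- S4Vectors::mcols(catalog)
  if (any(is.na(mc$flank5)) || any(is.na(mc$flank3))) {
    if (is.null(genome))
      stop("catalog lacks reference flanks; pass 'genome' or validate the ",
           "catalog with readCatalog(..., genome=)", call. = FALSE)
    catalog <- .validateCatalogGenome(catalog, genome, flankLen = cfg$flankLen)
    mc <- S4Vectors::mcols(catalog)
  }

  targets <- names(Rsamtools::scanBamHeader(file)[[1]]$targets)
  chroms <- as.character(GenomicRanges::seqnames(catalog))
  present <- chroms %in% targets
  if (!all(present)) {
    warning(sum(!present), " locus/loci on chromosome(s) absent from the ",
            "alignment header skipped")
    catalog <- catalog[present]
    mc <- S4Vectors::mcols(catalog)
  }
  if (!length(catalog))
    stop("no catalog loci on chromosomes present in ", file, call. = FALSE)

  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::granges(catalog),
    what = c("pos", "cigar", "seq", "mapq", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  hits <- Rsamtools::scanBam(file, param = param)

  st0 <- GenomicRanges::start(catalog) - 1L
  en0 <- GenomicRanges::end(catalog)
  dropBits <- sum(c(1024L, 256L, 2048L, 512L) *
                    c(cfg$dropDuplicates, cfg$dropSecondary,
                      cfg$dropSupplementary, cfg$dropQcfail))

  cnt <- vector("list", length(catalog))
  rej <- vector("list", length(catalog))
  for (i in seq_along(catalog)) {
    h <- hits[[i]]
    nread <- length(h$pos)
    if (!nread) next
    reasons <- character(0)
    flagged <- bitwAnd(h$flag, dropBits) != 0L
    if (any(flagged))
      reasons <- c(reasons, rep("filtered_flag", sum(flagged)))
    mapq <- h$mapq
    mapq[is.na(mapq)] <- 255L
    lowq <- !flagged & mapq < cfg$minMapq
    if (any(lowq)) reasons <- c(reasons, rep("low_mapq", sum(lowq)))
    use <- !flagged & !lowq
    if (any(use)) {
      codes <- .measure_tract_cpp(h$pos[use], h$cigar[use],
                                  as.character(h$seq[use]),
                                  st0[i], en0[i],
                                  mc$flank5[i], mc$flank3[i], cfg$flankLen)
      bad <- codes < 0L
      if (any(bad))
        reasons <- c(reasons, .reasonFromCode(codes[bad]))
      lens <- codes[!bad]
      short <- lens < cfg$minTractLen
      if (any(short)) reasons <- c(reasons, rep("short_tract", sum(short)))
      lens <- lens[!short]
      if (length(lens)) {
        tab <- table(lens)
        cnt[[i]] <- data.table::data.table(
          locus_id = mc$locus_id[i],
          length = as.integer(names(tab)),
          count = as.integer(tab))
      }
    }
    if (length(reasons)) {
      rtab <- table(reasons)
      rej[[i]] <- data.table::data.table(
        locus_id = mc$locus_id[i],
        reason = names(rtab), n = as.integer(rtab))
    }
  }
  counts <- data.table::rbindlist(cnt)
  rejections <- data.table::rbindlist(rej)
  if (!nrow(counts))
    counts <- data.table::data.table(locus_id = character(0),
                                     length = integer(0), count = integer(0))
  if (!nrow(rejections))
    rejections <- data.table::data.table(locus_id = character(0),
                                         reason = character(0),
                                         n = integer(0))
  methods::new("LengthProfile", sampleId = sampleId,
               counts = as.data.frame(counts),
               rejections = as.data.frame(rejections))
}

.PROFILE_FORMAT <- "msirna_profile_v1"

#' Write / read a length profile
#'
#' Profiles are stored as tab-separated text with a versioned header:
#' comment lines \code{#format=} and \code{#sample=}, then columns
#' \code{sample_id}, \code{locus_id}, \code{length}, \code{count}.  The
#' round trip is lossless for the length counts (rejection tallies are a
#' run diagnostic and are not serialized).
#'
#' @param profile A \code{\linkS4class{LengthProfile}}.
#' @param path Output (input) file.
#' @return \code{writeProfile}: \code{path}, invisibly;
#'   \code{readProfile}: a \code{LengthProfile}.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(methods::is(profile, "LengthProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#format=", .PROFILE_FORMAT),
               paste0("#sample=", profile@sampleId),
               "sample_id\tlocus_id\tlength\tcount"), con)
  cnt <- profile@counts
  if (nrow(cnt)) {
    cnt <- cnt[order(cnt$locus_id, cnt$length), , drop = FALSE]
    utils::write.table(
      data.frame(sample_id = profile@sampleId, cnt),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  lines <- readLines(path, n = 2L)
  if (!length(lines) || !identical(lines[1], paste0("#format=",
                                                    .PROFILE_FORMAT)))
    stop("not a ", .PROFILE_FORMAT, " file (header mismatch): ", path,
         call. = FALSE)
  sid <- sub("^#sample=", "", lines[2])
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c("character", "character",
                                         "integer", "integer"))
  counts <- df[c("locus_id", "length", "count")]
  if (nrow(counts) && !all(df$sample_id == sid))
    stop("sample_id column disagrees with header in ", path, call. = FALSE)
  methods::new("LengthProfile", sampleId = sid, counts = counts,
               rejections = data.frame(locus_id = character(0),
                                       reason = character(0),
                                       n = integer(0)))
}
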