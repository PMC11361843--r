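# Synthetic test bed: toy genome + catalog, and aligned reads with a
# stutter / somatic-shift model, with per-locus truth tables.

.BASES <- c("A", "C", "G", "T")

# Random flank of n bases with no homopolymer run of 4+ (so flanks never
# look like mononucleotide microsatellites) and constrained edge bases so
# the flank can never extend the repeat tract.
.randFlank <- function(n, forbidFirst = NULL, forbidLast = NULL) {
  b <- sample(.BASES, n, replace = TRUE)
  repeat {
    r <- rle(b)
    long <- which(r$lengths >= 4L)
    if (!length(long)) break
    ends <- cumsum(r$lengths)
    for (j in long) {
      at <- ends[j] - 1L
      b[at] <- sample(setdiff(.BASES, b[at]), 1L)
    }
  }
  if (!is.null(forbidFirst) && b[1L] == forbidFirst)
    b[1L] <- sample(setdiff(.BASES, c(forbidFirst, b[2L])), 1L)
  if (!is.null(forbidLast) && b[n] == forbidLast)
    b[n] <- sample(setdiff(.BASES, c(forbidLast, b[n - 1L])), 1L)
  paste(b, collapse = "")
}

# A motif whose minimal period equals its length (an "AT"-type dimer is a
# real dimer, never a disguised mononucleotide).
.randMotif <- function(unitLen) {
  repeat {
    m <- paste(sample(.BASES, unitLen, replace = TRUE), collapse = "")
    periods <- seq_len(unitLen - 1L)
    ok <- !any(vapply(periods, function(p)
      unitLen %% p == 0L &&
        m == strrep(substr(m, 1L, p), unitLen %/% p), logical(1)))
    if (unitLen == 1L || ok) return(m)
  }
}

#' Generate a synthetic reference genome and microsatellite catalog
#'
#' Builds contigs of \code{lociPerContig} loci each, every locus being a
#' perfect tandem repeat (motif class and genic-region label drawn from
#' the configured mixes) embedded in random non-repetitive flanks whose
#' edge bases are guaranteed not to extend the tract.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @param dir Output directory (created if needed) for the FASTA and its
#'   index.
#' @return A list with \code{genome} (FASTA path), \code{catalog} (a
#'   genome-validated \code{\linkS4class{MsCatalog}}), \code{seqs} (named
#'   character vector of contig sequences), and \code{cfg}.
#' @seealso \code{\link{simulateSample}}, \code{\link{simulateCohort}}
#' @export
generateReference <- function(cfg = simulationConfig(), dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  n <- cfg$nLoci
  unitLen <- c(mono = 1L, di = 2L, tri = 3L, tetra = 4L)[
    sample(names(cfg$classMix), n, replace = TRUE, prob = cfg$classMix)]
  motif <- vapply(unitLen, .randMotif, character(1))
  region <- sample(names(cfg$regionMix), n, replace = TRUE,
                   prob = cfg$regionMix)
  uRange <- seq.int(cfg$tractUnits[1], cfg$tractUnits[2])
  units <- uRange[sample.int(length(uRange), n, replace = TRUE)]
  tractLen <- units * unitLen

  contig <- paste0("ctg", sprintf("%03d", (seq_len(n) - 1L) %/%
                                    cfg$lociPerContig + 1L))
  rows <- vector("list", n)
  seqParts <- split(seq_len(n), contig)
  seqs <- character(length(seqParts))
  names(seqs) <- names(seqParts)
  for (ct in names(seqParts)) {
    idx <- seqParts[[ct]]
    offset <- 0L
    parts <- character(0)
    for (i in idx) {
      lf <- .randFlank(cfg$flankLenRef,
                       forbidLast = substr(motif[i], unitLen[i], unitLen[i]))
      rf <- .randFlank(cfg$flankLenRef,
                       forbidFirst = substr(motif[i], 1L, 1L))
      tract <- strrep(motif[i], units[i])
      start0 <- offset + cfg$flankLenRef
      rows[[i]] <- data.frame(
        chrom = ct, start = start0, end = start0 + tractLen[i],
        motif = motif[i], region = region[i],
        gene = sprintf("GENE%04d", i), stringsAsFactors = FALSE)
      parts <- c(parts, lf, tract, rf)
      offset <- offset + 2L * cfg$flankLenRef + tractLen[i]
    }
    seqs[ct] <- paste(parts, collapse = "")
  }
  df <- do.call(rbind, rows)

  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  Rsamtools::indexFa(fa)
  catalog <- .validateCatalogGenome(msCatalog(df), seqs)
  stopifnot(all(S4Vectors::mcols(catalog)$perfect))
  list(genome = fa, catalog = catalog, seqs = seqs, cfg = cfg)
}

#' Simulate aligned reads for one sample
#'
#' Per locus, the spanning-read depth is Poisson; in an MSI-H sample each
#' eligible locus (region in \code{destabilizedRegions}) independently
#' acquires a somatic repeat-length shift with probability
#' \code{destabilizedFraction}.  Each read draws the shifted allele with
#' probability \code{tumorPurity} (destabilized loci only), then slips by
#' whole motif units with probability \code{stutterRate}; the read is
#' placed uniformly so tract and flanks lie inside it, and its CIGAR
#' encodes the exact indel relative to the reference.  Output is a
#' coordinate-sorted, indexed BAM plus per-locus truth rows.
#'
#' @param genome Genome as returned by \code{\link{generateReference}}
#'   (FASTA path or named character vector of contig sequences).
#' @param catalog The matching \code{\linkS4class{MsCatalog}}.
#' @param cfg The \code{\link{simulationConfig}}.
#' @param status One of \code{"normal"}, \code{"MSS"}, \code{"MSI-H"}.
#' @param sampleId Sample name (also the BAM file stem).
#' @param dir Output directory.
#' @param seed Per-sample seed (default derived from \code{cfg$seed}).
#' @return A list with \code{bam} (path) and \code{truth} (data.frame with
#'   columns \code{sample_id}, \code{locus_id}, \code{ref_length},
#'   \code{destabilized}, \code{shift_bases}, \code{expected_modal},
#'   \code{depth}).
#' @export
simulateSample <- function(genome, catalog, cfg, status, sampleId,
                           dir = tempfile(), seed = NULL) {
  status <- match.arg(status, c("normal", "MSS", "MSI-H"))
  stopifnot(methods::is(catalog, "MsCatalog"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- if (is.character(genome) && !is.null(names(genome))) genome
          else .genomeSeqs(genome)
  set.seed(seed %||% deriveSeed(cfg$seed, 7919L))

  mc <- S4Vectors::mcols(catalog)
  n <- length(catalog)
  chrom <- as.character(GenomicRanges::seqnames(catalog))
  st0 <- GenomicRanges::start(catalog) - 1L
  en0 <- GenomicRanges::end(catalog)
  unitLen <- nchar(mc$motif)
  refLen <- en0 - st0
  refUnits <- refLen %/% unitLen

  eligible <- status == "MSI-H" & mc$region %in% cfg$destabilizedRegions
  destab <- eligible & stats::runif(n) < cfg$destabilizedFraction
  shiftU <- integer(n)
  nd <- sum(destab)
  if (nd) {
    sRange <- seq.int(cfg$shiftUnits[1], cfg$shiftUnits[2])
    mag <- sRange[sample.int(length(sRange), nd, replace = TRUE)]
    sgn <- sample(c(-1L, 1L), nd, replace = TRUE)
    # keep the shifted allele at >= 1 repeat unit
    sgn[refUnits[destab] + sgn * mag < 1L] <- 1L
    shiftU[destab] <- sgn * mag
  }
  shiftB <- shiftU * unitLen

  depth <- stats::rpois(n, cfg$coverageMean)
  # loci a read cannot span even unshifted are marked, not simulated
  unspannable <- refLen + 2L * cfg$shiftUnits[2] * unitLen + 6L > cfg$readLen
  if (any(unspannable)) {
    warning(sum(unspannable), " locus/loci too long to span with ",
            cfg$readLen, " base reads; skipped")
    depth[unspannable] <- 0L
  }

  li <- rep(seq_len(n), depth)
  nr <- length(li)
  truth <- data.frame(
    sample_id = sampleId, locus_id = mc$locus_id,
    ref_length = refLen, destabilized = destab, shift_bases = shiftB,
    expected_modal = refLen + (if (cfg$tumorPurity > 0.5) shiftB else 0L),
    depth = depth, unspannable = unspannable)

  if (nr == 0L) {
    sam <- .writeSam(character(0), seqs, file.path(dir, paste0(sampleId,
                                                               ".sam")))
    bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE,
                            indexDestination = TRUE)
    return(list(bam = bam, truth = truth))
  }

  shifted <- destab[li] & stats::runif(nr) < cfg$tumorPurity
  alleleU <- refUnits[li] + ifelse(shifted, shiftU[li], 0L)
  slip <- stats::runif(nr) < cfg$stutterRate
  slipMag <- ifelse(slip, 1L + stats::rgeom(nr, cfg$stutterGeom), 0L)
  slipSgn <- ifelse(stats::runif(nr) < cfg$stutterBias, -1L, 1L)
  obsU <- pmax(1L, alleleU + slipSgn * slipMag)
  obsLen <- obsU * unitLen[li]
  refL <- refLen[li]

  refCons <- cfg$readLen - obsLen + refL        # reference bases consumed
  ctgLen <- nchar(seqs)[chrom[li]]
  lo <- pmax(0L, en0[li] + 3L - refCons)
  hi <- pmin(st0[li] - 3L, ctgLen - refCons)
  ok <- lo <= hi
  r0 <- lo + floor(stats::runif(nr) * (hi - lo + 1L))
  r0 <- pmin(r0, hi)

  li <- li[ok]; obsLen <- obsLen[ok]; refL <- refL[ok]; r0 <- r0[ok]
  refCons <- refCons[ok]; obsU <- obsU[ok]
  npre <- st0[li] - r0
  ctg <- chrom[li]
  cseq <- seqs[ctg]

  pre <- substr(cseq, r0 + 1L, st0[li])
  tract <- strrep(mc$motif[li], obsU)
  nsuf <- cfg$readLen - npre - obsLen
  suf <- substr(cseq, en0[li] + 1L, en0[li] + nsuf)
  seq <- paste0(pre, tract, suf)

  ins <- pmax(0L, obsLen - refL)
  del <- pmax(0L, refL - obsLen)
  cigar <- ifelse(
    ins > 0L,
    paste0(npre + refL, "M", ins, "I", cfg$readLen - npre - refL - ins, "M"),
    ifelse(del > 0L,
           paste0(npre + obsLen, "M", del, "D",
                  cfg$readLen - npre - obsLen, "M"),
           paste0(cfg$readLen, "M")))

  recs <- data.table::data.table(
    qname = sprintf("%s_r%07d", sampleId, seq_along(li)),
    flag = 0L, rname = ctg, pos = r0 + 1L, mapq = 60L, cigar = cigar,
    rnext = "*", pnext = 0L, tlen = 0L, seq = seq,
    qual = strrep("I", cfg$readLen))
  recs[, rname := factor(rname, levels = names(seqs))]
  data.table::setorder(recs, rname, pos)
  recs[, rname := as.character(rname)]

  sam <- .writeSam(do.call(paste, c(as.list(recs), sep = "\t")),
                   seqs, file.path(dir, paste0(sampleId, ".sam")))
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  list(bam = bam, truth = truth)
}

.writeSam <- function(bodyLines, seqs, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)))
  writeLines(c(header, bodyLines), path)
  path
}

#' Simulate a cohort of normal / MSS / MSI-H samples
#'
#' Draws independent per-sample seeds from the master seed; destabilized
#' locus sets are drawn independently per MSI-H sample.
#'
#' @param genome,catalog,cfg As in \code{\link{simulateSample}}.
#' @param nNormal,nMss,nMsih Sample counts per group.
#' @param dir Output directory for the per-sample BAMs.
#' @return A list with \code{sheet} (data.frame: \code{sample_id},
#'   \code{status}, \code{bam}) and \code{truth} (row-bound truth tables).
#' @export
simulateCohort <- function(genome, catalog, cfg, nNormal, nMss, nMsih,
                           dir = tempfile()) {
  stopifnot(nNormal >= 0, nMss >= 0, nMsih >= 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plan <- data.frame(
    sample_id = c(sprintf("normal%03d", seq_len(nNormal)),
                  sprintf("mss%03d", seq_len(nMss)),
                  sprintf("msih%03d", seq_len(nMsih))),
    status = rep(c("normal", "MSS", "MSI-H"), c(nNormal, nMss, nMsih)),
    stringsAsFactors = FALSE)
  seqs <- if (is.character(genome) && !is.null(names(genome))) genome
          else .genomeSeqs(genome)
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    out[[i]] <- simulateSample(seqs, catalog, cfg, plan$status[i],
                               plan$sample_id[i], dir = dir,
                               seed = deriveSeed(cfg$seed, i))
  }
  plan$bam <- vapply(out, `[[`, character(1), "bam")
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  rownames(truth) <- NULL
  list(sheet = plan, truth = truth)
}
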