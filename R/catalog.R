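#' Classify a repeat motif by its unit length
#'
#' @param motif Character vector of repeat units over \{A,C,G,T\},
#'   1-4 bases each.
#' @return Character vector over \code{mono}, \code{di}, \code{tri},
#'   \code{tetra}.
#' @examples
#' classifyMotif(c("A", "AG", "ACC", "ACGT"))
#' @export
classifyMotif <- function(motif) {
  if (length(motif) == 0L) return(character(0))
  motif <- toupper(motif)
  if (any(is.na(motif)) || any(!nzchar(motif)))
    stop("motif must be non-empty", call. = FALSE)
  if (any(grepl("[^ACGT]", motif)))
    stop("motif alphabet must be {A,C,G,T}", call. = FALSE)
  n <- nchar(motif)
  if (any(n > 4L))
    stop("motif length must be at most 4 (mono- to tetranucleotide)",
         call. = FALSE)
  c("mono", "di", "tri", "tetra")[n]
}

#' Construct a microsatellite catalog from a data.frame
#'
#' Coordinates are BED-style: 0-based \code{start}, exclusive \code{end}.
#'
#' @param df A data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{motif}, \code{region}, \code{gene} and optionally
#'   \code{locus_id}, \code{flank5}, \code{flank3}, \code{perfect}.
#' @return An \code{\linkS4class{MsCatalog}}.
#' @examples
#' msCatalog(data.frame(chrom = "chr1", start = 100, end = 110,
#'                      motif = "A", region = "UTR3", gene = "G1"))
#' @export
msCatalog <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "motif", "region", "gene")
                %in% names(df)))
  id <- df$locus_id %||% sprintf("%s_%d_%d", df$chrom, df$start, df$end)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locus_id = as.character(id),
    motif = toupper(as.character(df$motif)),
    region = as.character(df$region),
    gene = as.character(df$gene),
    flank5 = if ("flank5" %in% names(df)) as.character(df$flank5)
             else NA_character_,
    flank3 = if ("flank3" %in% names(df)) as.character(df$flank3)
             else NA_character_,
    perfect = if ("perfect" %in% names(df)) as.logical(df$perfect) else NA)
  methods::new("MsCatalog", gr)
}

#' Read a microsatellite locus catalog
#'
#' Reads the BED4+2 catalog dialect: tab-separated
#' \code{chrom start end motif region gene}, 0-based half-open coordinates,
#' optional \code{#}-prefixed header lines.  \code{locus_id} is derived as
#' \code{chrom_start_end} and must be unique.  When a reference genome is
#' supplied, each locus is validated against it: the tract must sit inside
#' its chromosome, the 2 bp reference flanks are recorded, and tracts that
#' are not an exact (whole or partial) tandem of the motif are flagged
#' \code{perfect = FALSE}.  Loci on chromosomes absent from the genome are
#' dropped with a warning.
#'
#' @param path Catalog file.
#' @param genome Optional reference: a FASTA path (indexed or indexable),
#'   an \code{\link[Rsamtools]{FaFile}}, or a named
#'   \code{\link[Biostrings]{DNAStringSet}}.
#' @param minTractLen Minimum tract length in bases (default 5); shorter
#'   loci are rejected.
#' @param strict If \code{TRUE} (default) any malformed line is an error
#'   naming the line; if \code{FALSE} malformed lines are dropped and
#'   logged in the \code{"drops"} attribute of the result
#'   (a data.frame with columns \code{line}, \code{reason}).
#' @param flankLen Flank length recorded from the genome (default 2).
#' @return An \code{\linkS4class{MsCatalog}} (attribute \code{"drops"}
#'   lists dropped lines).
#' @seealso \code{\link{writeCatalog}}, \code{\link{filterCatalog}}
#' @export
readCatalog <- function(path, genome = NULL, minTractLen = 5L,
                        strict = TRUE, flankLen = 2L) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("catalog contains no data lines: ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  drops <- list()
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    reason <- NULL
    if (length(f) < 6L) {
      reason <- "fewer than 6 columns"
    } else {
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      motif <- toupper(f[4])
      if (is.na(start) || is.na(end)) reason <- "non-integer coordinates"
      else if (start < 0L) reason <- "negative start"
      else if (start >= end) reason <- "start must be < end"
      else if (end - start < minTractLen)
        reason <- sprintf("tract shorter than %d bases", minTractLen)
      else if (!nzchar(motif) || grepl("[^ACGT]", motif) || nchar(motif) > 4L)
        reason <- "invalid motif"
      else if (!f[5] %in% c("CDS", "UTR5", "UTR3", "OTHER"))
        reason <- "unknown region label"
    }
    if (is.null(reason)) {
      rows[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                              motif = motif, region = f[5], gene = f[6],
                              stringsAsFactors = FALSE)
    } else if (strict) {
      stop(sprintf("catalog line %d: %s", lineno[i], reason), call. = FALSE)
    } else {
      drops[[length(drops) + 1L]] <-
        data.frame(line = lineno[i], reason = reason)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no valid catalog lines in ", path)
  df <- do.call(rbind, rows)
  id <- sprintf("%s_%d_%d", df$chrom, df$start, df$end)
  if (anyDuplicated(id))
    stop("duplicate locus_id in catalog: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  cat <- msCatalog(df)
  if (!is.null(genome))
    cat <- .validateCatalogGenome(cat, genome, flankLen = flankLen)
  attr(cat, "drops") <- if (length(drops)) do.call(rbind, drops)
    else data.frame(line = integer(0), reason = character(0))
  cat
}

# Pull the reference sequence for tract + flanks, record flanks, flag
# imperfect tandems, drop loci whose chromosome is missing or whose flanks
# fall off the contig.
.validateCatalogGenome <- function(cat, genome, flankLen = 2L) {
  seqs <- .genomeSeqs(genome)
  chroms <- as.character(GenomicRanges::seqnames(cat))
  present <- chroms %in% names(seqs)
  if (!all(present)) {
    warning(sum(!present), " locus/loci on chromosome(s) absent from the ",
            "genome dropped: ",
            paste(unique(chroms[!present]), collapse = ", "))
    cat <- cat[present]
    chroms <- chroms[present]
  }
  st1 <- GenomicRanges::start(cat)   # 1-based tract start
  en1 <- GenomicRanges::end(cat)
  clen <- nchar(seqs)[chroms]
  fits <- st1 - flankLen >= 1L & en1 + flankLen <= clen
  if (!all(fits)) {
    warning(sum(!fits), " locus/loci too close to a contig edge dropped")
    cat <- cat[fits]; chroms <- chroms[fits]
    st1 <- st1[fits]; en1 <- en1[fits]
  }
  if (!length(cat)) return(cat)
  tract <- unname(substr(seqs[chroms], st1, en1))
  mc <- S4Vectors::mcols(cat)
  mc$flank5 <- unname(toupper(substr(seqs[chroms], st1 - flankLen, st1 - 1L)))
  mc$flank3 <- unname(toupper(substr(seqs[chroms], en1 + 1L, en1 + flankLen)))
  expect <- substr(strrep(mc$motif,
                          ceiling(GenomicRanges::width(cat) / nchar(mc$motif))),
                   1L, GenomicRanges::width(cat))
  mc$perfect <- toupper(tract) == expect
  S4Vectors::mcols(cat) <- mc
  cat
}

# Accept FASTA path, FaFile, DNAStringSet, or an already-named character
# vector of contig sequences; return named character vector
.genomeSeqs <- function(genome) {
  if (is.character(genome) && !is.null(names(genome)))
    return(toupper(genome))
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (methods::is(genome, "FaFile")) {
    genome <- Rsamtools::scanFa(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  setNames(as.character(genome), names(genome))
}

#' Write a catalog in the BED4+2 dialect
#'
#' Inverse of \code{\link{readCatalog}}: tab-separated \code{chrom start
#' end motif region gene} with BED (0-based half-open) coordinates.
#'
#' @param x An \code{\linkS4class{MsCatalog}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(x, path) {
  stopifnot(methods::is(x, "MsCatalog"))
  mc <- S4Vectors::mcols(x)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1L,
                   end = GenomicRanges::end(x),
                   motif = mc$motif, region = mc$region, gene = mc$gene)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter a catalog by region, repeat class, or locus id
#'
#' Filters intersect; input order is preserved; an empty result is allowed.
#'
#' @param x An \code{\linkS4class{MsCatalog}}.
#' @param regions Optional subset of \code{c("CDS","UTR5","UTR3","OTHER")}.
#' @param classes Optional subset of \code{c("mono","di","tri","tetra")}.
#' @param ids Optional locus ids to keep.
#' @param perfectOnly Keep only loci whose reference tract is an exact
#'   tandem of the motif (requires genome validation; default \code{FALSE}).
#' @return The filtered \code{MsCatalog}.
#' @examples
#' cat <- msCatalog(data.frame(chrom = "c", start = c(0, 20),
#'                             end = c(10, 30), motif = c("A", "AG"),
#'                             region = c("UTR3", "CDS"), gene = "g"))
#' length(filterCatalog(cat, regions = "UTR3"))
#' @export
filterCatalog <- function(x, regions = NULL, classes = NULL, ids = NULL,
                          perfectOnly = FALSE) {
  stopifnot(methods::is(x, "MsCatalog"))
  keep <- rep(TRUE, length(x))
  if (!is.null(regions)) {
    bad <- setdiff(regions, c("CDS", "UTR5", "UTR3", "OTHER"))
    if (length(bad)) stop("unknown region label(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    keep <- keep & regions(x) %in% regions
  }
  if (!is.null(classes)) {
    bad <- setdiff(classes, c("mono", "di", "tri", "tetra"))
    if (length(bad)) stop("unknown repeat class(es): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    keep <- keep & repeatClass(x) %in% classes
  }
  if (!is.null(ids))
    keep <- keep & locusIds(x) %in% ids
  if (isTRUE(perfectOnly)) {
    pf <- S4Vectors::mcols(x)$perfect
    if (all(is.na(pf)))
      stop("perfectOnly requires a genome-validated catalog", call. = FALSE)
    keep <- keep & !is.na(pf) & pf
  }
  x[keep]
}
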