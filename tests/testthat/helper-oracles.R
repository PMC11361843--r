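# Independent brute-force oracles used to validate the package's
# implementations.  Deliberately naive: replay / enumerate, never share
# code with the functions under test.

# Replay an alignment base by base and measure the tract length by the
# anchor rule.  Returns an integer length or a rejection reason string.
oracleMeasure <- function(pos1, cigar, seq, start0, end0, f5, f3, fl = 2L) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub(".$", "", ops))
  op <- substr(ops, nchar(ops), nchar(ops))
  g <- pos1 - 1L; r <- 0L
  refOf <- integer(0); readOf <- integer(0)
  skips <- list()
  for (k in seq_along(op)) {
    L <- len[k]
    if (op[k] %in% c("M", "=", "X")) {
      refOf <- c(refOf, seq.int(g, g + L - 1L))
      readOf <- c(readOf, seq.int(r, r + L - 1L))
      g <- g + L; r <- r + L
    } else if (op[k] %in% c("I", "S")) {
      r <- r + L
    } else if (op[k] == "D") {
      g <- g + L
    } else if (op[k] == "N") {
      skips[[length(skips) + 1L]] <- c(g, g + L - 1L)
      g <- g + L
    }
  }
  winLo <- start0 - fl; winHi <- end0 + fl - 1L
  for (sr in skips)
    if (sr[1] <= winHi && sr[2] >= winLo) return("not_spanning")
  if (!length(refOf) || min(refOf) > winLo || max(refOf) < winHi)
    return("not_spanning")
  a5 <- readOf[match(start0 - 1L, refOf)]
  a3 <- readOf[match(end0, refOf)]
  if (is.na(a5) || is.na(a3)) return("boundary_indel")
  if (a5 - fl + 1L < 0L || a3 + fl > nchar(seq)) return("not_spanning")
  s <- strsplit(toupper(seq), "")[[1]]
  rf5 <- paste(s[(a5 - fl + 2L):(a5 + 1L)], collapse = "")
  rf3 <- paste(s[(a3 + 1L):(a3 + fl)], collapse = "")
  if (grepl("N", rf5) || grepl("N", rf3) ||
      rf5 != toupper(f5) || rf3 != toupper(f3)) return("flank_mismatch")
  as.integer(a3 - a5 - 1L)
}

# sup |ECDF_x - ECDF_y| evaluated naively at every merged support point
oracleKsD <- function(x, y) {
  support <- sort(unique(c(x, y)))
  max(abs(vapply(support, function(t) mean(x <= t) - mean(y <= t),
                 numeric(1))))
}

# pairwise-concordance AUC with half weight for ties
oracleAuc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# classical BH step-up rejection set at level alpha
oracleStepUpReject <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(n) / n * alpha)
  rej <- logical(n)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of
# group assignments (no ties assumed)
oracleRankSumP <- function(a, b) {
  z <- c(a, b)
  n <- length(z); na <- length(a)
  obs <- sum(rank(z)[seq_len(na)])
  combs <- utils::combn(n, na)
  stats <- apply(combs, 2, function(ix) sum(rank(z)[ix]))
  mu <- na * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# write a SAM file for hand-constructed reads; contigs is a named
# character vector of sequences
makeSamFile <- function(reads, contigs, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  reads$mapq, reads$cigar, reads$seq,
                  strrep("I", nchar(reads$seq)))
  writeLines(c(header, body[order(reads$rname, reads$pos)]), path)
  path
}

# A single-locus fixture: 30 bp flank | A x 12 | 30 bp flank
tractFixture <- function(seed = 99) {
  set.seed(seed)
  left <- paste(sample(c("C", "G", "T"), 30, TRUE), collapse = "")
  right <- paste(sample(c("C", "G", "T"), 30, TRUE), collapse = "")
  contig <- paste0(left, strrep("A", 12), right)
  list(contig = c(ctg = contig), start0 = 30L, end0 = 42L,
       f5 = substr(contig, 29, 30), f3 = substr(contig, 43, 44))
}

# Replay a CIGAR over the reference to build a consistent read sequence.
# ops: list of list(op=, len=, bases= (I), sub=/base= (planted mismatch)).
buildReadOn <- function(fix, r0, ops) {
  contig <- fix$contig[[1]]
  seq <- ""; g <- r0; cig <- ""
  for (o in ops) {
    if (o$op == "M") {
      part <- substr(contig, g + 1L, g + o$len)
      if (!is.null(o$sub))
        substr(part, o$sub, o$sub) <- o$base
      seq <- paste0(seq, part); g <- g + o$len
    } else if (o$op == "I") {
      seq <- paste0(seq, o$bases); o$len <- nchar(o$bases)
    } else if (o$op %in% c("D", "N")) {
      g <- g + o$len
    } else if (o$op == "S") {
      seq <- paste0(seq, strrep("T", o$len))
    }
    cig <- paste0(cig, o$len, o$op)
  }
  list(pos = r0 + 1L, cigar = cig, seq = seq)
}

# Random alignment shapes over the fixture locus: matches, tract indels,
# clips, splices, and non-spanning reads.
randomGridRead <- function(fix) {
  refLen <- fix$end0 - fix$start0
  r0 <- sample(0:28, 1)
  npre <- fix$start0 - r0
  kind <- sample(c("match", "ins", "del", "clip", "splice", "short"), 1)
  ops <- switch(kind,
    match = list(list(op = "M", len = npre + sample(16:40, 1))),
    ins = {
      at <- sample(1:(refLen - 1), 1)
      list(list(op = "M", len = npre + at),
           list(op = "I", bases = strrep("A", sample(1:4, 1))),
           list(op = "M", len = refLen - at + sample(5:20, 1)))
    },
    del = {
      dl <- sample(1:4, 1)
      at <- sample(1:(refLen - dl - 1), 1)
      list(list(op = "M", len = npre + at),
           list(op = "D", len = dl),
           list(op = "M", len = refLen - at - dl + sample(5:20, 1)))
    },
    clip = list(list(op = "S", len = sample(1:5, 1)),
                list(op = "M", len = npre + sample(16:40, 1))),
    splice = list(list(op = "M", len = npre + sample(2:8, 1)),
                  list(op = "N", len = sample(2:6, 1)),
                  list(op = "M", len = 30)),
    short = list(list(op = "M", len = max(2L, npre - sample(0:2, 1)))))
  read <- buildReadOn(fix, r0, ops)
  read$ins <- sum(vapply(ops, function(o)
    if (o$op == "I") nchar(o$bases) else 0L, integer(1)))
  read$del <- sum(vapply(ops, function(o)
    if (o$op == "D") o$len else 0L, integer(1)))
  read
}

# profile built directly from a counts data.frame (bypasses BAM plumbing
# for statistical tests)
makeProfile <- function(sampleId, counts) {
  new("LengthProfile", sampleId = sampleId,
      counts = counts,
      rejections = data.frame(locus_id = character(0),
                              reason = character(0), n = integer(0)))
}
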