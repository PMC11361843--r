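# Tract measurement against a base-by-base replay oracle, and the BAM
# profiling loop.

# one locus: 30 bp flank | A x 12 | 30 bp flank, on a fixed contig
.tract <- tractFixture()

buildRead <- function(r0, ops) buildReadOn(.tract, r0, ops)

measureAt <- function(read, cfg = profilerConfig(minMapq = 0)) {
  measureTractLength(read, list(start = .tract$start0, end = .tract$end0),
                     flanks = c(.tract$f5, .tract$f3), cfg = cfg)
}

test_that("all-match reads measure the reference tract length", {
  for (r0 in c(0L, 5L, 20L, 27L)) {
    rd <- buildRead(r0, list(list(op = "M", len = 50)))
    expect_equal(measureAt(rd)$length, 12L)
  }
})

test_that("indels inside the tract shift the measured length additively", {
  # insertion of 3 A's wholly inside the tract
  rd <- buildRead(10L, list(list(op = "M", len = 26),
                            list(op = "I", bases = "AAA"),
                            list(op = "M", len = 24)))
  expect_equal(measureAt(rd)$length, 15L)
  # deletion of 2 tract bases
  rd <- buildRead(10L, list(list(op = "M", len = 25),
                            list(op = "D", len = 2),
                            list(op = "M", len = 25)))
  expect_equal(measureAt(rd)$length, 10L)
})

test_that("measured length matches replay oracle and indel arithmetic on a CIGAR grid", {
  set.seed(404)
  refLen <- .tract$end0 - .tract$start0
  checked <- 0L
  for (i in 1:300) {
    rd <- randomGridRead(.tract)
    got <- measureAt(rd)
    exp <- oracleMeasure(rd$pos, rd$cigar, rd$seq, .tract$start0,
                         .tract$end0, .tract$f5, .tract$f3)
    if (got$accepted) {
      expect_identical(got$length, exp)
      expect_equal(got$length, refLen + rd$ins - rd$del)
      checked <- checked + 1L
    } else {
      expect_identical(got$reason, exp)
    }
  }
  expect_gt(checked, 50L)  # the grid must actually exercise accepted reads
})

test_that("flank mismatches and boundary deletions always reject", {
  # mismatch at the base immediately 5' of the tract
  rd <- buildRead(10L, list(list(op = "M", len = 50, sub = 20L,
                                 base = "A")))
  stopifnot(substr(.tract$contig, 30, 30) != "A")
  expect_equal(measureAt(rd)$reason, "flank_mismatch")
  # N in the read flank
  rd2 <- buildRead(10L, list(list(op = "M", len = 50, sub = 20L,
                                  base = "N")))
  expect_equal(measureAt(rd2)$reason, "flank_mismatch")
  # deletion crossing the 5' flank/tract boundary (covers start0 - 1)
  rd3 <- buildRead(10L, list(list(op = "M", len = 19),
                             list(op = "D", len = 3),
                             list(op = "M", len = 30)))
  expect_equal(measureAt(rd3)$reason, "boundary_indel")
  # deletion swallowing the 3' anchor base at end0
  rd4 <- buildRead(10L, list(list(op = "M", len = 31),
                             list(op = "D", len = 2),
                             list(op = "M", len = 20)))
  expect_equal(measureAt(rd4)$reason, "boundary_indel")
})

test_that("flag and MAPQ filters reject before alignment inspection", {
  rd <- buildRead(10L, list(list(op = "M", len = 50)))
  rd$mapq <- 5L
  expect_equal(measureAt(rd, profilerConfig(minMapq = 20))$reason,
               "low_mapq")
  rd$mapq <- 60L; rd$flag <- 1024L
  expect_equal(measureAt(rd)$reason, "filtered_flag")
  rd$flag <- 256L
  expect_equal(measureAt(rd)$reason, "filtered_flag")
  rd$flag <- 0L
  expect_true(measureAt(rd, profilerConfig(minMapq = 20))$accepted)
})

test_that("profileSample accounts for every overlapping read", {
  ctg <- .tract$contig
  mk <- function(r0, ops) buildRead(r0, ops)$seq
  m50 <- list(list(op = "M", len = 50))
  reads <- data.frame(
    qname = sprintf("r%d", 1:6),
    flag = c(0L, 0L, 1024L, 0L, 0L, 0L),
    rname = "ctg",
    pos = c(11L, 16L, 11L, 36L, 11L, 11L),
    mapq = c(60L, 3L, 60L, 60L, 60L, 60L),
    cigar = c("50M", "50M", "50M", "20M", "50M", "19M3D30M"),
    seq = c(mk(10L, m50), mk(15L, m50), mk(10L, m50),
            mk(35L, list(list(op = "M", len = 20))), mk(10L, m50),
            mk(10L, list(list(op = "M", len = 19), list(op = "D", len = 3),
                         list(op = "M", len = 30)))),
    stringsAsFactors = FALSE)
  sam <- makeSamFile(reads, ctg)
  cat <- msCatalog(data.frame(chrom = "ctg", start = .tract$start0,
                              end = .tract$end0, motif = "A",
                              region = "UTR3", gene = "G",
                              flank5 = .tract$f5, flank3 = .tract$f3,
                              perfect = TRUE))
  prof <- profileSample(sam, cat, profilerConfig(minMapq = 20))
  accepted <- sum(profileCounts(prof)$count)
  rejected <- sum(rejectionTallies(prof)$n)
  expect_equal(accepted + rejected, nrow(reads))
  rej <- rejectionTallies(prof)
  expect_equal(sum(rej$n[rej$reason == "filtered_flag"]), 1L)
  expect_equal(sum(rej$n[rej$reason == "low_mapq"]), 1L)
  expect_equal(sum(rej$n[rej$reason == "not_spanning"]), 1L)
  expect_equal(sum(rej$n[rej$reason == "boundary_indel"]), 1L)
  expect_equal(accepted, 2L)
  expect_equal(profileCounts(prof)$length, 12L)
})

test_that("profiling is deterministic and lengths below the minimum are never recorded", {
  coh <- smallCohort()
  p1 <- coh$profiles[[1]]
  p2 <- profileSample(coh$sheet$bam[1], coh$ref$catalog,
                      sampleId = coh$sheet$sample_id[1])
  expect_identical(profileCounts(p1), profileCounts(p2))
  all_counts <- do.call(rbind, lapply(coh$profiles, profileCounts))
  expect_true(all(all_counts$length >= 5L))
  expect_true(all(all_counts$count >= 1L))
})

test_that("mononucleotide contraction stutter reproduces its binomial rate", {
  # one mono locus, 12 repeat units, ~1000 reads, every read slipping one
  # unit toward contraction with probability 0.5
  cfg <- simulationConfig(nLoci = 1, classMix = c(mono = 1, di = 0, tri = 0,
                                                  tetra = 0),
                          regionMix = c(CDS = 0, UTR5 = 0, UTR3 = 1),
                          tractUnits = c(12, 12), coverageMean = 1000,
                          stutterRate = 0.5, stutterGeom = 1,
                          stutterBias = 1, seed = 31)
  ref <- generateReference(cfg)
  s <- simulateSample(ref$seqs, ref$catalog, cfg, "normal", "s", seed = 77)
  prof <- profileSample(s$bam, ref$catalog)
  pc <- profileCounts(prof)
  frac11 <- pc$count[pc$length == 11] / sum(pc$count)
  expect_gt(frac11, 0.45)
  expect_lt(frac11, 0.55)
})

test_that("profiles round-trip losslessly through the TSV format", {
  coh <- smallCohort()
  p <- coh$profiles[[3]]
  path <- tempfile(fileext = ".tsv")
  writeProfile(p, path)
  back <- readProfile(path)
  expect_equal(sampleId(back), sampleId(p))
  o <- order(profileCounts(p)$locus_id, profileCounts(p)$length)
  expect_equal(back@counts, profileCounts(p)[o, ], ignore_attr = TRUE)
  # empty profile -> header-only file
  empty <- makeProfile("none", data.frame(locus_id = character(0),
                                          length = integer(0),
                                          count = integer(0)))
  pe <- tempfile(fileext = ".tsv")
  writeProfile(empty, pe)
  expect_equal(nrow(profileCounts(readProfile(pe))), 0L)
  # version guard
  bad <- tempfile()
  writeLines(c("#format=other", "x"), bad)
  expect_error(readProfile(bad), "header mismatch")
})
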