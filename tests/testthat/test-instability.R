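# KS statistic, FDR adjustment, unstable-locus calling, group comparison.

test_that("KS statistic matches worked examples", {
  expect_equal(ksTwoSample(c(`10` = 5), c(`10` = 5))$D, 0)
  expect_equal(ksTwoSample(c(`10` = 5), c(`10` = 5))$p, 1)
  expect_equal(ksTwoSample(c(`10` = 5), c(`12` = 5))$D, 1)
  expect_equal(ksTwoSample(c(`10` = 3, `11` = 2),
                           c(`10` = 1, `11` = 3, `12` = 1))$D, 0.4)
  expect_error(ksTwoSample(numeric(0), c(1)), "empty")
})

test_that("KS statistic agrees with the brute-force ECDF oracle", {
  set.seed(15)
  for (i in 1:1000) {
    x <- sample(5:20, sample(2:30, 1), replace = TRUE)
    y <- sample(5:20, sample(2:30, 1), replace = TRUE)
    expect_lt(abs(ksTwoSample(x, y)$D - oracleKsD(x, y)), 1e-12)
  }
})

test_that("KS D is invariant under strictly monotone relabeling", {
  set.seed(77)
  for (i in 1:50) {
    x <- sample(5:15, 20, replace = TRUE)
    y <- sample(5:15, 20, replace = TRUE)
    f <- function(v) v^3 + 2 * v  # strictly increasing
    expect_equal(ksTwoSample(x, y)$D, ksTwoSample(f(x), f(y))$D)
  }
})

test_that("asymptotic KS p decreases in D and matches the degenerate case", {
  # degenerate vs degenerate disjoint: D = 1, effective n = 5
  r <- ksTwoSample(c(`9` = 10), c(`12` = 10))
  expect_equal(r$D, 1)
  expect_equal(r$p, 2 * sum((-1)^(0:100) * exp(-2 * ((1:101)^2) * 5)),
               tolerance = 1e-12)
  ps <- vapply(seq(0.1, 1, by = 0.1), function(d)
    msirna:::.kolmogorovQ(sqrt(5) * d), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("exact small-sample KS p-values match ks.test", {
  set.seed(41)
  for (i in 1:20) {
    x <- sample(8:13, sample(5:15, 1), replace = TRUE)
    y <- sample(8:13, sample(5:15, 1), replace = TRUE)
    mine <- ksTwoSample(x, y, method = "exact")
    ref <- suppressWarnings(stats::ks.test(x, y, exact = TRUE))
    expect_equal(mine$D, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces hand step-up results", {
  expect_equal(bhFdr(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bhFdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bhFdr(0.05), 0.05)
  expect_error(bhFdr(c(0.1, 0)), "0, 1")
  expect_error(bhFdr(c(0.1, 1.2)), "0, 1")
})

test_that("q-values dominate p-values and reproduce the step-up rule", {
  set.seed(6)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    p <- round(runif(n), 3)
    p[p == 0] <- 0.001
    q <- bhFdr(p)
    expect_true(all(q >= p - 1e-12))
    alpha <- runif(1, 0.01, 0.2)
    expect_equal(q < alpha, oracleStepUpReject(p, alpha))
    # BH rejections contain Bonferroni rejections
    expect_true(all(which(p < alpha / n) %in% which(q < alpha)))
  }
})

test_that("rank-sum comparison matches exact enumeration", {
  expect_equal(compareGroups(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(compareGroups(c(10, 11, 12, 13), c(1, 2, 3))$p, 2 / 35,
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:20) {
    a <- sample(1:1000, sample(3:5, 1))
    b <- sample(2001:3000, sample(3:5, 1)) / 2  # all > max(a), no ties
    expect_equal(compareGroups(a, b)$p, oracleRankSumP(a, b),
                 tolerance = 1e-9)
  }
  # identical groups: no evidence of difference
  expect_equal(compareGroups(c(5, 5, 6, 7), c(5, 5, 6, 7))$p, 1)
  expect_error(compareGroups(numeric(0), 1:3), "non-empty")
})

test_that("degenerate tumor-vs-reference calls behave as constructed", {
  cat <- msCatalog(data.frame(chrom = "c", start = c(0, 100),
                              end = c(12, 110), motif = "A",
                              region = c("UTR3", "CDS"), gene = "g"))
  ids <- locusIds(cat)
  rn <- new("ReferenceNormal",
            table = data.frame(locus_id = ids, ref_length = c(12L, 10L),
                               ref_count = c(10L, 10L)))
  stable <- makeProfile("t", data.frame(locus_id = ids,
                                        length = c(12L, 10L),
                                        count = c(10L, 10L)))
  res <- callUnstable(stable, rn, cat)
  expect_equal(instabilityCalls(res)$D, c(0, 0))
  expect_false(any(instabilityCalls(res)$unstable))
  shifted <- makeProfile("t", data.frame(locus_id = ids,
                                         length = c(9L, 10L),
                                         count = c(10L, 10L)))
  res2 <- callUnstable(shifted, rn, cat)
  calls <- instabilityCalls(res2)
  expect_equal(calls$D[calls$locus_id == ids[1]], 1)
  expect_true(calls$unstable[calls$locus_id == ids[1]])
  expect_false(calls$unstable[calls$locus_id == ids[2]])
  s <- instabilitySummary(res2)
  expect_equal(s$n_unstable[s$region == "UTR3" & s$class == "ALL"], 1L)
  expect_equal(s$n_tested[s$region == "ALL" & s$class == "ALL"], 2L)
})

test_that("loci below the read floor on either side are never tested", {
  cat <- msCatalog(data.frame(chrom = "c", start = c(0, 100, 200),
                              end = c(12, 110, 215), motif = "A",
                              region = "UTR3", gene = "g"))
  ids <- locusIds(cat)
  rn <- new("ReferenceNormal",
            table = data.frame(locus_id = ids, ref_length = 12L,
                               ref_count = c(10L, 4L, 10L)))
  tumor <- makeProfile("t", data.frame(locus_id = ids, length = 12L,
                                       count = c(10L, 10L, 4L)))
  res <- callUnstable(tumor, rn, cat)
  expect_equal(instabilityCalls(res)$locus_id, ids[1])
  # nothing testable at all -> diagnostic error
  thin <- makeProfile("t", data.frame(locus_id = ids, length = 12L,
                                      count = c(2L, 2L, 2L)))
  expect_error(callUnstable(thin, rn, cat), "coverage too low")
})

test_that("strata counts in the summary add up to the totals", {
  coh <- smallCohort()
  normals <- coh$profiles[coh$sheet$status == "normal"]
  inv <- selectInvariable(normals, detectionConfig())
  rn <- buildReferenceNormal(normals, inv$invariable, detectionConfig())
  res <- callUnstable(coh$profiles[["msih001"]], rn, coh$ref$catalog,
                      loci = inv$invariable)
  s <- instabilitySummary(res)
  tot <- s[s$region == "ALL" & s$class == "ALL", ]
  byReg <- s[s$region != "ALL" & s$class == "ALL", ]
  byCls <- s[s$region == "ALL" & s$class != "ALL", ]
  expect_equal(sum(byReg$n_tested), tot$n_tested)
  expect_equal(sum(byReg$n_unstable), tot$n_unstable)
  expect_equal(sum(byCls$n_tested), tot$n_tested)
  expect_equal(sum(byCls$n_unstable), tot$n_unstable)
  calls <- instabilityCalls(res)
  expect_true(all(calls$q >= calls$p - 1e-12))
  expect_equal(calls$unstable, calls$q < 0.05)
})

test_that("null tumors drawn from the normal stutter model stay below the FDR budget", {
  coh <- smallCohort()
  normals <- coh$profiles[coh$sheet$status == "normal"]
  inv <- selectInvariable(normals, detectionConfig())
  rn <- buildReferenceNormal(normals, inv$invariable, detectionConfig())
  mss <- coh$profiles[coh$sheet$status == "MSS"]
  fracs <- vapply(mss, function(p) {
    res <- callUnstable(p, rn, coh$ref$catalog, loci = inv$invariable)
    s <- instabilitySummary(res)
    tot <- s[s$region == "ALL" & s$class == "ALL", ]
    tot$n_unstable / tot$n_tested
  }, numeric(1))
  expect_true(all(fracs <= 0.05 + 3 * sqrt(0.05 * 0.95 / 100)))
})

test_that("planted shifts are detected and severity is monotone in shift size", {
  coh <- smallCohort()
  normals <- coh$profiles[coh$sheet$status == "normal"]
  inv <- selectInvariable(normals, detectionConfig())
  rn <- buildReferenceNormal(normals, inv$invariable, detectionConfig())
  msih <- coh$profiles[coh$sheet$status == "MSI-H"]
  hits <- lapply(names(msih), function(sid) {
    res <- callUnstable(msih[[sid]], rn, coh$ref$catalog,
                        loci = inv$invariable)
    merge(instabilityCalls(res),
          coh$truth[coh$truth$sample_id == sid, ],
          by = "locus_id")
  })
  m <- do.call(rbind, hits)
  planted <- m$destabilized & abs(m$shift_bases) >= 2 & m$n_tumor >= 20
  expect_gt(mean(m$unstable[planted]), 0.9)
  stable <- !m$destabilized
  expect_lt(mean(m$unstable[stable]), 0.05)
})

test_that("larger planted shifts never lower median unstable counts", {
  # tracts of >= 8 units so that even a 3-unit contraction stays above the
  # 5-base recording floor (no allele dropout confounding severity)
  base <- simulationConfig(nLoci = 80, seed = 808, tractUnits = c(8, 15))
  ref <- generateReference(base, dir = file.path(tempdir(), "sev-ref"))
  coh <- simulateCohort(ref$seqs, ref$catalog, base, 10, 0, 0)
  normals <- lapply(seq_len(nrow(coh$sheet)), function(i)
    profileSample(coh$sheet$bam[i], ref$catalog,
                  sampleId = coh$sheet$sample_id[i]))
  inv <- selectInvariable(normals, detectionConfig())
  rn <- buildReferenceNormal(normals, inv$invariable, detectionConfig())
  medianCount <- function(delta) {
    cfg <- simulationConfig(nLoci = 80, seed = 808, tractUnits = c(8, 15),
                            shiftUnits = c(delta, delta))
    counts <- vapply(1:3, function(i) {
      sid <- sprintf("d%d_%d", delta, i)
      s <- simulateSample(ref$seqs, ref$catalog, cfg, "MSI-H", sid,
                          seed = 7000L + i)  # same draws across deltas
      p <- profileSample(s$bam, ref$catalog, sampleId = sid)
      smry <- instabilitySummary(callUnstable(p, rn, ref$catalog,
                                              loci = inv$invariable))
      smry$n_unstable[smry$region == "ALL" & smry$class == "ALL"]
    }, numeric(1))
    median(counts)
  }
  meds <- vapply(1:3, medianCount, numeric(1))
  expect_true(all(diff(meds) >= 0))
})
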