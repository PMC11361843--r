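# A small simulated cohort shared across test files, generated once per
# test run: 120 loci, 12 normals, 6 MSS, 6 MSI-H at default noise/effect
# parameters.

.cohortCache <- new.env(parent = emptyenv())

smallCohort <- function() {
  if (!is.null(.cohortCache$coh)) return(.cohortCache$coh)
  cfg <- simulationConfig(nLoci = 120, seed = 20260925)
  ref <- generateReference(cfg, dir = file.path(tempdir(), "small-ref"))
  coh <- simulateCohort(ref$seqs, ref$catalog, cfg, 12, 6, 6,
                        dir = file.path(tempdir(), "small-coh"))
  profs <- lapply(seq_len(nrow(coh$sheet)), function(i)
    profileSample(coh$sheet$bam[i], ref$catalog,
                  sampleId = coh$sheet$sample_id[i]))
  names(profs) <- coh$sheet$sample_id
  out <- list(cfg = cfg, ref = ref, sheet = coh$sheet, truth = coh$truth,
              profiles = profs)
  .cohortCache$coh <- out
  out
}
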