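## small two-strain config used by several blocks
smallConfig <- function(seed = 11, baseline = 1, f = 0, noiseCv = 0.15,
                        bgSd = 0.3, slope = 0, release = 1, att = NA) {
  fx <- featureSet(c("snrA", "geneB"), c("snr", "orf"), "chrS",
                   c(1001, 3001), c(1400, 4800), strand = "+",
                   mature_end = c(1400, NA), baseline = baseline,
                   downstream_stop = c(2000, NA),
                   attenuator_offset = c(NA, att))
  ef <- effectTable(c("snrA", "geneB"), c("WT", "mut"))
  ef$readthrough_fraction[ef$feature_id == "snrA" &
                            ef$strain == "mut"] <- f
  ef$elongation_slope[ef$feature_id == "geneB" &
                        ef$strain == "mut"] <- slope
  ef$attenuator_release[ef$feature_id == "geneB" &
                          ef$strain == "mut"] <- release
  simConfig(seed = seed, genome = data.frame(chrom = "chrS",
                                             length = 6000L),
            features = fx, effects = ef, strains = c("WT", "mut"),
            wtLabel = "WT", background = c(log(60), bgSd),
            noiseCv = noiseCv)
}

test_that("identical seeds give bitwise-identical simulations", {
  s1 <- simulateArrays(smallConfig())
  s2 <- simulateArrays(smallConfig())
  expect_identical(pm(s1$experiment), pm(s2$experiment))
  expect_identical(mm(s1$experiment), mm(s2$experiment))
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  s3 <- simulateArrays(smallConfig(seed = 12))
  expect_false(identical(pm(s1$experiment), pm(s3$experiment)))
})

test_that("with zero abundance PM-MM is centred on zero genome-wide", {
  sim <- simulateArrays(smallConfig(baseline = 0))
  d <- pm(sim$experiment)[, 1] - mm(sim$experiment)[, 1]
  expect_lt(abs(pseudomedian(d[seq(1, length(d), by = 10)])), 3)
})

test_that("noiseless run reproduces the abundance formula exactly", {
  cfg <- smallConfig(f = 0.3, noiseCv = 0, bgSd = 0)
  sim <- simulateArrays(cfg)
  d <- pm(sim$experiment) - mm(sim$experiment)
  Tm <- expectedAbundance(cfg, "mut", sim$probes)
  expect_equal(unname(d[, "mut_r1"]), cfg@gain * Tm, tolerance = 1e-12)
  expect_identical(d[, "mut_r1"], d[, "mut_r2"])  # replicates: noise only

  ## downstream of the terminator the level is f times the gene body,
  ## by direct evaluation of the abundance model
  ctr <- start(sim$probes)
  body <- ctr >= 1001 & ctr <= 1400
  down <- ctr > 1400 & ctr <= 2000
  expect_equal(mean(d[down, "mut_r1"]) / mean(d[body, "mut_r1"]), 0.3,
               tolerance = 1e-12)
})

test_that("readthrough abundance is monotone in the injected fraction", {
  ratios <- vapply(c(0, 0.2, 0.4, 0.8), function(f) {
    cfg <- smallConfig(f = f)
    Tm <- expectedAbundance(cfg, "mut")
    ctr <- start(probeLayout(cfg))
    mean(Tm[ctr > 1400 & ctr <= 2000]) / mean(Tm[ctr >= 1001 &
                                                   ctr <= 1400])
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("attenuator release and elongation slope shape the profile", {
  cfg <- smallConfig(noiseCv = 0, bgSd = 0, release = 0.25, att = 500,
                     slope = 0)
  Tm <- expectedAbundance(cfg, "mut")
  ctr <- start(probeLayout(cfg))
  expect_equal(mean(Tm[ctr >= 3001 & ctr < 3501]), 1)
  expect_equal(mean(Tm[ctr >= 3501 & ctr <= 4800]), 0.25)

  cfg2 <- smallConfig(noiseCv = 0, bgSd = 0, slope = 0.5)
  T2 <- expectedAbundance(cfg2, "mut")
  atStart <- T2[ctr == 3005]
  at1kb <- T2[ctr == 4000]
  expect_equal(at1kb / atStart, (1 - 0.5 * 999 / 1000) / (1 - 0.5 * 4 / 1000),
               tolerance = 1e-9)
})

test_that("the default scenario states the advertised world", {
  cfg <- defaultScenario(1)
  expect_true(methods::validObject(cfg))
  m <- mcols(cfg@features)
  expect_gte(length(cfg@strains), 7)          # wild type + 6 mutants
  expect_gte(sum(m$kind == "snr"), 8)
  expect_gte(sum(m$kind == "orf"), 20)
  expect_gte(sum(m$kind == "mask"), 1)
  ## injected readthrough fractions span 0 to 0.6
  f <- cfg@effects$readthrough_fraction
  expect_equal(max(f), 0.6)
  expect_true(all(c(0.15, 0.3, 0.6) %in% f))
  ## the negative-control gene has no effect in any strain
  neg <- cfg@effects[cfg@effects$feature_id == "snr07", ]
  expect_true(all(neg$readthrough_fraction == 0))
  expect_true(all(neg$fold_change == 1))
})

test_that("planted promoter regions carry the advertised elements", {
  sim <- getDefaultSim()
  g <- sim$features[mcols(sim$features)$id == "orf_stss"]
  utr <- Biostrings::subseq(sim$genome[["chrI"]], start(g) - 350,
                            start(g) - 1)
  expect_equal(length(Biostrings::matchPattern("ATG", utr)), 0L)
  expect_gte(length(Biostrings::matchPattern("TCTT", utr)), 1L)
  tata <- Biostrings::subseq(sim$genome[["chrI"]], start(g) - 400,
                             start(g) - 201)
  hits <- Biostrings::matchPattern(Biostrings::DNAString("TATAWAWR"),
                                   tata, fixed = FALSE)
  expect_equal(length(hits), 1L)
})
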