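## a hand-built snr gene on probes every 5 bp: gene body 1001..1400
## (mature end 1400), downstream region 1410..1710
rtGene <- featureSet("snrX", "snr", "chrT", 1001, 1400, strand = "+",
                     mature_end = 1400)

## track whose *linear* level is `body` over the gene and `down`
## downstream (log2 values; 0 encodes linear 0 by the floor rule)
rtTrack <- function(body, down, n = 500, strain = "m") {
  centers <- seq(5, by = 5, length.out = n)
  lin <- ifelse(centers >= 1001 & centers <= 1400, body,
                ifelse(centers > 1400 & centers <= 1710, down, 0))
  vals <- ifelse(lin > 1, log2(lin), 0)
  tinyTrack(vals, strain = strain)
}

test_that("readthrough ratios match their defining arithmetic", {
  expect_equal(readthroughRatio(rtGene, rtTrack(200, 0))$ratio, 0)
  expect_equal(readthroughRatio(rtGene, rtTrack(200, 200))$ratio, 100)
  expect_equal(readthroughRatio(rtGene, rtTrack(200, 60))$ratio, 30)
  ## zero body -> undefined, recorded not thrown
  expect_true(is.na(readthroughRatio(rtGene, rtTrack(0, 60))$ratio))
  ## scale invariance: doubling the linear signal leaves the ratio alone
  r1 <- readthroughRatio(rtGene, rtTrack(100, 30))$ratio
  r2 <- readthroughRatio(rtGene, rtTrack(200, 60))$ratio
  expect_equal(r1, r2)
})

test_that("max50 scans sub-windows while mean_region averages", {
  ## downstream: one hot 50-bp stretch (level 120) in an otherwise
  ## low (level 20) region
  centers <- seq(5, by = 5, length.out = 500)
  lin <- ifelse(centers >= 1001 & centers <= 1400, 200,
           ifelse(centers > 1400 & centers <= 1710, 20, 0))
  lin[centers >= 1511 & centers < 1561] <- 120
  tr <- tinyTrack(ifelse(lin > 1, log2(lin), 0), strain = "m")
  mx <- readthroughRatio(rtGene, tr, "max50")$ratio
  mn <- readthroughRatio(rtGene, tr, "mean_region")$ratio
  expect_equal(mx, 60, tolerance = 0.02)   # the hot window: 120/200
  expect_lt(mn, 25)                        # diluted across the region
})

test_that("differential classification follows the 10/100 thresholds", {
  wt <- rtTrack(200, 10, strain = "WT")
  expect_equal(differentialReadthrough(rtGene, wt, wt)$differential, 0)
  expect_equal(differentialReadthrough(rtGene, wt, wt)$classification,
               "none")
  r <- differentialReadthrough(rtGene, rtTrack(200, 70), wt)
  expect_equal(r$differential, 30)
  expect_equal(r$classification, "readthrough")
  r2 <- differentialReadthrough(rtGene, rtTrack(200, 240), wt)
  expect_equal(r2$classification, "confounded")  # differential 115
  ## apparent readthrough driven by diminished mature RNA: ratio rises
  ## because the body shrank; flagged via body_decrease
  r3 <- differentialReadthrough(rtGene, rtTrack(80, 14), wt)
  expect_equal(r3$classification, "readthrough")  # 17.5 - 5 = 12.5
  expect_true(r3$body_decrease)
})

test_that("genes with adjacent 3' transcription units are excluded", {
  fx <- suppressWarnings(c(
    rtGene,
    featureSet("cutY", "cut", "chrT", 1451, 1900, strand = "+"),
    featureSet("mz", "mask", "chrT", 1405, 1500)))
  flags <- flagConfoundedGenes(rtGene, fx)
  expect_true(flags[["snrX"]])              # CUT 50 bp downstream
  ## masks do not exclude; an isolated gene survives
  flags2 <- flagConfoundedGenes(rtGene, fx[mcols(fx)$id != "cutY"])
  expect_false(flags2[["snrX"]])
  ## user overrides win
  expect_false(flagConfoundedGenes(rtGene, fx,
                                   forceInclude = "snrX")[["snrX"]])
})

test_that("the panel table recovers injected readthrough truth", {
  sim <- getDefaultSim()
  tracks <- getRnaTracks()
  tbl <- readthroughTable(sim$features, tracks, "WT",
                          allFeatures = sim$features)
  ## the gene with a CUT at its 3' end is excluded, the rest retained
  expect_true("snr09" %in% attr(tbl, "excluded"))
  retained <- setdiff(sprintf("snr%02d", 1:9), attr(tbl, "excluded"))
  expect_equal(nrow(tbl), length(retained) * length(MUTANTS))

  truth <- sim$truth
  key <- paste(tbl$gene_id, tbl$strain)
  f <- truth$readthrough_fraction[match(key, paste(truth$feature_id,
                                                   truth$strain))]
  ## injected f >= 0.15 classifies as a termination defect; f = 0 as none
  expect_true(all(tbl$classification[f >= 0.15] == "readthrough"))
  expect_true(all(tbl$classification[f == 0] == "none"))
  ## the negative control is clean in every strain
  expect_true(all(tbl$classification[tbl$gene_id == "snr07"] == "none"))
  ## monotonicity: within snr01 the measured differential follows the
  ## injected fraction ordering (hrp1 0.15 < nrd1 0.3 < sen1 0.6)
  d <- tbl[tbl$gene_id == "snr01", ]
  expect_lt(d$differential[d$strain == "hrp1"],
            d$differential[d$strain == "nrd1"])
  expect_lt(d$differential[d$strain == "nrd1"],
            d$differential[d$strain == "sen1"])
  ## wide view has one row per gene, one column per mutant
  wide <- readthroughWide(tbl)
  expect_equal(dim(wide), c(length(retained), length(MUTANTS) + 1L))
})

test_that("ratios agree with direct windowed means to 1e-9", {
  tracks <- getRnaTracks()
  sim <- getDefaultSim()
  for (id in c("snr01", "snr03")) {          # plus and minus strand
    g <- sim$features[mcols(sim$features)$id == id]
    tr <- tracks$sen1
    got <- readthroughRatio(g, tr, "mean_region")
    pr <- probeCenters(tr)
    ctr <- start(pr)
    on <- as.character(seqnames(pr)) == as.character(seqnames(g))
    v <- trackValues(tr)
    lin <- ifelse(!is.na(v) & v > 0, 2^v, 0)
    me <- mcols(g)$mature_end
    if (as.character(strand(g)) == "-") {
      body <- on & ctr >= me & ctr <= end(g)
      down <- on & (me - ctr) >= 10 & (me - ctr) < 310
    } else {
      body <- on & ctr >= start(g) & ctr <= me
      down <- on & (ctr - me) >= 10 & (ctr - me) < 310
    }
    expect_equal(got$ratio, 100 * mean(lin[down]) / mean(lin[body]),
                 tolerance = 1e-9)
  }
})
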