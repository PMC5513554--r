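test_that("metagene bins average correctly and respect strand", {
  ## constant track: every bin equals the constant
  genes <- featureSet("g1", "orf", "chrT", 501, 1500, strand = "+")
  tr <- tinyTrack(rep(1.25, 400), kind = "log2fc", baseline = "WT")
  mg <- metagene(genes, tr)
  expect_true(all(abs(mg$mean[mg$n_genes > 0] - 1.25) < 1e-12))

  ## a plus-strand ramp and its minus-strand mirror give identical
  ## profiles (gene bounds chosen so probe offsets from the 5' end are
  ## the same set on both strands)
  n <- 400
  centers <- seq(5, by = 5, length.out = n)
  inGene <- centers >= 503 & centers <= 1502
  ramp <- ifelse(inGene, (centers - 503) / 1000, 0)
  mirror <- ifelse(inGene, (1502 - centers) / 1000, 0)
  trP <- tinyTrack(ramp, kind = "log2fc", baseline = "WT")
  trM <- tinyTrack(mirror, kind = "log2fc", baseline = "WT")
  gP <- featureSet("g", "orf", "chrT", 503, 1502, strand = "+")
  gM <- featureSet("g", "orf", "chrT", 503, 1502, strand = "-")
  mgP <- metagene(gP, trP)
  mgM <- metagene(gM, trM)
  orfBins <- mgP$region == "orf"
  expect_equal(mgP$mean[orfBins], mgM$mean[orfBins], tolerance = 1e-12)

  ## ramp oracle: each bin mean equals the direct probe lookup
  for (b in c(1, 25, 50, 99)) {
    inBin <- inGene & floor(100 * (centers - 503) / 1000) + 1 == b
    expect_equal(mgP$mean[orfBins][b], mean(ramp[inBin]),
                 tolerance = 1e-12)
  }
})

test_that("correlation matrix has the defining properties", {
  set.seed(5)
  v <- rnorm(500)
  t1 <- tinyTrack(v, kind = "log2fc", strain = "a", baseline = "WT")
  t2 <- tinyTrack(-v, kind = "log2fc", strain = "b", baseline = "WT")
  t3 <- tinyTrack(2 * v + 3, kind = "log2fc", strain = "c",
                  baseline = "WT")
  M <- correlationMatrix(list(a = t1, b = t2, c = t3))
  expect_equal(diag(M), c(a = 1, b = 1, c = 1))
  expect_equal(M, t(M))
  expect_equal(M["a", "b"], -1)
  expect_equal(M["a", "c"], 1)    # affine invariance

  ## missing values are dropped pairwise
  v2 <- v; v2[1:100] <- NA
  t4 <- tinyTrack(v2, kind = "log2fc", strain = "d", baseline = "WT")
  M2 <- correlationMatrix(list(a = t1, d = t4))
  expect_equal(M2["a", "d"], 1)
})

test_that("mutants sharing more targets correlate higher", {
  fc <- getFcTracks()
  M <- correlationMatrix(lapply(fc, `[[`, "signal"))
  ## nrd1/nab3 share most affected genes; rpb11's are mostly private
  expect_gt(M["nrd1", "nab3"], M["nrd1", "rpb11"])
  expect_gt(M["nrd1", "nab3"], M["nab3", "rpb11"])
  expect_gt(M["sen1", "nrd1"], M["hrp1", "rpb11"])
})

test_that("loop detection isolates injected excursions", {
  set.seed(77)
  n <- 2000
  base <- rnorm(n, 0, 0.1)
  centers <- seq(5, by = 5, length.out = n)
  inj <- centers >= 4001 & centers <= 6000     # one 2-kb region
  a <- base; a[inj] <- 3 + rnorm(sum(inj), 0, 0.1)
  trA <- tinyTrack(a, kind = "log2fc", strain = "A", baseline = "WT")
  trB <- tinyTrack(rnorm(n, 0, 0.1), kind = "log2fc", strain = "B",
                   baseline = "WT")
  segs <- detectLoops(trA, trB)
  expect_equal(length(segs), 1L)
  expect_lte(start(segs), 4005)
  expect_gte(end(segs), 5995)
  expect_gt(segs$meanA, 2.5)

  ## an unreachable threshold yields nothing; identical points too
  expect_equal(length(detectLoops(trA, trB, zThreshold = Inf)), 0L)
  flat <- tinyTrack(rep(1, 50), kind = "log2fc", strain = "A",
                    baseline = "WT")
  expect_warning(expect_warning(none <- detectLoops(flat, flat),
                                "MAD"), "MAD")   # once per track
  expect_equal(length(none), 0L)

  ## segments are disjoint and sorted
  b2 <- base
  b2[centers >= 1001 & centers <= 1500] <- -3
  b2[centers >= 8001 & centers <= 8500] <- 4
  trC <- tinyTrack(b2, kind = "log2fc", strain = "C", baseline = "WT")
  segs2 <- detectLoops(trC, trB)
  expect_gte(length(segs2), 2L)
  expect_true(all(diff(start(segs2)) > 0))
  expect_true(all(start(segs2)[-1] > end(segs2)[-length(segs2)]))
})

test_that("gene-level change equals the direct probe mean", {
  genes <- featureSet(c("g1", "g2"), "orf", "chrT", c(101, 1101),
                      c(600, 1600), strand = "+")
  v <- c(rep(0, 20), rep(1, 100), rep(0, 100), rnorm(100), rep(0, 80))
  tr <- tinyTrack(v, kind = "log2fc", baseline = "WT")
  gl <- geneLevelChange(genes, tr)
  expect_equal(gl$mean_log2fc[1], 1)
  expect_equal(gl$fold[1], 2)
  centers <- seq(5, by = 5, length.out = length(v))
  expect_equal(gl$mean_log2fc[2],
               mean(v[centers >= 1101 & centers <= 1600]),
               tolerance = 1e-9)
})
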