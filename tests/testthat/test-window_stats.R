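test_that("window widths and membership follow the bp definition", {
  expect_warning(w <- adjustWindowWidth(500), "adjusted")
  expect_equal(w, 501L)
  expect_error(adjustWindowWidth(0), ">= 1")

  exp <- tinyExp(matrix(1, 60, 2), strains = c("A", "A"))
  ## width 1: only the centre probe, both arrays
  wv <- collectWindow(exp, "chrT", 150, windowBp = 1)
  expect_equal(length(wv$d), 2L)
  ## 5-bp spacing, width 101: 21 probes per array in the interior
  wv2 <- collectWindow(exp, "chrT", 150, windowBp = 101)
  expect_equal(length(wv2$d), 42L)
  ## chromosome edge: truncated, no wraparound (centre 5: probes 5..55)
  wv3 <- collectWindow(exp, "chrT", 5, windowBp = 101)
  expect_equal(length(wv3$d), 22L)
})

test_that("signed-rank signal matches hand-derived examples", {
  ## d = {1,2,3}: Walsh averages 1,1.5,2,2,2.5,3 -> pseudomedian 2
  r <- signedRankSignal(c(1, 2, 3))
  expect_equal(r$s, 2)
  expect_equal(r$rna_level, 1)      # log2(2)

  ## the floor rule: s <= 1 gives RNA level 0
  r2 <- signedRankSignal(c(0.2, 0.5, 0.9))
  expect_lte(r2$s, 1)
  expect_equal(r2$rna_level, 0)

  ## all-zero window: p = 1, score 0, level 0
  r3 <- signedRankSignal(rep(0, 5))
  expect_equal(r3$p, 1)
  expect_equal(r3$detection_score, 0)
  expect_equal(r3$rna_level, 0)

  ## -10 log10 mapping
  expect_equal(-10 * log10(0.1), 10)
  expect_equal(r3$detection_score, -10 * log10(r3$p))
})

test_that("exact signed-rank p equals exhaustive sign enumeration", {
  set.seed(101)
  pool <- c(-3, -2, -1, 0, 0, 1, 1, 2, 2, 3, 4, 5)  # ties and zeros
  for (n in c(4, 7, 10, 12)) {
    for (rep_ in 1:6) {
      d <- sample(pool, n, replace = TRUE)
      expect_equal(signedRankSignal(d)$p, enumSignedRankP(d),
                   tolerance = 1e-12,
                   info = paste("n =", n, "d =", paste(d, collapse = ",")))
    }
  }
})

test_that("exact rank-sum p equals exhaustive subset enumeration", {
  ## frozen example: {1,2,3} vs {0,1,2} -> shift 1 (median of the nine
  ## pairwise differences -1,0,0,1,1,1,2,2,3)
  r <- rankSumDifferential(c(1, 2, 3), c(0, 1, 2))
  expect_equal(r$log2fc, 1)
  expect_equal(r$p, enumRankSumP(c(1, 2, 3), c(0, 1, 2)),
               tolerance = 1e-12)

  set.seed(202)
  for (rep_ in 1:8) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    xt <- sample(0:4, n1, replace = TRUE)  # heavy ties on purpose
    xc <- sample(0:4, n2, replace = TRUE)
    expect_equal(rankSumDifferential(xt, xc)$p, enumRankSumP(xt, xc),
                 tolerance = 1e-12)
  }
})

test_that("Hodges-Lehmann estimators match brute-force enumeration", {
  set.seed(303)
  for (rep_ in 1:5) {
    d <- round(rnorm(9), 2)
    expect_equal(pseudomedian(d), bruteWalshMedian(d), tolerance = 1e-12)
    a <- round(rnorm(6), 2); b <- round(rnorm(8), 2)
    expect_equal(hodgesLehmannShift(a, b), brutePairwiseShift(a, b),
                 tolerance = 1e-12)
  }
  ## shift equivariance: adding c to treatment adds exactly c
  a <- c(1.2, 3.1, 0.4); b <- c(0.3, 1.1, 2.2)
  expect_equal(hodgesLehmannShift(a + 0.7, b),
               hodgesLehmannShift(a, b) + 0.7)
  expect_equal(hodgesLehmannShift(a, a), 0)
})

test_that("normal-approximation path matches wilcox.test", {
  set.seed(404)
  d <- rnorm(40) + 0.2                       # no ties, no zeros
  ref <- stats::wilcox.test(d, alternative = "greater", exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(signedRankSignal(d)$p, ref, tolerance = 1e-10)

  xt <- rnorm(30); xc <- rnorm(25)
  ref2 <- stats::wilcox.test(xt, xc, exact = FALSE,
                             correct = TRUE)$p.value
  expect_equal(rankSumDifferential(xt, xc)$p, ref2, tolerance = 1e-10)
})

test_that("tracks behave on constant and null inputs", {
  ## constant PM-MM -> constant RNA level in the interior
  exp <- tinyExp(matrix(9, 80, 2), matrix(1, 80, 2),
                 strains = c("A", "A"))
  tr <- makeTracks(exp, "A", windowBp = 101)
  v <- trackValues(tr$signal)
  expect_equal(v[15:65], rep(3, 51))         # log2(9 - 1)

  ## widening the window reduces variance on null regions
  set.seed(9)
  expN <- tinyExp(matrix(rlnorm(2000 * 4, log(200), .3), 2000, 4),
                  matrix(rlnorm(2000 * 4, log(60), .3), 2000, 4),
                  strains = c("A", "A", "B", "B"))
  narrow <- makeTracks(expN, "A", baseline = "B", windowBp = 101)
  wide <- makeTracks(expN, "A", baseline = "B", windowBp = 301)
  expect_lt(stats::var(trackValues(wide$signal)),
            stats::var(trackValues(narrow$signal)))
})

test_that("log2fc tracks require a baseline and propagate masks", {
  exp <- tinyExp(matrix(5, 30, 2), strains = c("A", "A"))
  expect_error(makeTrack(exp, "A", "log2fc"), "baseline")
  tr <- makeTrack(exp, "A", "rna_level")
  mk <- featureSet("m", "mask", "chrT", 1, 40)
  masked <- maskTrack(tr, mk)
  expect_true(all(is.na(trackValues(masked)[1:8])))
  expect_false(anyNA(trackValues(masked)[9:30]))
})
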