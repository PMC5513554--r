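test_that("GFF3 and BED dialects land on the same genomic bases", {
  ## GFF3 is 1-based inclusive: start=101 end=200 covers 100 bases
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA"), gff)
  fs <- readFeatures(gff, "gff3")
  expect_equal(start(fs), 101L)
  expect_equal(end(fs), 200L)
  expect_equal(width(fs), 100L)
  expect_equal(mcols(fs)$kind, "orf")

  ## BED is 0-based half-open: 99..200 covers bases 100..200
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tgeneX\t0\t-", bed)
  fb <- readFeatures(bed, "bed")
  expect_equal(start(fb), 100L)
  expect_equal(end(fb), 200L)
  expect_equal(as.character(strand(fb)), "-")
  expect_equal(mcols(fb)$id, "geneX")
})

test_that("feature write/read round trips are lossless", {
  fs <- featureSet(c("g1", "snrA", "cutB"), c("orf", "snr", "cut"),
                   c("chrI", "chrI", "chrII"), c(100, 500, 20),
                   c(400, 800, 220), strand = c("+", "-", "+"),
                   mature_end = c(NA, 600, NA))
  gff <- tempfile(fileext = ".gff3")
  writeFeatures(fs, gff, "gff3")
  back <- readFeatures(gff, "gff3")
  back <- back[match(mcols(fs)$id, mcols(back)$id)]
  expect_equal(start(back), start(fs))
  expect_equal(end(back), end(fs))
  expect_equal(as.character(strand(back)), as.character(strand(fs)))
  expect_equal(mcols(back)$kind, mcols(fs)$kind)
  expect_equal(mcols(back)$mature_end, mcols(fs)$mature_end)

  bed <- tempfile(fileext = ".bed")
  writeFeatures(fs, bed, "bed")
  back2 <- readFeatures(bed, "bed")
  back2 <- back2[match(mcols(fs)$id, mcols(back2)$id)]
  expect_equal(start(back2), start(fs))
  expect_equal(end(back2), end(fs))
})

test_that("feature invariants are enforced", {
  expect_error(featureSet(c("a", "a"), "orf", "chrI", c(1, 10),
                          c(5, 20)), "unique")
  expect_error(featureSet("s", "snr", "chrI", 1, 100, strand = "*",
                          mature_end = 50), "strand")
  expect_error(featureSet("s", "snr", "chrI", 100, 200, strand = "+",
                          mature_end = 300), "mature_end")
  expect_error(featureSet("x", "nonsense", "chrI", 1, 10), "kind")
})

test_that("intensity TSVs round trip and align to the probe map", {
  pmap <- probeMap(data.frame(probe_id = c("a", "b", "c"),
                              chrom = "chrI", center = c(5, 10, 15)))
  exp <- TilingExperiment(pmap, pm = cbind(c(1, 2, 3), c(4, 5, 6)),
                          mm = cbind(c(.1, .2, .3), c(.4, .5, .6)),
                          strain = c("WT", "WT"), replicate = 1:2)
  f <- tempfile(fileext = ".tsv")
  writeIntensities(exp, f)
  back <- readIntensities(f, pmap)
  expect_equal(pm(back), pm(exp))
  expect_equal(mm(back), mm(exp))

  ## shuffled row order gives the identical object
  df <- read.delim(f)
  fs <- tempfile(fileext = ".tsv")
  write.table(df[c(3, 1, 2), ], fs, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(pm(readIntensities(fs, pmap)), pm(exp))

  ## a missing probe is an error naming the probe
  fm <- tempfile(fileext = ".tsv")
  write.table(df[-2, ], fm, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readIntensities(fm, pmap), "b")

  ## negative intensities are rejected
  df2 <- df; df2$PM_WT_r1[1] <- -1
  fn <- tempfile(fileext = ".tsv")
  write.table(df2, fn, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readIntensities(fn, pmap), "negative")
})

test_that("track output formats behave and round trip", {
  tr <- tinyTrack(c(2, 2, 2))
  bg <- tempfile(fileext = ".bedgraph")
  writeTrack(tr, bg, "bedgraph")
  lines <- readLines(bg)
  expect_lte(length(lines), 3L)

  tr2 <- tinyTrack(c(1.2345678, NA, -0.5))
  bg2 <- tempfile(fileext = ".bedgraph")
  writeTrack(tr2, bg2, "bedgraph")
  back <- readTrack(bg2, "bedgraph", probes = probeCenters(tr2))
  expect_equal(trackValues(back)[c(1, 3)], c(1.234568, -0.5),
               tolerance = 1e-6)
  expect_true(is.na(trackValues(back)[2]))  # masked probe omitted

  tsv <- tempfile(fileext = ".tsv")
  writeTrack(tr2, tsv, "tsv")
  back2 <- readTrack(tsv, "tsv")
  expect_equal(trackValues(back2), c(1.234568, NA, -0.5),
               tolerance = 1e-6)
})

test_that("masking removes exactly the probes inside mask intervals", {
  ## printed coordinates with reversed bounds (as genome papers
  ## sometimes print them) are normalized with a warning
  expect_warning(
    mk <- maskFeatures(c("Chr15", "Chr3"), c(771766, 91185),
                       c(722818, 92702)),
    "reversed")
  expect_equal(start(mk), c(722818L, 91185L))
  expect_equal(end(mk), c(771766L, 92702L))

  centers <- c(722000, 722818, 750000, 771766, 772000)
  pmap <- probeMap(data.frame(probe_id = paste0("p", 1:5),
                              chrom = "Chr15", center = centers))
  tr <- SignalTrack(pmap, rep(1, 5), "rna_level", 101L, "WT")
  masked <- maskTrack(tr, mk)
  expect_equal(is.na(trackValues(masked)), c(FALSE, TRUE, TRUE, TRUE,
                                             FALSE))
  ## idempotent
  expect_equal(trackValues(maskTrack(masked, mk)), trackValues(masked))
  ## empty mask is the identity; a whole-genome mask blanks everything
  expect_equal(trackValues(maskTrack(tr, GRanges())), trackValues(tr))
  all_ <- featureSet("m", "mask", "Chr15", 1, 1e6)
  expect_true(all(is.na(trackValues(maskTrack(tr, all_)))))
})
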