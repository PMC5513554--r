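## Bundled simulation scenarios. The default scenario emulates the kind
## of strain panel the pipeline was designed for: a wild type plus six
## termination-pathway mutants (sen1, nrd1, nab3, ssu72, rpb11, hrp1)
## hybridized in duplicate to a ~200-kb two-chromosome mock genome, with
## sn/snoRNA terminator-readthrough fractions spanning 0-0.6, an
## attenuated gene with a long ATG-free 5'-UTR, an elongation-defect
## ("sawtooth") gene, a meiotic-style gene with upstream-biased
## derepression, a Pol III-like negative-control snRNA, and mask
## intervals standing in for plasmid-borne marker loci.

.MUTANTS <- c("sen1", "nrd1", "nab3", "ssu72", "rpb11", "hrp1")

#' Default validation scenario
#'
#' A ~200-kb, 2-chromosome genome tiled at 5-bp spacing; 7 strains (wild
#' type + six mutants) x 2 replicates. Injected effects:
#' \itemize{
#'  \item nine sn/snoRNA genes with per-strain readthrough fractions
#'    between 0 and 0.6, including one negative control (`snr07`, no
#'    effect anywhere, emulating a Pol III transcript) and one gene with
#'    a cryptic unstable transcript 50 bp downstream (`snr09`, which the
#'    adjacency filter must exclude);
#'  \item `orf_fc` with a log2 fold change of exactly 1.5 in nrd1;
#'  \item `orf_saw` with a 5'->3' elongation gradient in hrp1;
#'  \item `orf_mei` with upstream-biased derepression in sen1;
#'  \item `orf_stss` with a planted attenuator: ATG-free 5'-UTR, single
#'    TATA box, Nab3/Nrd1 sites, upstream poly(A) cluster, and 3-fold
#'    attenuator release in sen1;
#'  \item `orf_dtds` regulated by an independent upstream CUT;
#'  \item filler genes shaping the between-mutant effect overlap (nrd1
#'    and nab3 share most targets; rpb11 is mostly private), plus two
#'    mask intervals.
#' }
#'
#' @param seed integer seed.
#' @return a [SimConfig-class].
#' @export
defaultScenario <- function(seed = 1L) {
  genome <- data.frame(chrom = c("chrI", "chrII"),
                       length = c(120000L, 80000L))
  strains <- c("WT", .MUTANTS)

  snrStart <- c(2001, 5001, 8001, 11001, 14001, 17001, 20001, 23001, 26001)
  snrId <- sprintf("snr%02d", 1:9)
  snrStrand <- c("+", "+", "-", "+", "+", "+", "+", "+", "+")
  snrEnd <- snrStart + 299
  matureEnd <- ifelse(snrStrand == "-", snrStart, snrEnd)
  dsStop <- ifelse(snrStrand == "-", snrStart - 600, snrEnd + 600)
  snr <- featureSet(snrId, "snr", "chrI", snrStart, snrEnd,
                    strand = snrStrand, mature_end = matureEnd,
                    baseline = 1.5, downstream_stop = dsStop)

  orfDef <- rbind(
    data.frame(id = "orf_fc",   chrom = "chrI",  start = 30001, end = 32000),
    data.frame(id = "orf_saw",  chrom = "chrI",  start = 34001, end = 36000),
    data.frame(id = "orf_mei",  chrom = "chrI",  start = 38001, end = 40000),
    data.frame(id = "orf_stss", chrom = "chrI",  start = 43001, end = 44800),
    data.frame(id = "orf_dtds", chrom = "chrI",  start = 47001, end = 48800),
    data.frame(id = paste0("orf_nn", 1:5), chrom = "chrI",
               start = seq(52001, by = 3000, length.out = 5),
               end = seq(53500, by = 3000, length.out = 5)),
    data.frame(id = c("orf_n1", "orf_n2", "orf_b1", "orf_b2"),
               chrom = "chrI",
               start = seq(67001, by = 3000, length.out = 4),
               end = seq(68500, by = 3000, length.out = 4)),
    data.frame(id = paste0("orf_r", 1:3), chrom = "chrI",
               start = seq(80001, by = 3000, length.out = 3),
               end = seq(81500, by = 3000, length.out = 3)),
    data.frame(id = c("orf_ss1", "orf_ss2"), chrom = "chrI",
               start = c(89001, 92001), end = c(90500, 93500)),
    data.frame(id = paste0("orf_h", 1:3), chrom = "chrII",
               start = seq(2001, by = 3000, length.out = 3),
               end = seq(3500, by = 3000, length.out = 3)),
    data.frame(id = paste0("orf_c", 1:4), chrom = "chrII",
               start = seq(12001, by = 3000, length.out = 4),
               end = seq(13500, by = 3000, length.out = 4)))
  orfStrand <- rep("+", nrow(orfDef))
  orfStrand[orfDef$id == "orf_c3"] <- "-"
  orfs <- featureSet(orfDef$id, "orf", orfDef$chrom, orfDef$start,
                     orfDef$end, strand = orfStrand, baseline = 1)
  mcols(orfs)$baseline[orfDef$id == "orf_mei"] <- 0.4
  mcols(orfs)$tss <- NA_real_
  mcols(orfs)$tss[orfDef$id == "orf_stss"] <- 42651   # 350-bp 5'-UTR
  mcols(orfs)$tss[orfDef$id == "orf_dtds"] <- 46651
  mcols(orfs)$attenuator_offset <- NA_real_
  mcols(orfs)$attenuator_offset[orfDef$id == "orf_stss"] <- 300
  mcols(orfs)$plant <- NA_character_
  mcols(orfs)$plant[orfDef$id == "orf_stss"] <- "stss"
  mcols(orfs)$plant[orfDef$id == "orf_dtds"] <- "utr_nab3"

  extra <- featureSet(
    id = c("mei_up", "cut_snr09", "cut_dtds", "pA_stss",
           "mask_hisA", "mask_leuB"),
    kind = c("other", "cut", "cut", "polyA_cluster", "mask", "mask"),
    chrom = c("chrI", "chrI", "chrI", "chrI", "chrII", "chrII"),
    start = c(38001, 26351, 46401, 42986, 30001, 33001),
    end = c(39000, 26800, 46900, 43030, 31000, 33800),
    strand = c("+", "+", "+", "*", "*", "*"),
    baseline = c(0.1, 0.5, 0.2, 0, 0, 0))

  features <- suppressWarnings(c(snr, orfs, extra))
  features <- suppressWarnings(
    c(features, .backgroundFillers(features, genome)))

  ef <- effectTable(mcols(features)$id, strains)
  rt <- function(ef, id, ...) {
    v <- list(...)
    for (st in names(v))
      ef <- .setEffect(ef, id, st, readthrough_fraction = v[[st]])
    ef
  }
  ef <- rt(ef, "snr01", sen1 = 0.6, nrd1 = 0.3, nab3 = 0.3, ssu72 = 0.3,
           hrp1 = 0.15)
  ef <- rt(ef, "snr02", sen1 = 0.3, nrd1 = 0.3, nab3 = 0.25)
  ef <- rt(ef, "snr03", sen1 = 0.45, nrd1 = 0.2, nab3 = 0.2, ssu72 = 0.2)
  ef <- rt(ef, "snr04", sen1 = 0.15, ssu72 = 0.15, rpb11 = 0.3)
  ef <- rt(ef, "snr05", sen1 = 0.6, nrd1 = 0.4, nab3 = 0.45, ssu72 = 0.3,
           rpb11 = 0.2, hrp1 = 0.2)
  ef <- rt(ef, "snr06", sen1 = 0.3)
  ef <- rt(ef, "snr08", sen1 = 0.5, nrd1 = 0.25, nab3 = 0.25, ssu72 = 0.25)
  ef <- rt(ef, "snr09", sen1 = 0.3)

  ef <- .setEffect(ef, "orf_fc", "nrd1", fold_change = 2^1.5)
  ef <- .setEffect(ef, "orf_saw", "hrp1", elongation_slope = 0.35)
  ef <- .setEffect(ef, "orf_mei", "sen1", fold_change = 2.5)
  ef <- .setEffect(ef, "mei_up", "sen1", fold_change = 12)
  ## constitutive attenuation at the stss gene: most transcripts stop in
  ## the 5'-UTR; sen1 releases three times as many into the ORF
  ef <- .setEffect(ef, "orf_stss", strains, attenuator_release = 0.25)
  ef <- .setEffect(ef, "orf_stss", "sen1", attenuator_release = 0.75)
  ef <- .setEffect(ef, "orf_dtds", "nab3", fold_change = 2.2)
  ef <- .setEffect(ef, "cut_dtds", "nab3", fold_change = 3)
  ef <- .setEffect(ef, "cut_snr09", "sen1", fold_change = 2)
  for (id in paste0("orf_nn", 1:5)) {
    ef <- .setEffect(ef, id, "nrd1", fold_change = 3)
    ef <- .setEffect(ef, id, "nab3", fold_change = 3)
  }
  for (id in paste0("orf_nn", 1:3))
    ef <- .setEffect(ef, id, "sen1", fold_change = 3)
  ef <- .setEffect(ef, "orf_n1", "nrd1", fold_change = 3)
  ef <- .setEffect(ef, "orf_n2", "nrd1", fold_change = 3)
  ef <- .setEffect(ef, "orf_b1", "nab3", fold_change = 3)
  ef <- .setEffect(ef, "orf_b2", "nab3", fold_change = 3)
  for (id in paste0("orf_r", 1:3))
    ef <- .setEffect(ef, id, "rpb11", fold_change = 3)
  ef <- .setEffect(ef, "orf_ss1", "ssu72", fold_change = 3)
  ef <- .setEffect(ef, "orf_ss1", "sen1", fold_change = 2.5)
  ef <- .setEffect(ef, "orf_ss2", "ssu72", fold_change = 3)
  ef <- .setEffect(ef, "orf_ss2", "nrd1", fold_change = 2.5)
  ef <- .setEffect(ef, "orf_h1", "hrp1", fold_change = 0.5)
  ef <- .setEffect(ef, "orf_h2", "hrp1", fold_change = 0.5)
  ef <- .setEffect(ef, "orf_h3", "hrp1", elongation_slope = 0.2)

  simConfig(seed = seed, genome = genome, features = features,
            effects = ef, strains = strains, wtLabel = "WT")
}

## Neutral "background transcription" units tiling the gaps between the
## designed features: real yeast chromosomes are pervasively transcribed
## and rank-based normalization presumes a mostly unchanged intensity
## distribution, so the mock genome should not be mostly silent.
## Baselines cycle through a log-spaced ladder to give a smooth
## abundance distribution. Clearance margins keep the sn/snoRNA
## readthrough regions and planted promoter regions free.
.backgroundFillers <- function(features, genome, unitBp = 1000L,
                               gapBp = 200L, margin = 150L) {
  m <- mcols(features)
  lo <- start(features) - margin
  hi <- end(features) + margin
  snr <- which(m$kind == "snr" & !is.na(m$downstream_stop))
  minus <- as.character(strand(features)) == "-"
  lo[snr] <- ifelse(minus[snr], m$downstream_stop[snr] - margin, lo[snr])
  hi[snr] <- ifelse(minus[snr], hi[snr], m$downstream_stop[snr] + margin)
  planted <- which(!is.na(m$plant))
  lo[planted] <- pmin(lo[planted], start(features)[planted] - 500L)
  blocked <- GenomicRanges::reduce(
    GRanges(seqnames(features), IRanges(pmax(1L, lo), hi)),
    ignore.strand = TRUE)
  ladder <- c(0.3, 0.5, 0.8, 1.2, 1.8, 2.7, 4, 6)
  out <- NULL
  k <- 0L
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    free <- GenomicRanges::setdiff(
      GRanges(ch, IRanges(1L, genome$length[i])),
      blocked[seqnames(blocked) == ch], ignore.strand = TRUE)
    for (j in seq_along(free)) {
      s <- start(free)[j] + gapBp
      while (s + unitBp - 1L <= end(free)[j] - gapBp) {
        k <- k + 1L
        gr <- featureSet(sprintf("bg%03d", k), "other", ch,
                         s, s + unitBp - 1L, strand = "+",
                         baseline = ladder[(k - 1L) %% length(ladder) + 1L])
        out <- if (is.null(out)) gr else suppressWarnings(c(out, gr))
        s <- s + unitBp + gapBp
      }
    }
  }
  if (is.null(out)) GRanges() else out
}

#' No-effect calibration scenario
#'
#' A 60-kb single-chromosome genome with 20 expressed but unaffected
#' genes and two strains (wild type and a mutant with every effect
#' neutral). Under this null the differential detection score should
#' exceed the p < 0.05 line at ~5\% of positions and the metagene
#' profile should be flat.
#'
#' @param seed integer seed.
#' @param nGenes number of expressed genes (default 20).
#' @return a [SimConfig-class].
#' @export
nullScenario <- function(seed = 1L, nGenes = 20L) {
  genome <- data.frame(chrom = "chrN", length = 60000L)
  starts <- 501 + (seq_len(nGenes) - 1L) * floor(58000 / nGenes)
  orfs <- featureSet(sprintf("gene%02d", seq_len(nGenes)), "orf", "chrN",
                     starts, starts + 1499, strand = "+", baseline = 1)
  simConfig(seed = seed, genome = genome, features = orfs,
            effects = effectTable(mcols(orfs)$id, c("WT", "mut")),
            strains = c("WT", "mut"), wtLabel = "WT")
}
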