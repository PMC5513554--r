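## Rule-based candidate screens: transcription attenuation (long
## ATG-free 5'-UTR with terminator motifs and premature poly(A) sites)
## and meiotic-style upstream-biased derepression.

#' @importFrom Biostrings DNAString matchPattern reverseComplement subseq
NULL

.DEFAULT_SCREEN_PARAMS <- list(
  minFold = 2, utrLength = 350, tataWindow = c(200, 400),
  nab3 = "UCUU", nrd1 = "GUAR", tata = "TATAWAWR")

## sense-strand (nontemplate) sequence of a genome interval
.senseSeq <- function(genome, chrom, from, to, minus) {
  if (!chrom %in% names(genome))
    stop("no sequence for chromosome ", chrom)
  s <- subseq(genome[[chrom]], max(1L, from),
              min(length(genome[[chrom]]), to))
  if (minus) reverseComplement(s) else s
}

.iupacDNA <- function(consensus) {
  DNAString(chartr("uU", "tT", consensus))
}

.motifHits <- function(seq, consensus) {
  start(matchPattern(.iupacDNA(consensus), seq, fixed = FALSE))
}

#' Screen protein-coding genes for attenuation-like features
#'
#' Candidate genes (fold change >= `minFold` in at least one strain)
#' are tested for the hallmarks of regulation by an upstream Sen1-
#' dependent terminator: an ATG-free nontemplate strand across the
#' 5'-UTR scan region, Nab3/Nrd1 motif matches on the transcript strand,
#' a TATA consensus in the promoter window, and a premature poly(A)
#' cluster in the UTR. `passed` is the conjunction fold-filter AND
#' ATG-free AND (motif OR poly(A) cluster); every component is reported
#' so users can re-weight. The mode hint distinguishes single-TATA
#' single-start attenuation (ST-SS), an independent upstream transcript
#' (DT-DS, when an annotated CUT overlaps the UTR), and the remaining
#' dual-start cases (ST-DS).
#'
#' @param genes feature `GRanges` (orf rows are screened). A `tss`
#'   metadata column, when present, anchors the UTR at the annotated
#'   transcript start; otherwise the scan region is `utrLength` bp
#'   upstream of the start codon.
#' @param geneChanges combined [geneLevelChange()] table over strains
#'   (must contain `gene_id`, `strain`, `fold`).
#' @param genome a `DNAStringSet` of chromosome sequences.
#' @param polyA feature `GRanges` of poly(A) clusters (kind
#'   "polyA_cluster" rows are used).
#' @param features optional full feature `GRanges`; `cut` rows flag
#'   DT-DS candidates.
#' @param params list overriding [.DEFAULT_SCREEN_PARAMS]: `minFold`,
#'   `utrLength`, `tataWindow` (bp upstream of the start codon),
#'   motif consensi in IUPAC code (`nab3`, `nrd1`, `tata`).
#' @return data.frame, one row per candidate gene.
#' @export
screenAttenuators <- function(genes, geneChanges, genome, polyA,
                              features = NULL, params = list()) {
  p <- utils::modifyList(.DEFAULT_SCREEN_PARAMS, params)
  genes <- genes[mcols(genes)$kind == "orf"]
  if (!is.null(polyA) && !is.null(mcols(polyA)$kind))
    polyA <- polyA[mcols(polyA)$kind == "polyA_cluster"]
  cuts <- if (!is.null(features))
    features[mcols(features)$kind == "cut"] else GRanges()
  maxFold <- tapply(geneChanges$fold, geneChanges$gene_id, max,
                    na.rm = TRUE)
  cand <- names(maxFold)[is.finite(maxFold) & maxFold >= p$minFold]
  cand <- intersect(mcols(genes)$id, cand)
  rows <- lapply(cand, function(id) {
    g <- genes[mcols(genes)$id == id]
    minus <- as.character(strand(g)) == "-"
    ch <- as.character(seqnames(g))
    tss <- if (!is.null(mcols(g)$tss)) mcols(g)$tss else NA_real_
    utrLen <- if (!is.na(tss)) {
      if (minus) tss - end(g) else start(g) - tss
    } else p$utrLength
    if (minus) {
      utrFrom <- end(g) + 1L; utrTo <- end(g) + utrLen
      tataFrom <- end(g) + p$tataWindow[1]; tataTo <- end(g) + p$tataWindow[2]
    } else {
      utrFrom <- start(g) - utrLen; utrTo <- start(g) - 1L
      tataFrom <- start(g) - p$tataWindow[2]
      tataTo <- start(g) - p$tataWindow[1]
    }
    utrSeq <- .senseSeq(genome, ch, utrFrom, utrTo, minus)
    tataSeq <- .senseSeq(genome, ch, tataFrom, tataTo, minus)
    atgFree <- length(.motifHits(utrSeq, "ATG")) == 0L
    nab3Hits <- .motifHits(utrSeq, p$nab3)
    nrd1Hits <- .motifHits(utrSeq, p$nrd1)
    tataHits <- .motifHits(tataSeq, p$tata)
    utrGr <- GRanges(ch, IRanges(max(1L, utrFrom), utrTo))
    pA <- length(polyA) > 0L &&
      length(GenomicRanges::findOverlaps(utrGr, polyA,
                                         ignore.strand = TRUE)) > 0L
    cutOverlap <- length(cuts) > 0L &&
      length(GenomicRanges::findOverlaps(utrGr, cuts,
                                         ignore.strand = TRUE)) > 0L
    passed <- atgFree && (length(nab3Hits) + length(nrd1Hits) > 0L || pA)
    mode <- if (!passed) "none"
    else if (length(tataHits) == 1L && pA) "ST-SS"
    else if (cutOverlap) "DT-DS"
    else "ST-DS"
    data.frame(gene_id = id, max_fold = unname(maxFold[id]),
               utr_start = utrFrom, utr_end = utrTo, atg_free = atgFree,
               tata_hits = length(tataHits),
               nab3_sites = paste(nab3Hits, collapse = ","),
               nrd1_sites = paste(nrd1Hits, collapse = ","),
               n_motif_sites = length(nab3Hits) + length(nrd1Hits),
               polyA_cluster_present = pA, cut_overlap = cutOverlap,
               mode_hint = mode, passed = passed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), max_fold = numeric(),
                      utr_start = integer(), utr_end = integer(),
                      atg_free = logical(), tata_hits = integer(),
                      nab3_sites = character(), nrd1_sites = character(),
                      n_motif_sites = integer(),
                      polyA_cluster_present = logical(),
                      cut_overlap = logical(), mode_hint = character(),
                      passed = logical())
  out
}

#' Upstream-half vs downstream-half expression bias
#'
#' Splits each ORF at its midpoint in transcription direction and
#' compares the mean log2 fold change of the two halves. Genes whose
#' upstream half rises at least `minUp` with a bias (up - down) of at
#' least `minBias` are flagged — the signature of a derepressed
#' upstream (e.g. meiotic) transcription start site.
#'
#' @param genes feature `GRanges` (orf rows are used).
#' @param track a log2fc [SignalTrack-class].
#' @param minUp,minBias flag thresholds (defaults 1.0 and 0.5).
#' @return data.frame (gene_id, up_mean, down_mean, bias, flagged).
#' @export
upstreamBias <- function(genes, track, minUp = 1.0, minBias = 0.5) {
  genes <- genes[mcols(genes)$kind == "orf"]
  pr <- probeCenters(track)
  ctr <- start(pr)
  chrom <- as.character(seqnames(pr))
  v <- trackValues(track)
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    minus <- as.character(strand(g)) == "-"
    mid <- start(g) + (end(g) - start(g)) %/% 2L
    on <- chrom == as.character(seqnames(g)) & !is.na(v)
    left <- on & ctr >= start(g) & ctr <= mid
    right <- on & ctr > mid & ctr <= end(g)
    upSel <- if (minus) right else left
    downSel <- if (minus) left else right
    up <- if (any(upSel)) mean(v[upSel]) else NA_real_
    down <- if (any(downSel)) mean(v[downSel]) else NA_real_
    data.frame(gene_id = mcols(g)$id, up_mean = up, down_mean = down,
               bias = up - down,
               flagged = !is.na(up) && !is.na(down) &&
                 up >= minUp && (up - down) >= minBias,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genes above a fold-change threshold in one strain
#'
#' @param geneChanges [geneLevelChange()] output (optionally combined
#'   over strains with a `strain` column).
#' @param strain strain to filter on (required when the table has a
#'   `strain` column with several levels).
#' @param minFold inclusive fold threshold (default 2: "at least
#'   two-fold").
#' @return character vector of gene ids sorted by decreasing fold.
#' @export
thresholdGeneList <- function(geneChanges, strain = NULL, minFold = 2) {
  if (!is.null(geneChanges$strain) && !is.null(strain)) {
    if (!strain %in% geneChanges$strain)
      stop("unknown strain: ", strain)
    geneChanges <- geneChanges[geneChanges$strain == strain, ]
  }
  keep <- !is.na(geneChanges$fold) & geneChanges$fold >= minFold
  sel <- geneChanges[keep, ]
  sel$gene_id[order(-sel$fold)]
}
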