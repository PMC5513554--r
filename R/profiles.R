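## Metagene profiles, between-mutant track correlation, scatter-loop
## segment detection, and gene-level fold changes.

#' Metagene profile over scaled gene bodies and 3'-UTRs
#'
#' Each gene's probes map to percent-distance bins along the ORF in
#' transcription direction (minus-strand genes reversed), plus fixed-
#' width bins over the first `utrBp` bases past the stop codon (a
#' surrogate for the 3'-UTR). Per-gene bin means are computed first and
#' then averaged across genes with equal weight, so long genes do not
#' dominate.
#'
#' @param genes feature `GRanges` (orf rows are used).
#' @param track a [SignalTrack-class] (typically log2fc).
#' @param orfBins number of percent-distance bins (default 100).
#' @param utrBp,utrBins 3'-UTR stretch and bin count (default 100 bp in
#'   10 bins).
#' @return data.frame with columns `region` ("orf"/"utr3"), `bin`,
#'   `mean`, `se`, `n_genes`; attribute `n_genes` gives the number of
#'   genes contributing anywhere.
#' @export
metagene <- function(genes, track, orfBins = 100L, utrBp = 100L,
                     utrBins = 10L) {
  genes <- genes[mcols(genes)$kind == "orf"]
  if (!length(genes)) stop("no orf features to profile")
  pr <- probeCenters(track)
  ctr <- start(pr)
  chrom <- as.character(seqnames(pr))
  v <- trackValues(track)
  nb <- orfBins + utrBins
  prof <- matrix(NA_real_, length(genes), nb)
  for (i in seq_along(genes)) {
    g <- genes[i]
    minus <- as.character(strand(g)) == "-"
    on <- chrom == as.character(seqnames(g))
    w <- end(g) - start(g) + 1L
    inOrf <- on & ctr >= start(g) & ctr <= end(g)
    frac <- if (minus) (end(g) - ctr) / w else (ctr - start(g)) / w
    bin <- pmin(orfBins, floor(orfBins * frac) + 1L)
    inUtr <- if (minus) on & ctr >= start(g) - utrBp & ctr < start(g)
      else on & ctr > end(g) & ctr <= end(g) + utrBp
    off <- if (minus) start(g) - 1L - ctr else ctr - end(g) - 1L
    ubin <- orfBins + pmin(utrBins, floor(off / (utrBp / utrBins)) + 1L)
    allBin <- ifelse(inOrf, bin, ifelse(inUtr, ubin, NA))
    sel <- !is.na(allBin) & !is.na(v)
    if (!any(sel)) next
    agg <- tapply(v[sel], allBin[sel], mean)
    prof[i, as.integer(names(agg))] <- agg
  }
  n <- colSums(!is.na(prof))
  mu <- colMeans(prof, na.rm = TRUE)
  sd_ <- apply(prof, 2L, stats::sd, na.rm = TRUE)
  se <- ifelse(n > 1, sd_ / sqrt(n), NA_real_)
  out <- data.frame(
    region = rep(c("orf", "utr3"), c(orfBins, utrBins)),
    bin = c(seq_len(orfBins), seq_len(utrBins)),
    mean = ifelse(n > 0, mu, NA_real_), se = se, n_genes = n)
  attr(out, "n_genes") <- sum(rowSums(!is.na(prof)) > 0)
  out
}

#' Pairwise Pearson correlation of differential tracks
#'
#' Correlates per-probe log2 fold changes for every pair of strains,
#' dropping masked/missing positions pairwise (6 mutants give 15 unique
#' pairs). Also reports a banded grouping of the coefficients.
#'
#' @param tracks named list of [SignalTrack-class] objects sharing one
#'   probe map.
#' @param bands coefficient band edges for the grouping report.
#' @return symmetric correlation matrix with attribute `groups`, a
#'   data.frame of pairs sorted by decreasing coefficient with a band
#'   label.
#' @export
correlationMatrix <- function(tracks,
                              bands = c(-Inf, 0.2, 0.4, 0.6, Inf)) {
  k <- length(tracks)
  labs <- names(tracks)
  V <- vapply(tracks, trackValues, numeric(length(tracks[[1]])))
  M <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  diag(M) <- 1
  pairs <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- is.finite(V[, i]) & is.finite(V[, j])
    M[i, j] <- M[j, i] <- if (sum(ok) >= 2L)
      stats::cor(V[ok, i], V[ok, j]) else NA_real_
    pairs <- rbind(pairs, data.frame(a = labs[i], b = labs[j],
                                     r = M[i, j]))
  }
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs$r), ]
    pairs$band <- cut(pairs$r, bands)
    rownames(pairs) <- NULL
  }
  attr(M, "groups") <- pairs
  M
}

#' Detect "loop" segments in a pairwise differential scatter
#'
#' In a scatter of two strains' smoothed log2 fold changes, strongly
#' affected transcription units stand out as discrete excursions from
#' the central mass. Probes are flagged when the larger of their two
#' robust z-scores (|value - median| / (1.4826 MAD) per track) reaches
#' `zThreshold`; flagged probes closer than `mergeGap` are merged and
#' segments spanning at least `minSpan` bp are reported.
#'
#' @param trackA,trackB [SignalTrack-class] log2fc tracks on a common
#'   probe map (intended at 500-bp smoothing).
#' @param zThreshold robust z cut-off (default 4).
#' @param mergeGap maximum gap between flagged probes to merge (bp).
#' @param minSpan minimum reported segment span (bp).
#' @param features optional feature `GRanges` for annotation.
#' @return a sorted `GRanges` of disjoint segments with mean log2fc in
#'   each strain, the peak robust z, and overlapping feature ids.
#' @export
detectLoops <- function(trackA, trackB, zThreshold = 4, mergeGap = 250,
                        minSpan = 300, features = NULL) {
  robustZ <- function(v) {
    med <- stats::median(v, na.rm = TRUE)
    md <- stats::mad(v, na.rm = TRUE)       # includes the 1.4826 factor
    if (!is.finite(md) || md == 0) {
      warning("MAD is zero; falling back to standard deviation")
      md <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(md) || md == 0) return(rep(0, length(v)))
    }
    (v - med) / md
  }
  pr <- probeCenters(trackA)
  zA <- robustZ(trackValues(trackA))
  zB <- robustZ(trackValues(trackB))
  z <- pmax(abs(zA), abs(zB))
  flagged <- which(!is.na(z) & z >= zThreshold)
  if (!length(flagged))
    return(GRanges(score = numeric(), meanA = numeric(),
                   meanB = numeric(), features = character()))
  ch <- as.character(seqnames(pr))[flagged]
  pos <- start(pr)[flagged]
  newseg <- c(TRUE, ch[-1] != ch[-length(ch)] |
                diff(pos) > mergeGap)
  seg <- cumsum(newseg)
  out <- NULL
  for (s in unique(seg)) {
    ix <- flagged[seg == s]
    span <- max(start(pr)[ix]) - min(start(pr)[ix]) + 1L
    if (span < minSpan) next
    gr <- GRanges(ch[seg == s][1],
                  IRanges(min(start(pr)[ix]), max(start(pr)[ix])))
    inSeg <- ch[seg == s][1] == as.character(seqnames(pr)) &
      start(pr) >= GenomicRanges::start(gr) &
      start(pr) <= GenomicRanges::end(gr)
    gr$score <- max(z[ix])
    gr$meanA <- mean(trackValues(trackA)[inSeg], na.rm = TRUE)
    gr$meanB <- mean(trackValues(trackB)[inSeg], na.rm = TRUE)
    gr$features <- if (is.null(features)) NA_character_ else {
      ov <- GenomicRanges::findOverlaps(gr, features,
                                        ignore.strand = TRUE)
      paste(mcols(features)$id[S4Vectors::subjectHits(ov)],
            collapse = ",")
    }
    out <- if (is.null(out)) gr else c(out, gr)
  }
  if (is.null(out))
    return(GRanges(score = numeric(), meanA = numeric(),
                   meanB = numeric(), features = character()))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Gene-level average fold change
#'
#' The mean smoothed log2 fold change over all probes inside each ORF,
#' plus the untransformed fold `2^mean`.
#'
#' @param genes feature `GRanges` (orf rows are used).
#' @param track a log2fc [SignalTrack-class].
#' @return data.frame (gene_id, strain, n_probes, mean_log2fc, fold);
#'   genes without probes get NA.
#' @export
geneLevelChange <- function(genes, track) {
  genes <- genes[mcols(genes)$kind == "orf"]
  pr <- probeCenters(track)
  v <- trackValues(track)
  ov <- GenomicRanges::findOverlaps(pr, genes, ignore.strand = TRUE)
  means <- rep(NA_real_, length(genes))
  np <- integer(length(genes))
  sp <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  for (nm in names(sp)) {
    i <- as.integer(nm)
    vals <- v[sp[[nm]]]
    vals <- vals[!is.na(vals)]
    np[i] <- length(vals)
    if (length(vals)) means[i] <- mean(vals)
  }
  data.frame(gene_id = mcols(genes)$id, strain = trackStrain(track),
             n_probes = np, mean_log2fc = means, fold = 2^means,
             stringsAsFactors = FALSE)
}
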