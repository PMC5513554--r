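## Terminator readthrough quantification for sn/snoRNA genes: the ratio
## of downstream to gene-body transcript level, in percent, minus the
## matched wild-type value ("differential readthrough ratio"). A
## differential above 10 percentage points is called a termination
## defect; above 100 points the signal is likely confounded by
## unannotated overlapping transcripts.

## linear-scale transcript level from an RNA-level track
.linearValues <- function(track) {
  stopifnot(trackKind(track) == "rna_level")
  v <- trackValues(track)
  ifelse(!is.na(v) & v > 0, 2^v, ifelse(is.na(v), NA_real_, 0))
}

## strand-aware distance of probe centers past the mature 3' end
## (positive = downstream); the gene-body selector
.geneGeometry <- function(gene, probes) {
  stopifnot(length(gene) == 1L)
  me <- mcols(gene)$mature_end
  if (is.na(me)) stop("gene ", mcols(gene)$id, " has no mature_end")
  minus <- as.character(strand(gene)) == "-"
  onChrom <- as.character(seqnames(probes)) ==
    as.character(seqnames(gene))
  ctr <- start(probes)
  body <- onChrom & if (minus) ctr >= me & ctr <= end(gene)
    else ctr >= start(gene) & ctr <= me
  dist <- if (minus) me - ctr else ctr - me
  dist[!onChrom] <- NA_real_
  list(body = body, dist = dist)
}

#' Readthrough ratio of one sn/snoRNA gene
#'
#' Divides the average linear transcript level downstream of the mature
#' 3' end by that of the mature coding region and multiplies by 100.
#' The downstream region spans 10 to 310 bp past the mature end on the
#' transcribed strand. `window_rule = "mean_region"` (default) averages
#' the whole region; `"max50"` takes the maximum mean over all 50-bp
#' sub-windows fully inside it, stepped at the probe spacing.
#'
#' @param gene a single snr feature (GRanges row with `mature_end`).
#' @param track an RNA-level [SignalTrack-class] for one strain.
#' @param rule "mean_region" or "max50".
#' @param dsFrom,dsTo downstream region bounds in bp past the mature
#'   end (defaults 10 and 310, half-open).
#' @param subWindow sub-window width for "max50" (default 50 bp).
#' @return list with `ratio` (percent; NA when the body mean is zero or
#'   unavailable), `body_mean` and `downstream_mean`.
#' @export
readthroughRatio <- function(gene, track, rule = c("mean_region", "max50"),
                             dsFrom = 10, dsTo = 310, subWindow = 50) {
  rule <- match.arg(rule)
  geo <- .geneGeometry(gene, probeCenters(track))
  lin <- .linearValues(track)
  bodyVals <- lin[geo$body]
  bodyVals <- bodyVals[!is.na(bodyVals)]
  body <- if (length(bodyVals)) mean(bodyVals) else NA_real_
  inRegion <- !is.na(geo$dist) & geo$dist >= dsFrom & geo$dist < dsTo &
    !is.na(lin)
  down <- if (!any(inRegion)) NA_real_
  else if (rule == "mean_region") mean(lin[inRegion])
  else {
    d <- geo$dist[inRegion]; v <- lin[inRegion]
    step <- metadata(probeCenters(track))$spacing_hint
    if (is.null(step) || is.na(step)) step <- 5L
    starts <- seq(dsFrom, dsTo - subWindow, by = step)
    means <- vapply(starts, function(w) {
      s <- d >= w & d < w + subWindow
      if (any(s)) mean(v[s]) else NA_real_
    }, numeric(1))
    if (all(is.na(means))) NA_real_ else max(means, na.rm = TRUE)
  }
  ratio <- if (!is.na(body) && body > 0 && !is.na(down))
    100 * down / body else NA_real_
  list(ratio = ratio, body_mean = body, downstream_mean = down)
}

#' Differential readthrough of a gene in a mutant vs wild type
#'
#' The mutant's readthrough ratio minus the wild type's. Values below 10
#' points are classified `none` (insignificant readthrough), 10-100
#' `readthrough`, above 100 `confounded` (likely overlapping unannotated
#' transcripts). When the mutant's body signal drops below half the wild
#' type's, `body_decrease` notes that the apparent readthrough may stem
#' from diminished mature RNA rather than elevated downstream signal.
#'
#' @param gene a single snr feature.
#' @param mutTrack,wtTrack RNA-level tracks computed with the same rule.
#' @param rule see [readthroughRatio()].
#' @return one-row data.frame (gene_id, strain, body/downstream means,
#'   ratio, wt_ratio, differential, classification, body_decrease).
#' @export
differentialReadthrough <- function(gene, mutTrack, wtTrack,
                                    rule = c("mean_region", "max50")) {
  rule <- match.arg(rule)
  mu <- readthroughRatio(gene, mutTrack, rule)
  wt <- readthroughRatio(gene, wtTrack, rule)
  diff_ <- mu$ratio - wt$ratio
  cls <- if (is.na(mu$ratio) || is.na(wt$ratio)) "undefined"
  else if (diff_ > 100) "confounded"
  else if (diff_ >= 10) "readthrough"
  else "none"
  data.frame(
    gene_id = mcols(gene)$id, strain = trackStrain(mutTrack),
    body_mean = mu$body_mean, downstream_mean = mu$downstream_mean,
    ratio = mu$ratio, wt_ratio = wt$ratio, differential = diff_,
    classification = cls,
    body_decrease = !is.na(mu$body_mean) && !is.na(wt$body_mean) &&
      mu$body_mean < 0.5 * wt$body_mean,
    stringsAsFactors = FALSE)
}

#' Flag sn/snoRNA genes with confounding 3' neighbours
#'
#' A gene is excluded when any non-mask feature (other than itself)
#' overlaps its downstream `[mature_end, mature_end + slack)` region on
#' either strand, since such transcription units could contribute to the
#' downstream signal.
#'
#' @param genes snr feature `GRanges`.
#' @param allFeatures the full feature `GRanges` to test against.
#' @param slack downstream slack in bp (default 310).
#' @param forceInclude,forceExclude gene ids overriding the automatic
#'   call.
#' @return named logical vector: TRUE = excluded.
#' @export
flagConfoundedGenes <- function(genes, allFeatures, slack = 310,
                                forceInclude = character(),
                                forceExclude = character()) {
  others <- allFeatures[!mcols(allFeatures)$kind %in% "mask"]
  out <- vapply(seq_along(genes), function(i) {
    g <- genes[i]
    me <- mcols(g)$mature_end
    if (is.na(me)) return(TRUE)
    zone <- if (as.character(strand(g)) == "-")
      GRanges(seqnames(g), IRanges(max(1L, me - slack + 1L), me))
    else GRanges(seqnames(g), IRanges(me, me + slack - 1L))
    hits <- others[mcols(others)$id != mcols(g)$id]
    length(GenomicRanges::findOverlaps(zone, hits,
                                       ignore.strand = TRUE)) > 0L
  }, logical(1))
  names(out) <- mcols(genes)$id
  out[names(out) %in% forceInclude] <- FALSE
  out[names(out) %in% forceExclude] <- TRUE
  out
}

#' Differential readthrough table over a strain panel
#'
#' One record per retained sn/snoRNA gene and mutant strain. Genes with
#' confounding 3' neighbours (see [flagConfoundedGenes()]) are dropped
#' and reported in the `excluded` attribute.
#'
#' @param genes feature `GRanges` (snr rows are used).
#' @param tracks named list of RNA-level tracks, one per strain,
#'   including the wild type.
#' @param wtLabel wild-type strain label.
#' @param rule see [readthroughRatio()].
#' @param allFeatures optional full feature set for the adjacency
#'   filter; when NULL no gene is excluded.
#' @return long data.frame of [differentialReadthrough()] records with
#'   attribute `excluded` (character ids).
#' @export
readthroughTable <- function(genes, tracks, wtLabel,
                             rule = c("mean_region", "max50"),
                             allFeatures = NULL) {
  rule <- match.arg(rule)
  if (!wtLabel %in% names(tracks))
    stop("wild-type track '", wtLabel, "' missing")
  snr <- genes[mcols(genes)$kind == "snr"]
  excluded <- character()
  if (!is.null(allFeatures)) {
    flags <- flagConfoundedGenes(snr, allFeatures)
    excluded <- names(flags)[flags]
    snr <- snr[!flags]
  }
  mutants <- setdiff(names(tracks), wtLabel)
  recs <- lapply(seq_along(snr), function(i)
    do.call(rbind, lapply(mutants, function(st)
      differentialReadthrough(snr[i], tracks[[st]], tracks[[wtLabel]],
                              rule))))
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(gene_id = character(), strain = character(),
                      body_mean = numeric(), downstream_mean = numeric(),
                      ratio = numeric(), wt_ratio = numeric(),
                      differential = numeric(),
                      classification = character(),
                      body_decrease = logical())
  attr(out, "excluded") <- excluded
  out
}

#' Wide (genes x strains) view of a readthrough table
#'
#' @param tbl output of [readthroughTable()].
#' @param value column to spread (default "differential").
#' @return data.frame with one row per gene and one column per strain.
#' @export
readthroughWide <- function(tbl, value = "differential") {
  genes <- unique(tbl$gene_id)
  strains <- unique(tbl$strain)
  out <- data.frame(gene_id = genes)
  for (st in strains)
    out[[st]] <- tbl[[value]][match(paste(genes, st),
                                    paste(tbl$gene_id, tbl$strain))]
  out
}

#' Count termination-defective genes per strain
#'
#' Applies the >10-point rule: a gene counts as defective in a strain
#' when its differential readthrough ratio classifies as `readthrough`
#' or `confounded`.
#'
#' @param tbl output of [readthroughTable()].
#' @return named integer vector of per-strain counts.
#' @export
countDefectiveGenes <- function(tbl) {
  def <- tbl$classification %in% c("readthrough", "confounded")
  counts <- tapply(def, tbl$strain, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
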