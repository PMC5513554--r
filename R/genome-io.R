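#' @importFrom rtracklayer import export
#' @importFrom utils read.delim write.table
NULL

.FEATURE_KINDS <- c("orf", "snr", "cut", "polyA_cluster", "mask", "other")

## default mapping from GFF3/SGD type strings to internal feature kinds
.DEFAULT_KIND_MAP <- c(
  gene = "orf", ORF = "orf", CDS = "orf", mRNA = "orf",
  snoRNA_gene = "snr", snRNA_gene = "snr", snoRNA = "snr", snRNA = "snr",
  CUT = "cut", cut = "cut", ncRNA_gene = "cut",
  polyA_cluster = "polyA_cluster", polyA_site = "polyA_cluster",
  mask = "mask", repeat_region = "mask",
  orf = "orf", snr = "snr", other = "other")

#' Build a typed, stranded feature set
#'
#' A feature set is a `GRanges` with metadata columns `id` (unique),
#' `kind` (one of orf, snr, cut, polyA_cluster, mask, other) and
#' `mature_end` (for sn/snoRNA genes, the genome coordinate of the
#' 3'-most base of the mature RNA, strand-aware; NA otherwise).
#'
#' @param id character vector of unique feature ids.
#' @param kind feature kinds (recycled).
#' @param chrom,start,end 1-based inclusive genome coordinates.
#' @param strand "+", "-" or "*".
#' @param mature_end optional mature 3'-end coordinates (1-based).
#' @param ... further metadata columns.
#' @return a validated `GRanges`.
#' @export
featureSet <- function(id, kind, chrom, start, end, strand = "*",
                       mature_end = NA_integer_, ...) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$id <- id
  mcols(gr)$kind <- rep_len(kind, length(gr))
  mcols(gr)$mature_end <- rep_len(as.integer(mature_end), length(gr))
  extra <- list(...)
  for (nm in names(extra)) mcols(gr)[[nm]] <- extra[[nm]]
  names(gr) <- id
  validateFeatures(gr)
  gr
}

#' Validate a feature set
#'
#' Checks the invariants required of a feature `GRanges`: unique ids,
#' known kinds, stranded sn/snoRNA genes, and `mature_end` inside its
#' feature.
#'
#' @param gr a feature `GRanges`.
#' @return invisibly `gr`; errors describe the first violated invariant.
#' @export
validateFeatures <- function(gr) {
  m <- mcols(gr)
  if (is.null(m$id) || anyDuplicated(m$id))
    stop("features must carry unique 'id's")
  if (is.null(m$kind) || !all(m$kind %in% .FEATURE_KINDS))
    stop("unknown feature kind(s): ",
         paste(setdiff(unique(m$kind), .FEATURE_KINDS), collapse = ", "))
  snr <- which(m$kind == "snr")
  if (length(snr) && any(!as.character(strand(gr)[snr]) %in% c("+", "-")))
    stop("snr features must be on a definite strand")
  has_me <- which(!is.na(m$mature_end))
  if (length(has_me)) {
    bad <- m$mature_end[has_me] < start(gr)[has_me] |
      m$mature_end[has_me] > end(gr)[has_me]
    if (any(bad))
      stop("mature_end outside its feature for: ",
           paste(m$id[has_me][bad], collapse = ", "))
  }
  invisible(gr)
}

#' Read genome features from GFF3 or BED
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) coordinates are
#' normalized by rtracklayer to the common in-memory representation.
#' Feature kinds are inferred from the GFF3 `type` column through
#' `kindMap`; BED files carry no type, so `defaultKind` applies.
#'
#' @param path file path (gzip transparent).
#' @param format "gff3" or "bed".
#' @param kindMap named character vector mapping type strings to kinds.
#' @param defaultKind kind assigned when no mapping matches.
#' @return a feature `GRanges` (see [featureSet()]).
#' @export
readFeatures <- function(path, format = c("gff3", "bed"),
                         kindMap = .DEFAULT_KIND_MAP,
                         defaultKind = "other") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e)
                   stop("failed to parse ", path, " as ", format, ": ",
                        conditionMessage(e)))
  m <- mcols(gr)
  if (format == "gff3") {
    type <- as.character(m$type)
    kind <- unname(kindMap[type])
    kind[is.na(kind)] <- defaultKind
    id <- if (!is.null(m$ID)) as.character(m$ID) else NULL
    if (is.null(id) && !is.null(m$Name)) id <- as.character(m$Name)
    if (is.null(id)) id <- paste0("feat", seq_along(gr))
    id[is.na(id)] <- paste0("feat", which(is.na(id)))
    me <- if (!is.null(m$mature_end))
      as.integer(as.character(m$mature_end)) else NA_integer_
    base <- if (!is.null(m$baseline))
      as.numeric(as.character(m$baseline)) else NULL
  } else {
    id <- if (!is.null(m$name)) as.character(m$name)
      else paste0("feat", seq_along(gr))
    kind <- rep(defaultKind, length(gr))
    me <- NA_integer_
    base <- NULL
  }
  mcols(gr) <- NULL
  mcols(gr)$id <- id
  mcols(gr)$kind <- kind
  mcols(gr)$mature_end <- rep_len(as.integer(me), length(gr))
  if (!is.null(base)) mcols(gr)$baseline <- base
  names(gr) <- id
  validateFeatures(gr)
  gr
}

#' Write genome features to GFF3 or BED
#'
#' The inverse of [readFeatures()]: GFF3 output stores the kind in the
#' `type` column and `mature_end` as an attribute, so a write/read round
#' trip is lossless; BED6 output keeps intervals, names and strand only.
#'
#' @param gr a feature `GRanges`.
#' @param path output path.
#' @param format "gff3" or "bed".
#' @export
writeFeatures <- function(gr, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  validateFeatures(gr)
  if (format == "gff3") {
    out <- gr
    mcols(out) <- DataFrame(
      type = mcols(gr)$kind, ID = mcols(gr)$id,
      mature_end = ifelse(is.na(mcols(gr)$mature_end), NA,
                          as.character(mcols(gr)$mature_end)))
    if (!is.null(mcols(gr)$baseline))
      mcols(out)$baseline <- as.character(mcols(gr)$baseline)
    rtracklayer::export(out, path, format = "gff3")
  } else {
    out <- gr
    mcols(out) <- DataFrame(name = mcols(gr)$id, score = 0L)
    rtracklayer::export(out, path, format = "bed")
  }
  invisible(path)
}

#' Mask intervals from printed (possibly reversed) coordinates
#'
#' Builds kind-"mask" features from 1-based inclusive coordinate pairs.
#' Reversed bounds (start > end, as occur in printed genome coordinates)
#' are normalized with a warning.
#'
#' @param chrom chromosome names.
#' @param start,end 1-based inclusive bounds; reversed pairs are swapped.
#' @param id optional mask ids.
#' @return a feature `GRanges` of kind "mask".
#' @export
maskFeatures <- function(chrom, start, end, id = NULL) {
  rev <- which(start > end)
  if (length(rev)) {
    warning("normalizing ", length(rev), " reversed mask interval(s)")
    tmp <- start[rev]; start[rev] <- end[rev]; end[rev] <- tmp
  }
  if (is.null(id)) id <- paste0("mask", seq_along(chrom))
  featureSet(id = id, kind = "mask", chrom = chrom,
             start = start, end = end, strand = "*")
}

#' Build a probe map
#'
#' @param df data.frame with columns `probe_id`, `chrom`, `center`
#'   (1-based probe interrogation position).
#' @return a sorted `GRanges` of width-1 probe positions named by probe
#'   id, with the median inter-probe spacing stored in
#'   `metadata(x)$spacing_hint`.
#' @export
probeMap <- function(df) {
  if (anyDuplicated(df$probe_id)) stop("probe ids must be unique")
  gr <- GRanges(df$chrom, IRanges(df$center, width = 1L))
  names(gr) <- df$probe_id
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  d <- unlist(lapply(split(start(gr), as.character(seqnames(gr))), diff),
              use.names = FALSE)
  metadata(gr)$spacing_hint <-
    if (length(d)) as.integer(stats::median(d)) else NA_integer_
  gr
}

#' Read / write a probe map TSV
#'
#' Plain TSV with columns `probe_id`, `chrom`, `center` (gzip
#' transparent).
#'
#' @param path file path.
#' @return [readProbeMap()]: a probe `GRanges`; [writeProbeMap()]: the
#'   path, invisibly.
#' @export
readProbeMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "center")
  if (!all(need %in% colnames(df)))
    stop("probe map must have columns: ", paste(need, collapse = ", "))
  probeMap(df)
}

#' @rdname readProbeMap
#' @param probes a probe `GRanges`.
#' @export
writeProbeMap <- function(probes, path) {
  df <- data.frame(probe_id = names(probes),
                   chrom = as.character(seqnames(probes)),
                   center = start(probes))
  write.table(df, .maybeGz(path), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read PM/MM intensities aligned to a probe map
#'
#' The TSV must have a `probe_id` column plus paired `PM_<array>` /
#' `MM_<array>` columns. Rows are aligned to the probe-map order
#' regardless of file order; a missing or unknown probe id is an error.
#'
#' @param path TSV path (gzip transparent).
#' @param probes probe `GRanges` from [probeMap()].
#' @param strain,replicate optional per-array annotations; by default
#'   parsed from array labels of the form `<strain>_r<replicate>`.
#' @return a [TilingExperiment-class].
#' @export
readIntensities <- function(path, probes, strain = NULL, replicate = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"probe_id" %in% colnames(df)) stop("missing 'probe_id' column")
  pmCols <- grep("^PM_", colnames(df), value = TRUE)
  mmCols <- grep("^MM_", colnames(df), value = TRUE)
  arrays <- sub("^PM_", "", pmCols)
  if (!setequal(arrays, sub("^MM_", "", mmCols)))
    stop("PM_*/MM_* columns must pair up")
  mmCols <- paste0("MM_", arrays)
  unknown <- setdiff(df$probe_id, names(probes))
  if (length(unknown))
    stop("unknown probe id(s): ", paste(head(unknown, 3), collapse = ", "))
  idx <- match(names(probes), df$probe_id)
  if (anyNA(idx))
    stop("intensity file is missing probe(s): ",
         paste(head(names(probes)[is.na(idx)], 3), collapse = ", "))
  pmMat <- as.matrix(df[idx, pmCols, drop = FALSE])
  mmMat <- as.matrix(df[idx, mmCols, drop = FALSE])
  if (any(pmMat < 0) || any(mmMat < 0))
    stop("negative intensities are not allowed")
  if (is.null(strain)) strain <- sub("_r[0-9]+$", "", arrays)
  if (is.null(replicate)) {
    rep_ <- sub("^.*_r([0-9]+)$", "\\1", arrays)
    replicate <- suppressWarnings(as.integer(rep_))
    replicate[is.na(replicate)] <- 1L
  }
  TilingExperiment(probes, pmMat, mmMat, strain = strain,
                   replicate = replicate, arrayLabels = arrays)
}

#' Write PM/MM intensities to TSV
#'
#' @param exp a [TilingExperiment-class].
#' @param path output path (`.gz` suffix compresses).
#' @export
writeIntensities <- function(exp, path) {
  arrays <- colnames(exp)
  df <- data.frame(probe_id = names(probeCenters(exp)))
  p <- pm(exp); m <- mm(exp)
  for (a in arrays) {
    df[[paste0("PM_", a)]] <- p[, a]
    df[[paste0("MM_", a)]] <- m[, a]
  }
  write.table(df, .maybeGz(path), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a signal track to bedGraph or TSV
#'
#' bedGraph records are 0-based half-open intervals at probe centers;
#' runs of adjacent equal values are merged; probes with missing values
#' are omitted. The TSV format keeps all probes (`probe_id`, `chrom`,
#' `center`, `value`, with NA for masked probes).
#'
#' @param track a [SignalTrack-class].
#' @param path output path.
#' @param format "bedgraph" or "tsv".
#' @export
writeTrack <- function(track, path, format = c("bedgraph", "tsv")) {
  format <- match.arg(format)
  pr <- probeCenters(track)
  v <- trackValues(track)
  if (any(!is.finite(v) & !is.na(v)))
    stop("track values must be finite where present")
  if (format == "bedgraph") {
    keep <- !is.na(v)
    recs <- .mergeEqualRuns(pr[keep], v[keep])
    rtracklayer::export(recs, path, format = "bedGraph")
  } else {
    df <- data.frame(probe_id = names(pr),
                     chrom = as.character(seqnames(pr)),
                     center = start(pr),
                     value = ifelse(is.na(v), NA, sprintf("%.6f", v)))
    write.table(df, .maybeGz(path), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

## merge runs of probes with equal (rounded) values into single bedGraph
## records when the single-base intervals would otherwise be contiguous
.mergeEqualRuns <- function(pr, v) {
  if (!length(pr)) {
    gr <- GRanges()
    gr$score <- numeric()
    return(gr)
  }
  v <- round(v, 6)
  ch <- as.character(seqnames(pr))
  pos <- start(pr)
  newrun <- c(TRUE, ch[-1] != ch[-length(ch)] | diff(pos) != 1L |
                v[-1] != v[-length(v)])
  run <- cumsum(newrun)
  s <- tapply(pos, run, min); e <- tapply(pos, run, max)
  gr <- GRanges(ch[newrun], IRanges(as.integer(s), as.integer(e)))
  gr$score <- v[newrun]
  gr
}

#' Read a signal track written by [writeTrack()]
#'
#' @param path file path.
#' @param format "bedgraph" or "tsv".
#' @param probes probe `GRanges` to align values to (required for
#'   bedgraph; probes without a record get NA).
#' @param kind,windowBp,strain,baseline track metadata to restore.
#' @return a [SignalTrack-class].
#' @export
readTrack <- function(path, format = c("bedgraph", "tsv"), probes = NULL,
                      kind = "rna_level", windowBp = 101L,
                      strain = "NA", baseline = NA_character_) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    pr <- probeMap(df[, c("probe_id", "chrom", "center")])
    val <- as.numeric(df$value)[match(names(pr), df$probe_id)]
    return(SignalTrack(pr, val, kind, windowBp, strain, baseline))
  }
  if (is.null(probes)) stop("bedgraph tracks need a probe map to align to")
  gr <- rtracklayer::import(path, format = "bedGraph")
  ov <- GenomicRanges::findOverlaps(probes, gr, ignore.strand = TRUE)
  val <- rep(NA_real_, length(probes))
  val[S4Vectors::queryHits(ov)] <- gr$score[S4Vectors::subjectHits(ov)]
  SignalTrack(probes, val, kind, windowBp, strain, baseline)
}

#' Mask probes inside excluded regions
#'
#' Sets track values to NA at every probe whose center falls inside a
#' mask interval (e.g. plasmid-borne marker genes whose amplification
#' would distort the comparison). Masking is idempotent.
#'
#' @param track a [SignalTrack-class].
#' @param mask a feature `GRanges`; only kind == "mask" rows are used
#'   when a `kind` column is present, otherwise all intervals.
#' @return the masked [SignalTrack-class].
#' @export
maskTrack <- function(track, mask) {
  if (!is.null(mcols(mask)$kind)) mask <- mask[mcols(mask)$kind == "mask"]
  if (!length(mask)) return(track)
  ov <- GenomicRanges::findOverlaps(probeCenters(track), mask,
                                    ignore.strand = TRUE)
  v <- trackValues(track)
  v[unique(S4Vectors::queryHits(ov))] <- NA_real_
  methods::initialize(track, values = v)
}

.maybeGz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}
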