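#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
NULL

#' Container for tiled PM/MM probe intensities
#'
#' \code{TilingExperiment} extends
#' \linkS4class{RangedSummarizedExperiment}: rows are tiling probes
#' (width-1 ranges at the probe interrogation centers, one per probe),
#' columns are arrays, and the two assays \code{"pm"} and \code{"mm"}
#' hold perfect-match and mismatch intensities. \code{colData} carries
#' \code{strain} and \code{replicate} labels for every array.
#'
#' @slot .
#'   inherited from \code{RangedSummarizedExperiment}.
#' @seealso [TilingExperiment()], [pm()], [mm()], [probeCenters()]
#' @export
setClass("TilingExperiment",
  contains = "RangedSummarizedExperiment")

setValidity("TilingExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("pm", "mm") %in% an))
    msg <- c(msg, "assays 'pm' and 'mm' are required")
  else {
    p <- SummarizedExperiment::assay(object, "pm")
    m <- SummarizedExperiment::assay(object, "mm")
    if (!identical(dim(p), dim(m)))
      msg <- c(msg, "'pm' and 'mm' must have identical dimensions")
    if (any(p < 0, na.rm = TRUE) || any(m < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("strain", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'strain' and 'replicate'")
  if (any(width(SummarizedExperiment::rowRanges(object)) != 1L))
    msg <- c(msg, "probe ranges must have width 1 (interrogation centers)")
  if (anyDuplicated(names(SummarizedExperiment::rowRanges(object))))
    msg <- c(msg, "probe ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a TilingExperiment
#'
#' @param probes a `GRanges` of probe centers (width 1, named by probe id,
#'   sorted by chromosome then position), as returned by [probeMap()].
#' @param pm,mm numeric matrices of intensities, probes x arrays.
#' @param strain,replicate character/integer vectors, one entry per array.
#' @param arrayLabels optional array names; default `<strain>_r<replicate>`.
#' @return a [TilingExperiment-class] object.
#' @examples
#' pmap <- probeMap(data.frame(probe_id = c("p1", "p2"),
#'                             chrom = "chrI", center = c(5L, 10L)))
#' te <- TilingExperiment(pmap, pm = matrix(1:4, 2), mm = matrix(0, 2, 2),
#'                        strain = c("WT", "WT"), replicate = 1:2)
#' @export
TilingExperiment <- function(probes, pm, mm, strain, replicate,
                             arrayLabels = NULL) {
  pm <- as.matrix(pm); mm <- as.matrix(mm)
  if (nrow(pm) != length(probes))
    stop("intensity matrices must have one row per probe")
  if (is.null(arrayLabels))
    arrayLabels <- paste0(strain, "_r", replicate)
  rownames(pm) <- rownames(mm) <- NULL
  colnames(pm) <- colnames(mm) <- arrayLabels
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pm = pm, mm = mm),
    rowRanges = probes,
    colData = DataFrame(strain = strain, replicate = replicate,
                        row.names = arrayLabels))
  methods::new("TilingExperiment", se)
}

#' Per-probe genome signal track
#'
#' A \code{SignalTrack} holds one value per probe position: a smoothed RNA
#' level (\code{kind = "rna_level"}), a log2 fold change between a strain
#' and its matched wild type (\code{"log2fc"}), or a detection score
#' \eqn{-10 \log_{10} p} (\code{"detection_score"}). Values may be
#' \code{NA} where probes were masked.
#'
#' @slot probes GRanges of probe centers (width 1).
#' @slot values numeric, one value per probe; NA = missing/masked.
#' @slot kind one of "rna_level", "log2fc", "detection_score".
#' @slot windowBp odd positive integer, the smoothing window width.
#' @slot strain strain label the track describes.
#' @slot baseline control strain label (required for "log2fc").
#' @export
setClass("SignalTrack",
  representation(probes = "GRanges", values = "numeric", kind = "character",
                 windowBp = "integer", strain = "character",
                 baseline = "character"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@values) != length(object@probes))
    msg <- c(msg, "one value per probe required")
  if (!object@kind %in% c("rna_level", "log2fc", "detection_score"))
    msg <- c(msg, "invalid track kind")
  if (length(object@windowBp) != 1L || is.na(object@windowBp) ||
      object@windowBp < 1L || object@windowBp %% 2L == 0L)
    msg <- c(msg, "windowBp must be a single odd positive integer")
  if (object@kind == "log2fc" && is.na(object@baseline))
    msg <- c(msg, "log2fc tracks require a baseline strain")
  if (length(msg)) msg else TRUE
})

#' @rdname SignalTrack-class
#' @param probes,values,kind,windowBp,strain,baseline see slots.
#' @export
SignalTrack <- function(probes, values, kind, windowBp, strain,
                        baseline = NA_character_) {
  methods::new("SignalTrack", probes = probes, values = as.numeric(values),
               kind = kind, windowBp = as.integer(windowBp),
               strain = strain, baseline = as.character(baseline))
}

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack <", object@kind, "> strain=", object@strain,
      if (!is.na(object@baseline)) paste0(" vs ", object@baseline) else "",
      "\n  ", length(object@probes), " probes, window ", object@windowBp,
      " bp, ", sum(is.na(object@values)), " masked\n", sep = "")
})

#' @export
setMethod("length", "SignalTrack", function(x) length(x@probes))

#' Synthetic-array simulation configuration
#'
#' Describes a mock genome, probe layout, strain panel and the injected
#' per-feature, per-strain effects (fold change, terminator readthrough
#' fraction, attenuator release, 5'->3' elongation gradient) from which
#' [simulateArrays()] generates PM/MM intensity matrices with known truth.
#'
#' @slot seed integer RNG seed; a fixed seed gives byte-identical output.
#' @slot genome data.frame with columns `chrom`, `length`.
#' @slot probeSpacing probe center spacing in bp (default 5).
#' @slot nReplicates biological replicates per strain (default 2).
#' @slot background numeric(2): meanlog, sdlog of the lognormal additive
#'   background intensity (shared by both replicates of a strain).
#' @slot gain intensity units per abundance unit.
#' @slot noiseCv coefficient of variation of the multiplicative noise on
#'   the signal term, drawn independently per array.
#' @slot features GRanges feature set (see [featureSet()]) with extra
#'   columns `baseline`, `attenuator_offset`, `downstream_stop`, `tss`,
#'   `plant`.
#' @slot effects data.frame with columns `feature_id`, `strain`,
#'   `fold_change`, `readthrough_fraction`, `attenuator_release`,
#'   `elongation_slope` (one row per feature x strain).
#' @slot strains character vector of strain labels (wild type first).
#' @slot wtLabel the matched wild-type label.
#' @export
setClass("SimConfig",
  representation(seed = "integer", genome = "data.frame",
                 probeSpacing = "integer", nReplicates = "integer",
                 background = "numeric", gain = "numeric",
                 noiseCv = "numeric", features = "GRanges",
                 effects = "data.frame", strains = "character",
                 wtLabel = "character"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@probeSpacing < 1L) msg <- c(msg, "probeSpacing must be >= 1")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (length(object@background) != 2L)
    msg <- c(msg, "background must be c(meanlog, sdlog)")
  if (anyDuplicated(object@genome$chrom))
    msg <- c(msg, "duplicated chromosome names")
  if (!object@wtLabel %in% object@strains)
    msg <- c(msg, "wtLabel must be one of strains")
  ef <- object@effects
  if (nrow(ef)) {
    frac <- c(ef$readthrough_fraction, ef$attenuator_release)
    if (any(frac < 0 | frac > 1, na.rm = TRUE))
      msg <- c(msg, "fractions must lie in [0, 1]")
    if (any(ef$fold_change < 0, na.rm = TRUE))
      msg <- c(msg, "fold_change must be non-negative")
  }
  fx <- object@features
  if (length(fx)) {
    snr <- which(mcols(fx)$kind == "snr")
    ds <- mcols(fx)$downstream_stop[snr]
    me <- mcols(fx)$mature_end[snr]
    bad <- !is.na(ds) & !is.na(me) &
      ifelse(as.character(strand(fx)[snr]) == "-", ds >= me, ds <= me)
    if (any(bad))
      msg <- c(msg, "downstream_stop must lie 3' of mature_end")
    if (any(!as.character(strand(fx)[snr]) %in% c("+", "-")))
      msg <- c(msg, "snr features must be stranded")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", sum(object@genome$length), " bp genome (",
      nrow(object@genome), " chrom), ", length(object@features),
      " features, strains: ", paste(object@strains, collapse = ", "),
      "\n  spacing ", object@probeSpacing, " bp, ", object@nReplicates,
      " replicates, gain ", object@gain, ", noise CV ", object@noiseCv,
      ", seed ", object@seed, "\n", sep = "")
})
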