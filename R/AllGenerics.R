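#' Accessors for TilingExperiment and SignalTrack objects
#'
#' `pm()` / `mm()` return the perfect-match / mismatch intensity matrices;
#' `probeCenters()` the GRanges of probe interrogation centers;
#' `arraysOf()` the array labels of one strain; `trackValues()` /
#' `trackKind()` / `trackStrain()` / `trackBaseline()` / `windowBp()` the
#' corresponding SignalTrack slots.
#'
#' @param x a [TilingExperiment-class] or [SignalTrack-class] object.
#' @param strain a strain label.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pm", function(x) standardGeneric("pm"))
#' @rdname accessors
#' @export
setGeneric("mm", function(x) standardGeneric("mm"))
#' @rdname accessors
#' @export
setGeneric("probeCenters", function(x) standardGeneric("probeCenters"))
#' @rdname accessors
#' @export
setGeneric("arraysOf", function(x, strain) standardGeneric("arraysOf"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setGeneric("trackKind", function(x) standardGeneric("trackKind"))
#' @rdname accessors
#' @export
setGeneric("trackStrain", function(x) standardGeneric("trackStrain"))
#' @rdname accessors
#' @export
setGeneric("trackBaseline", function(x) standardGeneric("trackBaseline"))
#' @rdname accessors
#' @export
setGeneric("windowBp", function(x) standardGeneric("windowBp"))

#' @rdname accessors
setMethod("pm", "TilingExperiment", function(x)
  SummarizedExperiment::assay(x, "pm"))
#' @rdname accessors
setMethod("mm", "TilingExperiment", function(x)
  SummarizedExperiment::assay(x, "mm"))
#' @rdname accessors
setMethod("probeCenters", "TilingExperiment", function(x)
  SummarizedExperiment::rowRanges(x))
#' @rdname accessors
setMethod("probeCenters", "SignalTrack", function(x) x@probes)
#' @rdname accessors
setMethod("arraysOf", "TilingExperiment", function(x, strain) {
  lab <- rownames(SummarizedExperiment::colData(x))
  lab[SummarizedExperiment::colData(x)$strain %in% strain]
})
#' @rdname accessors
setMethod("trackValues", "SignalTrack", function(x) x@values)
#' @rdname accessors
setMethod("trackKind", "SignalTrack", function(x) x@kind)
#' @rdname accessors
setMethod("trackStrain", "SignalTrack", function(x) x@strain)
#' @rdname accessors
setMethod("trackBaseline", "SignalTrack", function(x) x@baseline)
#' @rdname accessors
setMethod("windowBp", "SignalTrack", function(x) x@windowBp)
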