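#' Quantile normalization across arrays
#'
#' Makes the value distributions of a group of arrays identical: each
#' array's PM and MM intensities are concatenated into one vector, every
#' value is replaced by the mean of the group's order statistics at that
#' value's rank, and tied values receive the mean of the tied ranks'
#' targets. Afterwards the sorted value multiset is the same on every
#' array in the group.
#'
#' @param exp a [TilingExperiment-class].
#' @param arrays array labels forming the normalization group (>= 2);
#'   default: all arrays.
#' @return the [TilingExperiment-class] with the group's PM/MM replaced;
#'   arrays outside the group are untouched.
#' @export
quantileNormalize <- function(exp, arrays = colnames(exp)) {
  if (length(arrays) < 2L)
    stop("quantile normalization needs at least 2 arrays")
  p <- pm(exp); m <- mm(exp)
  np <- nrow(p)
  X <- rbind(p[, arrays, drop = FALSE], m[, arrays, drop = FALSE])
  target <- rowMeans(apply(X, 2L, sort))
  Xn <- apply(X, 2L, function(x) {
    v <- target[rank(x, ties.method = "first")]
    stats::ave(v, factor(x), FUN = mean)   # mean of tied ranks' targets
  })
  p[, arrays] <- Xn[seq_len(np), , drop = FALSE]
  m[, arrays] <- Xn[np + seq_len(np), , drop = FALSE]
  SummarizedExperiment::assay(exp, "pm") <- p
  SummarizedExperiment::assay(exp, "mm") <- m
  exp
}

#' Linear scaling to a target median intensity
#'
#' Multiplies every PM and MM value of the group by
#' `target / median(pooled PM and MM values)`, so that the pooled median
#' afterwards equals `target` (100 by default, matching common tiling
#' array practice). Within-array ratios are preserved.
#'
#' @param exp a [TilingExperiment-class].
#' @param arrays array labels forming the scaling group.
#' @param target positive target median (default 100).
#' @return the rescaled [TilingExperiment-class].
#' @export
scaleToMedian <- function(exp, arrays = colnames(exp), target = 100) {
  stopifnot(target > 0)
  p <- pm(exp); m <- mm(exp)
  med <- stats::median(c(p[, arrays], m[, arrays]))
  if (!is.finite(med) || med <= 0)
    stop("pooled median must be positive (all-zero input?)")
  f <- target / med
  p[, arrays] <- p[, arrays] * f
  m[, arrays] <- m[, arrays] * f
  SummarizedExperiment::assay(exp, "pm") <- p
  SummarizedExperiment::assay(exp, "mm") <- m
  exp
}

#' Normalize one comparison group
#'
#' Convenience wrapper applying [quantileNormalize()] then
#' [scaleToMedian()] to the named arrays and returning the group subset
#' only. For RNA-level tracks the group is the replicate arrays of one
#' strain; for differential tracks it is the mutant (treatment) plus
#' matched wild-type (control) arrays normalized jointly.
#'
#' @param exp a [TilingExperiment-class].
#' @param arrays the group's array labels.
#' @param target target median (default 100).
#' @return the normalized, scaled [TilingExperiment-class] subset.
#' @export
normalizeGroup <- function(exp, arrays, target = 100) {
  sub <- exp[, arrays]
  sub <- quantileNormalize(sub, arrays)
  scaleToMedian(sub, arrays, target)
}

#' Normalize a treatment/control comparison
#'
#' Quantile-normalizes each strain's replicate arrays among themselves
#' and scales each strain's pooled PM/MM values to the common target
#' median. Cross-strain comparability therefore rests on the median
#' (dominated by non-specific background, effectively total RNA), not on
#' forcing identical value distributions — joint quantile normalization
#' of treatment and control would compress the very differential signal
#' being estimated.
#'
#' @param exp a [TilingExperiment-class].
#' @param treat,ctrl strain labels of the treatment and control groups.
#' @param target target median (default 100).
#' @return a [TilingExperiment-class] holding the treatment arrays
#'   followed by the control arrays, each group normalized and scaled.
#' @export
normalizeDifferential <- function(exp, treat, ctrl, target = 100) {
  a <- normalizeGroup(exp, arraysOf(exp, treat), target)
  b <- normalizeGroup(exp, arraysOf(exp, ctrl), target)
  SummarizedExperiment::cbind(a, b)
}
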