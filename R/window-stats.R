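## Sliding-window rank statistics: the tiling-array analysis core.
##
## Every probe position gets a window of +/- (width-1)/2 bp on its own
## chromosome; the PM-MM differences of all probes in the window, pooled
## over the group's arrays, feed a Wilcoxon signed-rank test (detection)
## and a Hodges-Lehmann pseudomedian (signal), or -- for two groups -- a
## Wilcoxon rank-sum test and the Hodges-Lehmann shift of the
## log2-transformed values (log2 fold change).

#' Round a window width up to the next odd integer
#'
#' @param width requested width in bp.
#' @return an odd integer >= 1; even inputs are bumped with a warning.
#' @export
adjustWindowWidth <- function(width) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("window width must be >= 1")
  if (width %% 2L == 0L) {
    warning("even window width ", width, " adjusted to ", width + 1L)
    width <- width + 1L
  }
  width
}

#' Hodges-Lehmann one-sample pseudomedian
#'
#' The median of all Walsh averages \eqn{(d_i + d_j)/2, i \le j}. A
#' robust location estimate for the window's PM-MM differences.
#'
#' @param d numeric vector.
#' @return the pseudomedian (NA for empty input).
#' @export
pseudomedian <- function(d) {
  n <- length(d)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(d)
  w <- outer(d, d, "+")[upper.tri(matrix(0, n, n), diag = TRUE)] / 2
  stats::median(w)
}

#' Hodges-Lehmann two-sample shift estimate
#'
#' The median of all pairwise differences `a_i - b_j`; applied to
#' log2-scale values it is read directly as a log2 fold change.
#'
#' @param a,b numeric vectors (treatment, control).
#' @return the shift estimate.
#' @export
hodgesLehmannShift <- function(a, b) {
  if (!length(a) || !length(b)) return(NA_real_)
  stats::median(as.vector(outer(a, b, "-")))
}

## ---- p-values ------------------------------------------------------------

.scoreOf <- function(p) -10 * log10(max(p, 1e-300))

## one-sided (greater) signed-rank p with Pratt zero handling and
## midranks; exact convolution for <= exactNMax informative values.
.signedRankP <- function(d, exactNMax = 25L) {
  r <- rank(abs(d))           # midranks, zeros included (Pratt)
  nz <- d != 0
  if (!any(nz)) return(1)
  rnz <- r[nz]
  W <- sum(rnz[d[nz] > 0])
  if (sum(nz) <= exactNMax) {
    r2 <- as.integer(round(2 * rnz))
    return(.exactSignedRankP(r2, as.integer(round(2 * W))))
  }
  mu <- sum(rnz) / 2
  sd_ <- sqrt(sum(rnz^2) / 4)
  if (sd_ == 0) return(1)
  min(1, stats::pnorm((W - mu - 0.5) / sd_, lower.tail = FALSE))
}

.exactSignedRankP <- function(r2, w2) {
  f <- 1
  for (t in r2) {
    g <- c(f, numeric(t))
    g[(t + 1L):length(g)] <- g[(t + 1L):length(g)] + f
    f <- g / 2
  }
  if (w2 <= 0) return(1)
  if (w2 + 1L > length(f)) return(0)
  sum(f[(w2 + 1L):length(f)])
}

## two-sided rank-sum p with midranks; exact distribution for pooled
## n <= exactNMax, else normal approximation with tie-corrected variance
## and continuity correction.
.rankSumP <- function(xt, xc, exactNMax = 25L) {
  n1 <- length(xt); n2 <- length(xc); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) return(1)
  r <- rank(c(xt, xc))
  W <- sum(r[seq_len(n1)])
  if (n <= exactNMax) {
    r2 <- as.integer(round(2 * r))
    return(.exactRankSumP(r2, n1, as.integer(round(2 * W))))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  corr <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - corr)
  if (v <= 0) return(1)
  z <- (abs(W - mu) - 0.5) / sqrt(v)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

.exactRankSumP <- function(r2, n1, w2) {
  S <- sum(r2); n <- length(r2)
  f <- matrix(0, n1 + 1L, S + 1L)
  f[1L, 1L] <- 1
  for (t in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      f[k + 1L, (t + 1L):(S + 1L)] <-
        f[k + 1L, (t + 1L):(S + 1L)] + f[k, 1L:(S - t + 1L)]
    }
  }
  dist <- f[n1 + 1L, ] / choose(n, n1)
  mu2 <- n1 * S / n
  dev <- abs(w2 - mu2)
  sum(dist[abs(seq(0L, S) - mu2) >= dev - 1e-9])
}

## ---- window primitives ---------------------------------------------------

#' Collect the probe values of one smoothing window
#'
#' Returns every PM-MM difference (`d`, linear scale) and its floored
#' log2 transform (`x = log2(max(d, 1))`) for probes on the center's
#' chromosome within `(width - 1)/2` bp of the center, over the named
#' arrays. Windows are truncated at chromosome ends; the center probe
#' always qualifies.
#'
#' @param exp a [TilingExperiment-class] (normalized).
#' @param chrom chromosome of the window center.
#' @param center window center (a probe position, 1-based).
#' @param windowBp odd window width in bp (default 101).
#' @param arrays array labels to pool (default: all).
#' @return list with components `d` and `x`.
#' @export
collectWindow <- function(exp, chrom, center, windowBp = 101L,
                          arrays = colnames(exp)) {
  windowBp <- adjustWindowWidth(windowBp)
  half <- (windowBp - 1L) %/% 2L
  pr <- probeCenters(exp)
  sel <- as.character(seqnames(pr)) == chrom &
    abs(start(pr) - center) <= half
  d <- as.vector(pm(exp)[sel, arrays, drop = FALSE] -
                 mm(exp)[sel, arrays, drop = FALSE])
  list(d = d, x = log2(pmax(d, 1)))
}

#' Signed-rank detection and Hodges-Lehmann signal for one window
#'
#' One-sample Wilcoxon signed-rank test of the window's PM-MM
#' differences against location zero (one-sided, positive; zeros handled
#' by Pratt's method, ties by midranks; exact null distribution up to
#' `exactNMax` informative values, otherwise normal approximation with
#' continuity correction). The signal location estimate `s` is the
#' pseudomedian of the differences; the RNA level is `log2(s)` when
#' `s > 1` and 0 otherwise.
#'
#' @param d numeric vector of PM-MM differences (linear scale).
#' @param exactNMax switch point between exact and approximate p.
#' @param detectOn apply the test to the linear differences
#'   (`"linear"`, default) or to their floored log2 transform
#'   (`"log2"`, the literal tiling-software reading, degenerate for
#'   non-negative data).
#' @return list with `detection_score` (-10 log10 p), `s`, `rna_level`
#'   and `p`.
#' @export
signedRankSignal <- function(d, exactNMax = 25L,
                             detectOn = c("linear", "log2")) {
  detectOn <- match.arg(detectOn)
  stopifnot(length(d) >= 1L)
  td <- if (detectOn == "linear") d else log2(pmax(d, 1))
  p <- .signedRankP(td, exactNMax)
  s <- pseudomedian(d)
  list(detection_score = .scoreOf(p), s = s,
       rna_level = if (is.finite(s) && s > 1) log2(s) else 0,
       p = p)
}

#' Rank-sum detection and Hodges-Lehmann log2 fold change for one window
#'
#' Two-sample Wilcoxon rank-sum test (two-sided, midranks) on the
#' floored log2 values of the treatment and control windows, and the
#' Hodges-Lehmann shift (median over all pairwise differences
#' `x_t - x_c`), interpreted directly as the log2 fold change.
#'
#' @param xt,xc numeric vectors of log2 window values for treatment and
#'   control (see [collectWindow()]'s `x`).
#' @param exactNMax switch point between exact and approximate p.
#' @return list with `detection_score`, `log2fc` and `p`.
#' @export
rankSumDifferential <- function(xt, xc, exactNMax = 25L) {
  stopifnot(length(xt) >= 1L, length(xc) >= 1L)
  p <- .rankSumP(xt, xc, exactNMax)
  list(detection_score = .scoreOf(p),
       log2fc = hodgesLehmannShift(xt, xc), p = p)
}

## ---- whole-genome tracks -------------------------------------------------

## lo/hi window bounds (indices) for sorted integer centers
.windowIndex <- function(centers, half) {
  lo <- findInterval(centers - half - 1L, centers) + 1L
  hi <- findInterval(centers + half, centers)
  cbind(lo, hi)
}

#' Compute signal and detection tracks over the whole genome
#'
#' Applies [signedRankSignal()] (RNA level, one strain's replicate
#' arrays) or [rankSumDifferential()] (log2 fold change, mutant vs
#' matched wild type) in a sliding window at every probe position.
#' Inputs are expected to be normalized and median-scaled, e.g. via
#' [normalizeGroup()].
#'
#' @param exp a normalized [TilingExperiment-class] containing the
#'   group's arrays.
#' @param strain strain label of the treatment group.
#' @param baseline control strain label; when given, differential
#'   (log2fc) tracks are computed, otherwise RNA-level tracks.
#' @param windowBp smoothing window width in bp (odd; default 101).
#' @param exactNMax exact-test switch point (default 25).
#' @param detectOn see [signedRankSignal()].
#' @return a list with elements `signal` (kind "rna_level" or "log2fc")
#'   and `detection` (kind "detection_score"), both
#'   [SignalTrack-class] objects.
#' @export
makeTracks <- function(exp, strain, baseline = NULL, windowBp = 101L,
                       exactNMax = 25L, detectOn = c("linear", "log2")) {
  detectOn <- match.arg(detectOn)
  windowBp <- adjustWindowWidth(windowBp)
  half <- (windowBp - 1L) %/% 2L
  pr <- probeCenters(exp)
  tCols <- arraysOf(exp, strain)
  if (!length(tCols)) stop("no arrays for strain ", strain)
  d <- pm(exp) - mm(exp)
  nP <- length(pr)
  sig <- numeric(nP); det <- numeric(nP)
  chrom <- as.character(seqnames(pr))
  if (is.null(baseline)) {
    dT <- d[, tCols, drop = FALSE]
    for (ch in unique(chrom)) {
      ix <- which(chrom == ch)
      win <- .windowIndex(start(pr)[ix], half)
      dch <- dT[ix, , drop = FALSE]
      for (k in seq_along(ix)) {
        v <- as.vector(dch[win[k, 1L]:win[k, 2L], ])
        td <- if (detectOn == "linear") v else log2(pmax(v, 1))
        p <- .signedRankP(td, exactNMax)
        s <- pseudomedian(v)
        sig[ix[k]] <- if (is.finite(s) && s > 1) log2(s) else 0
        det[ix[k]] <- .scoreOf(p)
      }
    }
    list(signal = SignalTrack(pr, sig, "rna_level", windowBp, strain),
         detection = SignalTrack(pr, det, "detection_score", windowBp,
                                 strain))
  } else {
    cCols <- arraysOf(exp, baseline)
    if (!length(cCols)) stop("no arrays for baseline ", baseline)
    x <- log2(pmax(d, 1))
    xT <- x[, tCols, drop = FALSE]
    xC <- x[, cCols, drop = FALSE]
    for (ch in unique(chrom)) {
      ix <- which(chrom == ch)
      win <- .windowIndex(start(pr)[ix], half)
      xTch <- xT[ix, , drop = FALSE]
      xCch <- xC[ix, , drop = FALSE]
      for (k in seq_along(ix)) {
        rows <- win[k, 1L]:win[k, 2L]
        vt <- as.vector(xTch[rows, ])
        vc <- as.vector(xCch[rows, ])
        sig[ix[k]] <- hodgesLehmannShift(vt, vc)
        det[ix[k]] <- .scoreOf(.rankSumP(vt, vc, exactNMax))
      }
    }
    list(signal = SignalTrack(pr, sig, "log2fc", windowBp, strain,
                              baseline),
         detection = SignalTrack(pr, det, "detection_score", windowBp,
                                 strain, baseline))
  }
}

#' Compute a single whole-genome track
#'
#' Thin wrapper around [makeTracks()] returning one
#' [SignalTrack-class] of the requested kind.
#'
#' @inheritParams makeTracks
#' @param mode "rna_level", "log2fc" or "detection_score".
#' @export
makeTrack <- function(exp, strain, mode = c("rna_level", "log2fc",
                                            "detection_score"),
                      baseline = NULL, windowBp = 101L, exactNMax = 25L,
                      detectOn = c("linear", "log2")) {
  mode <- match.arg(mode)
  if (mode == "log2fc" && is.null(baseline))
    stop("log2fc tracks require a baseline strain")
  tr <- makeTracks(exp, strain, baseline = baseline, windowBp = windowBp,
                   exactNMax = exactNMax, detectOn = detectOn)
  if (mode == "detection_score") tr$detection else tr$signal
}
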