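## Shared fixtures. The heavyweight objects (default-scenario simulation
## and its tracks, the null-scenario pipeline runs) are computed once per
## session and cached, since several test files and the acceptance suite
## reuse them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

MUTANTS <- c("sen1", "nrd1", "nab3", "ssu72", "rpb11", "hrp1")

getDefaultSim <- function() cached("sim", simulateArrays(defaultScenario(1)))

getRnaTracks <- function() cached("rna", {
  sim <- getDefaultSim()
  exp <- sim$experiment
  tracks <- lapply(c("WT", MUTANTS), function(st)
    makeTracks(normalizeGroup(exp, arraysOf(exp, st)), st,
               windowBp = 101)$signal)
  names(tracks) <- c("WT", MUTANTS)
  tracks
})

getFcTracks <- function() cached("fc", {
  sim <- getDefaultSim()
  exp <- sim$experiment
  tracks <- lapply(MUTANTS, function(mu) {
    tr <- makeTracks(normalizeDifferential(exp, mu, "WT"), mu,
                     baseline = "WT", windowBp = 101)
    list(signal = tr$signal, detection = tr$detection)
  })
  names(tracks) <- MUTANTS
  tracks
})

getNullRun <- function() cached("null", {
  sim <- simulateArrays(nullScenario(7))
  tr <- makeTracks(normalizeDifferential(sim$experiment, "mut", "WT"),
                   "mut", baseline = "WT", windowBp = 101)
  list(sim = sim, signal = tr$signal, detection = tr$detection)
})

## two identical pipeline runs on a small no-effect panel (smoke +
## determinism); computed once
getPipelineRuns <- function() cached("pipe", {
  sim <- simulateArrays(nullScenario(3))
  base <- file.path(tempdir(), "tileTerm-pipe")
  cfg1 <- list(simulation = sim, wt = "WT",
               outDir = file.path(base, "run1"))
  cfg2 <- list(simulation = sim, wt = "WT",
               outDir = file.path(base, "run2"))
  m1 <- suppressWarnings(runPipeline(cfg1))
  m2 <- suppressWarnings(runPipeline(cfg2))
  list(sim = sim, m1 = m1, m2 = m2, dir1 = cfg1$outDir,
       dir2 = cfg2$outDir)
})

## small hand-built experiment: probes every 5 bp on one chromosome
tinyExp <- function(pmVals, mmVals = NULL, strains = NULL,
                    chrom = "chrT", spacing = 5L) {
  pmVals <- as.matrix(pmVals)
  if (is.null(mmVals)) mmVals <- matrix(0, nrow(pmVals), ncol(pmVals))
  if (is.null(strains)) strains <- paste0("s", seq_len(ncol(pmVals)))
  centers <- seq(spacing, by = spacing, length.out = nrow(pmVals))
  pmap <- probeMap(data.frame(
    probe_id = sprintf("p%03d", seq_len(nrow(pmVals))),
    chrom = chrom, center = centers))
  TilingExperiment(pmap, pmVals, as.matrix(mmVals), strain = strains,
                   replicate = ave(seq_along(strains), strains,
                                   FUN = seq_along))
}

## a SignalTrack over evenly spaced probes with given values
tinyTrack <- function(values, chrom = "chrT", spacing = 5L,
                      kind = "rna_level", strain = "s",
                      baseline = if (kind == "log2fc") "WT"
                        else NA_character_, start1 = spacing) {
  centers <- seq(start1, by = spacing, length.out = length(values))
  pmap <- probeMap(data.frame(
    probe_id = sprintf("p%05d", seq_along(values)),
    chrom = chrom, center = centers))
  SignalTrack(pmap, values, kind, 101L, strain, baseline)
}

## independent enumeration oracles for the rank statistics
enumSignedRankP <- function(d) {
  r <- rank(abs(d))
  nz <- d != 0
  if (!any(nz)) return(1)
  rnz <- r[nz]
  W <- sum(rnz[d[nz] > 0])
  m <- sum(nz)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  Ws <- as.vector(signs %*% rnz)
  mean(Ws >= W - 1e-9)
}

enumRankSumP <- function(xt, xc) {
  n1 <- length(xt)
  r <- rank(c(xt, xc))
  n <- length(r)
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  subs <- utils::combn(n, n1)
  Ws <- colSums(matrix(r[subs], nrow = n1))
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}

bruteWalshMedian <- function(d) {
  w <- c()
  for (i in seq_along(d)) for (j in i:length(d))
    w <- c(w, (d[i] + d[j]) / 2)
  median(w)
}

brutePairwiseShift <- function(a, b) {
  diffs <- c()
  for (i in seq_along(a)) for (j in seq_along(b))
    diffs <- c(diffs, a[i] - b[j])
  median(diffs)
}
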