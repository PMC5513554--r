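## Synthetic tiling-array generator: a mock genome, Affymetrix-style
## PM/MM probe pairs at ~5-bp spacing, two biological replicates per
## strain, and per-feature injected effects (terminator readthrough,
## attenuator release, fold change, 5'->3' elongation gradients) with a
## ground-truth table, so every downstream statistic can be validated
## against known parameters.

#' @importFrom Biostrings DNAStringSet writeXStringSet
NULL

## evaluate code under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, fun) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fun()
}

#' Default per-feature, per-strain effect grid
#'
#' One row per (feature, strain) with neutral effects: fold change 1, no
#' readthrough, full attenuator release, no elongation gradient.
#' Scenario builders override individual cells.
#'
#' @param featureIds feature id vector.
#' @param strains strain label vector.
#' @return a data.frame effect grid.
#' @export
effectTable <- function(featureIds, strains) {
  g <- expand.grid(feature_id = featureIds, strain = strains,
                   stringsAsFactors = FALSE)
  g$fold_change <- 1
  g$readthrough_fraction <- 0
  g$attenuator_release <- 1
  g$elongation_slope <- 0
  g
}

.setEffect <- function(effects, id, strain, ...) {
  i <- effects$feature_id == id & effects$strain %in% strain
  if (!any(i)) stop("no effect row for ", id)
  vals <- list(...)
  for (nm in names(vals)) effects[[nm]][i] <- vals[[nm]]
  effects
}

#' Construct a simulation configuration
#'
#' @param seed integer RNG seed.
#' @param genome data.frame with columns `chrom`, `length`.
#' @param features feature `GRanges` carrying `baseline` (abundance
#'   units), and optionally `attenuator_offset` (bp from the transcript
#'   start), `downstream_stop` (genome coordinate bounding readthrough
#'   transcripts, standing in for the downstream poly(A) site), `tss`
#'   (transcript start coordinate when upstream of the ORF), `plant`
#'   (sequence-planting directive: "stss" or "utr_nab3").
#' @param effects effect grid (see [effectTable()]); missing
#'   (feature, strain) pairs get neutral defaults.
#' @param strains strain labels (wild type included).
#' @param wtLabel matched wild-type label.
#' @param probeSpacing probe spacing in bp (default 5).
#' @param nReplicates replicates per strain (default 2).
#' @param background c(meanlog, sdlog) of the lognormal background.
#' @param gain intensity units per abundance unit.
#' @param noiseCv coefficient of variation of the signal noise.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(seed, genome, features, effects, strains,
                      wtLabel = strains[1], probeSpacing = 5L,
                      nReplicates = 2L, background = c(log(60), 0.30),
                      gain = 200, noiseCv = 0.15) {
  for (col in c("baseline", "attenuator_offset", "downstream_stop",
                "tss", "plant")) {
    if (is.null(mcols(features)[[col]]))
      mcols(features)[[col]] <- if (col == "plant") NA_character_
        else NA_real_
  }
  mcols(features)$baseline[is.na(mcols(features)$baseline)] <- 0
  full <- effectTable(mcols(features)$id, strains)
  key <- paste(full$feature_id, full$strain)
  got <- paste(effects$feature_id, effects$strain)
  hit <- match(key, got)
  for (col in c("fold_change", "readthrough_fraction",
                "attenuator_release", "elongation_slope"))
    full[[col]][!is.na(hit)] <- effects[[col]][hit[!is.na(hit)]]
  methods::new("SimConfig", seed = as.integer(seed), genome = genome,
               probeSpacing = as.integer(probeSpacing),
               nReplicates = as.integer(nReplicates),
               background = as.numeric(background), gain = as.numeric(gain),
               noiseCv = as.numeric(noiseCv), features = features,
               effects = full, strains = strains, wtLabel = wtLabel)
}

#' Probe layout of a simulation configuration
#'
#' Probe interrogation centers tiled every `probeSpacing` bp along each
#' chromosome.
#'
#' @param config a [SimConfig-class].
#' @return a probe `GRanges` (see [probeMap()]).
#' @export
probeLayout <- function(config) {
  dfs <- lapply(seq_len(nrow(config@genome)), function(i) {
    ch <- config@genome$chrom[i]
    centers <- seq(config@probeSpacing, config@genome$length[i],
                   by = config@probeSpacing)
    data.frame(probe_id = sprintf("%s_p%06d", ch, seq_along(centers)),
               chrom = ch, center = centers)
  })
  probeMap(do.call(rbind, dfs))
}

#' Expected transcript abundance at every probe
#'
#' Evaluates the generator's abundance model directly (no sampling):
#' each feature contributes `baseline * fold_change` over its transcript,
#' truncated at the attenuator for the non-released fraction, extended
#' past the mature 3' end for the readthrough fraction, and tapered
#' 5'->3' by the elongation gradient
#' `max(0, 1 - slope * dist5p / 1000)`.
#'
#' @param config a [SimConfig-class].
#' @param strain strain label.
#' @param probes optional probe `GRanges` (default [probeLayout()]).
#' @return numeric abundance per probe.
#' @export
expectedAbundance <- function(config, strain, probes = probeLayout(config)) {
  ctr <- start(probes)
  chrom <- as.character(seqnames(probes))
  Tvec <- numeric(length(probes))
  fx <- config@features
  m <- mcols(fx)
  ef <- config@effects[config@effects$strain == strain, ]
  ef <- ef[match(m$id, ef$feature_id), ]
  for (i in seq_along(fx)) {
    kind <- m$kind[i]
    if (kind %in% c("mask", "polyA_cluster")) next
    B <- m$baseline[i] * ef$fold_change[i]
    f <- ef$readthrough_fraction[i]
    if (B == 0) next
    ch <- as.character(seqnames(fx))[i]
    minus <- as.character(strand(fx))[i] == "-"
    if (kind == "snr") {
      me <- m$mature_end[i]
      ds <- m$downstream_stop[i]
      if (minus) {
        txStart <- end(fx)[i]
        lo <- if (f > 0 && !is.na(ds)) ds else me
        hi <- txStart
      } else {
        txStart <- start(fx)[i]
        lo <- txStart
        hi <- if (f > 0 && !is.na(ds)) ds else me
      }
      sel <- which(chrom == ch & ctr >= lo & ctr <= hi)
      if (!length(sel)) next
      dist <- if (minus) txStart - ctr[sel] else ctr[sel] - txStart
      inBody <- if (minus) ctr[sel] >= me else ctr[sel] <= me
      cov <- B * ifelse(inBody, 1, f)
    } else {
      tss <- m$tss[i]
      if (minus) {
        txStart <- if (!is.na(tss)) tss else end(fx)[i]
        lo <- start(fx)[i]; hi <- txStart
      } else {
        txStart <- if (!is.na(tss)) tss else start(fx)[i]
        lo <- txStart; hi <- end(fx)[i]
      }
      sel <- which(chrom == ch & ctr >= lo & ctr <= hi)
      if (!length(sel)) next
      dist <- if (minus) txStart - ctr[sel] else ctr[sel] - txStart
      att <- m$attenuator_offset[i]
      rel <- ef$attenuator_release[i]
      cov <- if (!is.na(att)) B * ifelse(dist < att, 1, rel)
        else rep(B, length(sel))
    }
    lam <- ef$elongation_slope[i]
    if (lam != 0) cov <- cov * pmax(0, 1 - lam * dist / 1000)
    Tvec[sel] <- Tvec[sel] + cov
  }
  Tvec
}

## ---- genome sequence with planted regulatory elements --------------------

.BASES <- c("A", "C", "G", "T")

.findTriplet <- function(s, from, to, trip) {
  i <- from:(to - 2L)
  i[s[i] == trip[1] & s[i + 1L] == trip[2] & s[i + 2L] == trip[3]]
}

.matchConsensus <- function(str, pattern) {
  m <- gregexpr(pattern, str, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

## remove ATG triplets in [from, to] of the sense strand, never touching
## protected positions (planted motifs); C replacements cannot create
## new ATG or TATA-box matches.
.scrubATG <- function(s, from, to, protect = integer(0)) {
  repeat {
    hits <- .findTriplet(s, from, to, c("A", "T", "G"))
    hits <- hits[!(hits %in% protect & (hits + 2L) %in% protect)]
    if (!length(hits)) break
    for (h in hits) {
      cand <- c(h + 2L, h, h + 1L)
      j <- cand[!cand %in% protect][1]
      if (is.na(j)) next
      s[j] <- "C"
    }
  }
  s
}

.plantMotif <- function(s, at, motif) {
  mv <- strsplit(motif, "")[[1]]
  s[at:(at + length(mv) - 1L)] <- mv
  s
}

## keep exactly one TATA-box consensus match (the planted one) in a window
.dedupTATA <- function(s, from, to, keepAt, protect) {
  pat <- "TATA[AT]A[AT][AG]"
  repeat {
    str <- paste(s[from:to], collapse = "")
    hits <- .matchConsensus(str, pat) + from - 1L
    hits <- hits[hits != keepAt]
    if (!length(hits)) break
    for (h in hits) {
      pos <- (h:(h + 7L))
      j <- pos[!pos %in% protect][1]
      if (is.na(j)) break
      s[j] <- "C"
    }
  }
  s
}

.plantFeatures <- function(seqs, features) {
  m <- mcols(features)
  for (i in seq_along(features)) {
    ch <- as.character(seqnames(features))[i]
    if (!ch %in% names(seqs)) next
    s <- seqs[[ch]]
    if (m$kind[i] == "orf" && as.character(strand(features))[i] == "+") {
      os <- start(features)[i]
      if (os + 2L <= length(s)) s <- .plantMotif(s, os, "ATG")
    }
    plant <- m$plant[i]
    if (!is.na(plant)) {
      if (as.character(strand(features))[i] != "+")
        stop("sequence planting implemented for + strand features only")
      os <- start(features)[i]
      from <- os - 420L; to <- os - 1L
      if (from < 1L) stop("no room to plant upstream of ", m$id[i])
      if (plant == "stss") {
        tata <- os - 300L
        nab3 <- os - 160L
        nrd1 <- os - 150L
        protect <- c(tata:(tata + 7L), nab3:(nab3 + 3L), nrd1:(nrd1 + 3L))
        s <- .plantMotif(s, tata, "TATAAATA")
        s <- .plantMotif(s, nab3, "TCTT")
        s <- .plantMotif(s, nrd1, "GTAA")
        s <- .dedupTATA(s, from, to, tata, protect)
        s <- .scrubATG(s, from, to, protect)
      } else if (plant == "utr_nab3") {
        nab3 <- os - 100L
        protect <- nab3:(nab3 + 3L)
        s <- .plantMotif(s, nab3, "TCTT")
        s <- .scrubATG(s, from, to, protect)
      }
    }
    seqs[[ch]] <- s
  }
  seqs
}

## ---- the sampler ---------------------------------------------------------

#' Simulate a strain panel of tiling arrays
#'
#' Draws, under the configuration's seed, (1) a random genome sequence
#' with regulatory elements planted per feature directives, (2) one pair
#' of lognormal additive background vectors per array (each replicate is
#' an independent hybridization), and (3) one multiplicative noise
#' vector per array. Then
#' `PM = background_pm + max(0, gain * T * (1 + noiseCv * z))` and
#' `MM = background_mm`, where `T` is [expectedAbundance()]. The same
#' seed yields bitwise-identical output.
#'
#' @param config a [SimConfig-class].
#' @return a `TilingSimulation`: a list with elements `config`,
#'   `features`, `probes`, `experiment` ([TilingExperiment-class] of
#'   all arrays), `truth` (ground-truth effect table with realized
#'   `net_fold` per feature x strain), and `genome` (`DNAStringSet`).
#' @export
simulateArrays <- function(config) {
  methods::validObject(config)
  probes <- probeLayout(config)
  P <- length(probes)
  strains <- config@strains
  nr <- config@nReplicates
  Tmat <- vapply(strains, function(st)
    expectedAbundance(config, st, probes), numeric(P))
  out <- .withSeed(config@seed, function() {
    seqs <- lapply(seq_len(nrow(config@genome)), function(i)
      sample(.BASES, config@genome$length[i], replace = TRUE))
    names(seqs) <- config@genome$chrom
    nArr <- length(strains) * nr
    bg <- lapply(seq_len(nArr), function(i)
      list(mm = stats::rlnorm(P, config@background[1], config@background[2]),
           pm = stats::rlnorm(P, config@background[1], config@background[2])))
    eps <- lapply(seq_len(nArr), function(i) stats::rnorm(P))
    list(seqs = seqs, bg = bg, eps = eps)
  })
  seqs <- .plantFeatures(out$seqs, config@features)
  genome <- DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  arrays <- expand.grid(replicate = seq_len(nr), strain = strains,
                        stringsAsFactors = FALSE)[, c("strain", "replicate")]
  pmMat <- matrix(0, P, nrow(arrays))
  mmMat <- matrix(0, P, nrow(arrays))
  for (a in seq_len(nrow(arrays))) {
    st <- arrays$strain[a]
    signal <- pmax(0, config@gain * Tmat[, st] *
                     (1 + config@noiseCv * out$eps[[a]]))
    pmMat[, a] <- out$bg[[a]]$pm + signal
    mmMat[, a] <- out$bg[[a]]$mm
  }
  exp <- TilingExperiment(probes, pmMat, mmMat, strain = arrays$strain,
                          replicate = arrays$replicate)
  truth <- .truthTable(config, probes, Tmat)
  structure(list(config = config, features = config@features,
                 probes = probes, experiment = exp, truth = truth,
                 genome = genome),
            class = "TilingSimulation")
}

#' @export
print.TilingSimulation <- function(x, ...) {
  cat("TilingSimulation: ", length(x$probes), " probes x ",
      ncol(x$experiment), " arrays (",
      paste(x$config@strains, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

## ground truth: injected parameters plus the realized net fold change
## over each feature (geometric mean abundance ratio vs wild type)
.truthTable <- function(config, probes, Tmat) {
  truth <- config@effects
  truth$net_fold <- NA_real_
  fx <- config@features
  m <- mcols(fx)
  ctr <- start(probes)
  chrom <- as.character(seqnames(probes))
  wt <- Tmat[, config@wtLabel]
  for (i in seq_along(fx)) {
    if (m$kind[i] %in% c("mask", "polyA_cluster")) next
    sel <- which(chrom == as.character(seqnames(fx))[i] &
                   ctr >= start(fx)[i] & ctr <= end(fx)[i])
    sel <- sel[wt[sel] > 0]
    if (!length(sel)) next
    for (st in config@strains) {
      r <- Tmat[sel, st] / wt[sel]
      r <- r[is.finite(r) & r > 0]
      if (!length(r)) next
      truth$net_fold[truth$feature_id == m$id[i] &
                       truth$strain == st] <- 2^mean(log2(r))
    }
  }
  truth
}

#' Write simulation outputs to standard formats
#'
#' Emits `genome.fa`, `features.gff3`, `probes.tsv`, `intensities.tsv`,
#' `truth.tsv` and `config.json` under `dir`.
#'
#' @param sim a `TilingSimulation` from [simulateArrays()].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  writeFeatures(sim$features, file.path(dir, "features.gff3"), "gff3")
  writeProbeMap(sim$probes, file.path(dir, "probes.tsv"))
  writeIntensities(sim$experiment, file.path(dir, "intensities.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  jsonlite::write_json(list(
    seed = cfg@seed, genome = cfg@genome, probeSpacing = cfg@probeSpacing,
    nReplicates = cfg@nReplicates, background = cfg@background,
    gain = cfg@gain, noiseCv = cfg@noiseCv, strains = cfg@strains,
    wtLabel = cfg@wtLabel),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
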