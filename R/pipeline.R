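## End-to-end orchestration: normalize -> tracks -> mask -> readthrough
## -> metagene -> correlation -> loops -> gene table -> screens, with a
## manifest of outputs and checksums. Reruns under an identical
## configuration and inputs are byte-identical.

.ALL_STAGES <- c("tracks", "readthrough", "metagene", "correlate",
                 "loops", "genes", "screens")

#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (or a JSON file readable with
#' `jsonlite`) with elements:
#' \describe{
#'  \item{simulation}{a `TilingSimulation` (in-memory input), OR}
#'  \item{input}{list of paths: `probeMap`, `intensities`, `features`
#'    (GFF3), `genome` (FASTA, optional unless screens run), `masks`
#'    (GFF3/BED, optional).}
#'  \item{wt}{named character: matched wild-type label per mutant, or a
#'    single unnamed label used for all mutants.}
#'  \item{mutants}{mutant strain labels (default: every non-wild-type
#'    strain).}
#'  \item{windowBp, loopWindowBp}{smoothing windows (101 / 500; even
#'    values are auto-adjusted up with a recorded warning).}
#'  \item{rule}{readthrough window rule (default "mean_region").}
#'  \item{stages}{subset of tracks, readthrough, metagene, correlate,
#'    loops, genes, screens.}
#'  \item{loopPair}{the two strains scattered against each other.}
#'  \item{outDir}{output directory.}
#' }
#'
#' @param config a run configuration list.
#' @return character vector of problems (empty when runnable); the
#'   adjusted configuration is attached as attribute `config`.
#' @export
validateConfig <- function(config) {
  problems <- character()
  if (is.null(config$outDir)) problems <- c(problems, "outDir missing")
  if (is.null(config$simulation) && is.null(config$input))
    problems <- c(problems, "either 'simulation' or 'input' required")
  if (!is.null(config$input)) {
    for (f in c("probeMap", "intensities", "features")) {
      if (is.null(config$input[[f]]))
        problems <- c(problems, paste0("input$", f, " missing"))
      else if (!file.exists(config$input[[f]]))
        problems <- c(problems, paste0("input$", f, ": no such file"))
    }
  }
  strains <- .configStrains(config)
  if (!is.null(strains)) {
    wt <- config$wt
    if (is.null(wt)) problems <- c(problems, "wt mapping missing")
    else {
      mutants <- config$mutants
      if (is.null(mutants))
        mutants <- setdiff(strains, unname(wt))
      if (is.null(names(wt)) && length(wt) == 1L)
        wt <- stats::setNames(rep(wt, length(mutants)), mutants)
      missing_ <- setdiff(mutants, names(wt))
      if (length(missing_))
        problems <- c(problems,
                      paste0("mutant without wt mapping: ",
                             paste(missing_, collapse = ", ")))
      bad <- setdiff(unique(unname(wt)), strains)
      if (length(bad))
        problems <- c(problems, paste0("unknown wt strain: ",
                                       paste(bad, collapse = ", ")))
      config$wt <- wt
      config$mutants <- mutants
    }
  }
  for (f in c("windowBp", "loopWindowBp")) {
    w <- config[[f]]
    if (!is.null(w) && w %% 2L == 0L) {
      config[[f]] <- w + 1L
      config$warnings <- c(config$warnings,
                           paste0(f, " adjusted from ", w, " to ", w + 1L))
    }
  }
  if (!is.null(config$stages)) {
    bad <- setdiff(config$stages, .ALL_STAGES)
    if (length(bad))
      problems <- c(problems,
                    paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  attr(problems, "config") <- config
  problems
}

.configStrains <- function(config) {
  if (!is.null(config$simulation))
    config$simulation$config@strains
  else config$strains
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and writes every artifact under
#' `outDir`: per-strain RNA-level and per-mutant log2 fold-change tracks
#' (bedGraph + TSV, masked), the differential readthrough table (long
#' and wide), per-mutant metagene profiles, the pairwise correlation
#' matrix, loop segments for the configured strain pair, gene-level fold
#' changes with threshold lists, and the attenuator/upstream-bias
#' screens. A `manifest.tsv` lists every output with its MD5 checksum
#' (inputs included). Identical configuration and inputs give
#' byte-identical manifests.
#'
#' @param config see [validateConfig()].
#' @return invisibly, a data.frame manifest (file, md5, stage).
#' @export
runPipeline <- function(config) {
  problems <- validateConfig(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  config <- attr(problems, "config")
  stages <- config$stages
  if (is.null(stages)) stages <- .ALL_STAGES
  windowBp <- config$windowBp
  if (is.null(windowBp)) windowBp <- 101L
  loopBp <- config$loopWindowBp
  if (is.null(loopBp)) loopBp <- 501L
  rule <- if (is.null(config$rule)) "mean_region" else config$rule
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(), md5 = character(),
                         stage = character(), stringsAsFactors = FALSE)
  note <- function(path, stage) {
    manifest[nrow(manifest) + 1L, ] <<-
      list(basename(path), unname(tools::md5sum(path)), stage)
  }
  stage <- "load"
  result <- tryCatch({
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      inDir <- file.path(outDir, "inputs")
      writeSimulation(sim, inDir)
      for (f in list.files(inDir, full.names = TRUE)) note(f, "input")
      exp <- sim$experiment; features <- sim$features
      genome <- sim$genome; probes <- sim$probes
    } else {
      probes <- readProbeMap(config$input$probeMap)
      exp <- readIntensities(config$input$intensities, probes)
      features <- readFeatures(config$input$features, "gff3")
      genome <- if (!is.null(config$input$genome))
        Biostrings::readDNAStringSet(config$input$genome) else NULL
      if (!is.null(genome)) names(genome) <- sub(" .*", "", names(genome))
      for (f in unlist(config$input)) note(f, "input")
    }
    masks <- features[mcols(features)$kind == "mask"]
    strains <- unique(SummarizedExperiment::colData(exp)$strain)
    mutants <- config$mutants
    wtMap <- config$wt

    rnaTracks <- list(); fcTracks <- list(); detTracks <- list()
    if ("tracks" %in% stages) {
      stage <- "tracks"
      for (st in strains) {
        sub <- normalizeGroup(exp, arraysOf(exp, st))
        tr <- makeTracks(sub, st, windowBp = windowBp)
        rnaTracks[[st]] <- maskTrack(tr$signal, masks)
        writeTrack(rnaTracks[[st]],
                   file.path(outDir, paste0("rna_", st, ".bedgraph")))
        writeTrack(rnaTracks[[st]],
                   file.path(outDir, paste0("rna_", st, ".tsv")), "tsv")
      }
      for (mu in mutants) {
        wt <- wtMap[[mu]]
        sub <- normalizeDifferential(exp, mu, wt)
        tr <- makeTracks(sub, mu, baseline = wt, windowBp = windowBp)
        fcTracks[[mu]] <- maskTrack(tr$signal, masks)
        detTracks[[mu]] <- maskTrack(tr$detection, masks)
        writeTrack(fcTracks[[mu]],
                   file.path(outDir, paste0("log2fc_", mu, ".bedgraph")))
        writeTrack(fcTracks[[mu]],
                   file.path(outDir, paste0("log2fc_", mu, ".tsv")), "tsv")
      }
      for (f in list.files(outDir, pattern = "\\.(bedgraph|tsv)$",
                           full.names = TRUE))
        if (grepl("^(rna|log2fc)_", basename(f))) note(f, "tracks")
    }

    if ("readthrough" %in% stages) {
      stage <- "readthrough"
      tbl <- readthroughTable(features, rnaTracks,
                              wtLabel = unname(wtMap[1]), rule = rule,
                              allFeatures = features)
      p1 <- file.path(outDir, "readthrough_long.tsv")
      write.table(tbl, p1, sep = "\t", quote = FALSE, row.names = FALSE)
      p2 <- file.path(outDir, "readthrough_wide.tsv")
      write.table(readthroughWide(tbl), p2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      note(p1, stage); note(p2, stage)
    }

    if ("metagene" %in% stages) {
      stage <- "metagene"
      mg <- do.call(rbind, lapply(mutants, function(mu) {
        d <- metagene(features, fcTracks[[mu]])
        d$strain <- mu
        d
      }))
      p <- file.path(outDir, "metagene.tsv")
      write.table(mg, p, sep = "\t", quote = FALSE, row.names = FALSE)
      note(p, stage)
    }

    if ("correlate" %in% stages) {
      stage <- "correlate"
      M <- correlationMatrix(fcTracks)
      p <- file.path(outDir, "correlation.tsv")
      write.table(round(M, 6), p, sep = "\t", quote = FALSE)
      note(p, stage)
    }

    if ("loops" %in% stages) {
      stage <- "loops"
      pair <- config$loopPair
      if (is.null(pair)) pair <- mutants[seq_len(min(2L, length(mutants)))]
      pair <- rep(pair, length.out = 2L)
      lt <- lapply(unique(pair), function(mu) {
        wt <- wtMap[[mu]]
        sub <- normalizeDifferential(exp, mu, wt)
        maskTrack(makeTrack(sub, mu, "log2fc", baseline = wt,
                            windowBp = loopBp), masks)
      })
      names(lt) <- unique(pair)
      loops <- detectLoops(lt[[pair[1]]], lt[[pair[2]]],
                           features = features)
      p <- file.path(outDir, "loops.tsv")
      df <- if (length(loops))
        data.frame(chrom = as.character(seqnames(loops)),
                   start = start(loops), end = end(loops),
                   peak_z = round(loops$score, 4),
                   mean_a = round(loops$meanA, 4),
                   mean_b = round(loops$meanB, 4),
                   features = loops$features)
      else data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_z = numeric(),
                      mean_a = numeric(), mean_b = numeric(),
                      features = character())
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      note(p, stage)
      pb <- file.path(outDir, "loops.bed")
      if (length(loops)) {
        bed <- loops
        mcols(bed) <- DataFrame(
          name = sprintf("loop%02d", seq_along(loops)),
          score = round(pmin(loops$score, 1000), 2))
        rtracklayer::export(bed, pb, format = "bed")
      } else file.create(pb)
      note(pb, stage)
    }

    geneTab <- NULL
    if ("genes" %in% stages || "screens" %in% stages) {
      stage <- "genes"
      geneTab <- do.call(rbind, lapply(mutants, function(mu)
        geneLevelChange(features, fcTracks[[mu]])))
      if ("genes" %in% stages) {
        p <- file.path(outDir, "gene_changes.tsv")
        write.table(geneTab, p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        note(p, stage)
        up <- do.call(rbind, lapply(mutants, function(mu) {
          ids <- thresholdGeneList(geneTab, mu, minFold = 2)
          if (length(ids)) data.frame(strain = mu, gene_id = ids)
          else NULL
        }))
        p <- file.path(outDir, "genes_2fold.tsv")
        if (is.null(up)) up <- data.frame(strain = character(),
                                          gene_id = character())
        write.table(up, p, sep = "\t", quote = FALSE, row.names = FALSE)
        note(p, stage)
      }
    }

    if ("screens" %in% stages) {
      stage <- "screens"
      if (is.null(genome))
        stop("screens need a genome sequence")
      att <- screenAttenuators(features, geneTab, genome,
                               polyA = features, features = features)
      p <- file.path(outDir, "attenuator_screen.tsv")
      write.table(att, p, sep = "\t", quote = FALSE, row.names = FALSE)
      note(p, stage)
      bias <- do.call(rbind, lapply(mutants, function(mu) {
        b <- upstreamBias(features, fcTracks[[mu]])
        b$strain <- mu
        b
      }))
      p <- file.path(outDir, "upstream_bias.tsv")
      write.table(bias, p, sep = "\t", quote = FALSE, row.names = FALSE)
      note(p, stage)
    }
    manifest
  }, error = function(e) {
    pm <- file.path(outDir, "manifest.partial.tsv")
    write.table(manifest, pm, sep = "\t", quote = FALSE,
                row.names = FALSE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial manifest at ", pm, ")", call. = FALSE)
  })
  mp <- file.path(outDir, "manifest.tsv")
  write.table(result, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(result)
}
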