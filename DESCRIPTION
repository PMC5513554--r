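Package: tileTerm
Title: Tiling-Microarray Analysis of Transcription Termination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sliding-window rank-statistic analysis of Affymetrix-style
    PM/MM genome-tiling microarrays, aimed at dissecting RNA polymerase II
    transcription termination in budding yeast mutant panels. Provides
    quantile normalization and median scaling, Wilcoxon signed-rank /
    rank-sum detection tracks with Hodges-Lehmann signal and log2
    fold-change estimates, sn/snoRNA terminator-readthrough ratios and
    classification, metagene profiles, pairwise track correlation,
    scatter-loop segment detection, rule-based screens for attenuated and
    upstream-biased (meiotic-style) genes, and a fully parameterised
    synthetic-array generator with ground-truth effect tables for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
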