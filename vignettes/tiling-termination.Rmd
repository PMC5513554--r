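---
title: "Sliding-window rank statistics for tiling-array termination analysis"
author: "tileTerm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window rank statistics for tiling-array termination analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Budding yeast terminates most short RNA polymerase II transcripts —
sn/snoRNAs, cryptic unstable transcripts (CUTs), and attenuated mRNAs —
through the Sen1-dependent (NNS) pathway, in which the helicase Sen1 and
the RNA-binding proteins Nrd1 and Nab3 dislodge the polymerase shortly
after the gene body. A panel of conditional mutants in this pathway
(sen1, nrd1, nab3, ssu72, rpb11, hrp1), hybridized to high-density
PM/MM genome-tiling microarrays against matched wild types, lets one ask
*which terminators depend on which factor*. `tileTerm` implements the
complete computational side of such an experiment: probe-level
normalization, sliding-window rank-statistic tracks, terminator
readthrough quantification, metagene and correlation analytics, and
rule-based screens for attenuated and upstream-derepressed genes —
together with a synthetic-array generator whose injected effects give
every stage a ground truth.

## The statistical core

Arrays carry paired perfect-match (PM) and mismatch (MM) probes tiled at
roughly 5-bp spacing; MM intensities estimate per-probe non-specific
background, so the per-probe signal is the difference
`d_i = PM_i - MM_i`. All downstream statistics are windowed: for every
interrogated position, all probes within a 101-bp window (in base pairs,
truncated at chromosome ends, never wrapped) are pooled across the
group's arrays.

**RNA level.** Within each window the one-sample Wilcoxon signed-rank
test (one-sided, positive; Pratt's treatment of zeros; midranks for
ties) gives a detection score `-10 log10 p`, and the Hodges–Lehmann
pseudomedian *s* — the median of all Walsh averages `(d_i + d_j)/2,
i <= j` — estimates the signal location. The reported RNA level is
`log2(s)` when `s > 1` and 0 otherwise.

**Differential level.** For a mutant against its matched wild type, the
floored log2 values `x_i = log2(max(d_i, 1))` of the two groups' windows
enter a two-sample Wilcoxon rank-sum test (two-sided, midranks), and the
Hodges–Lehmann shift — the median of all pairwise differences
`x_t - x_c` — is read directly as the smoothed log2 fold change.

Exact null distributions are used up to 25 informative values per test
(computed by convolution over doubled midranks, so ties and zeros are
handled exactly); beyond that a normal approximation with tie-corrected
variance and continuity correction takes over. The switch point, the
window width, and the exact-vs-approximate boundary are all arguments.

One reading ambiguity is worth recording: the tiling-software
description applies the signed-rank test to the *log-transformed*
values, which are non-negative by construction and make a test against
location zero degenerate, while its floor rule ("if the estimate *s* of
signal location is over 1, transform to log2(s)") only makes sense on
the linear scale. We therefore test the linear differences by default
and keep the literal behaviour behind `detectOn = "log2"`.

## Normalization

Replicate arrays of one strain are quantile-normalized among themselves
(PM and MM concatenated into one vector per array; tied values receive
the mean of the tied ranks' targets) and then linearly scaled so the
pooled PM+MM median is 100. For differential tracks the treatment and
control pairs are each normalized *within strain* and scaled to the
common median; they are deliberately **not** quantile-normalized
jointly, because forcing identical value distributions onto treatment
and control erases exactly the differential signal being estimated
(we measured the compression directly: an injected log2 fold change of
1.5 came back as ~0.85 under joint normalization). Because the pooled
median is dominated by non-specific background — mostly Pol I/III
transcripts in total cellular RNA — median scaling amounts to
normalizing to total RNA, which is what makes net genome-wide shifts
in Pol II output visible at all.

## Terminator readthrough

For an sn/snoRNA gene with an annotated mature 3' end, the readthrough
ratio is

```
ratio = 100 * mean(linear level, 10..310 bp past the mature end)
            / mean(linear level, mature coding region)
```

on the transcribed strand, with linear level `2^rna_level` (0 where the
floor rule assigned 0). The *differential* readthrough ratio subtracts
the matched wild-type value; above 10 percentage points we call a
termination defect, above 100 the signal is likely confounded by
unannotated overlapping transcripts. Genes with annotated transcription
units within 310 bp of their 3' ends are excluded up front.

Two aggregation rules are provided for the downstream region.
`mean_region` (the default) averages the whole 10–310 bp stretch;
`max50` scans all 50-bp sub-windows and takes the best. We default to
`mean_region` because the 101-bp smoothing window smears gene-body
signal across the first ~50 bp downstream of the mature end, and a
maximizing rule always parks itself on that contaminated boundary: on
noiseless synthetic data `max50` reports ~13.6 + 86.4·f percent for an
injected readthrough fraction f (single strain), whereas `mean_region`
dilutes the boundary six-fold and recovers ~100·f within a couple of
points. Differencing against wild type cancels most of the boundary
term for either rule, but the single-strain ratios are only honest under
`mean_region`.

## Profiles, correlations, loops, screens

* **Metagene**: probes map to 100 percent-distance bins along each ORF
  (strand-aware) plus ten 10-bp bins over the first 100 bp past the stop
  codon as a 3'-UTR surrogate; per-gene bin means are averaged across
  genes with equal weight so long genes do not dominate.
* **Correlation**: Pearson correlation of two mutants' smoothed log2
  fold changes over all mutually finite probe positions, reported for
  all pairs with a banded grouping.
* **Loops**: in a scatter of two strains' 500-bp-smoothed fold changes,
  strongly affected transcription units appear as discrete excursions.
  We flag probes whose larger robust z-score
  (`|value - median| / (1.4826 MAD)`, falling back to the standard
  deviation when the MAD vanishes) reaches 4, merge flagged probes
  within 250 bp, and report segments spanning at least 300 bp. These
  defaults isolate visually loop-like excursions; all are arguments,
  since the original analysis used an unpublished script.
* **Attenuation screen**: candidate genes (fold >= 2 in at least one
  strain) are tested for an ATG-free nontemplate strand across the
  5'-UTR scan region (350 bp upstream of the start codon, or the
  annotated TSS when present), Nab3/Nrd1 consensus matches on the
  transcript strand (defaults UCUU and GUAR — the literature consensi,
  configurable as IUPAC strings), a TATA box (TATAWAWR) 200–400 bp
  upstream, and a premature poly(A) cluster in the UTR. The pass rule is
  a transparent conjunction (fold AND ATG-free AND (motif OR poly(A)
  cluster)) with every component reported, so users can re-weight; the
  mode hint separates single-TATA/single-start attenuation (ST-SS),
  regulation by an independent overlapping upstream transcript (DT-DS,
  flagged by a CUT in the UTR), and the remaining dual-start cases.
* **Upstream bias**: ORFs are split at the midpoint in transcription
  direction; genes whose upstream half rises by >= 1.0 (log2) with an
  upstream-minus-downstream bias >= 0.5 are flagged, the signature of a
  derepressed upstream (e.g. meiosis-specific) start site.

## The synthetic world

`defaultScenario()` states a ~200-kb, two-chromosome genome tiled at
5-bp spacing, seven strains (wild type plus the six mutants), and two
replicates per strain. Transcript abundance at a position is the sum of
feature contributions `baseline * fold_change`, truncated at an
attenuator for the non-released fraction, extended past the mature 3'
end for the readthrough fraction f, and tapered 5'→3' by
`max(0, 1 - slope * dist/1000)`. Arrays are then
`MM = B_mm` and `PM = B_pm + max(0, gain * T * (1 + cv * z))`, with
`B_pm`, `B_mm` independent lognormal(log 60, 0.3) background draws per
array, gain 200 intensity units per abundance unit, and a 15% noise
coefficient of variation — values typical of the platform (background
median ~60 with ~30% spread; well-expressed genes one order of
magnitude above background). Each replicate gets its own background
draw: sharing one draw across replicates would duplicate every PM-MM
value across a strain's arrays and break the independence the rank
tests assume (we measured the null false-positive rate inflating from
5% to ~12% with shared draws).

Two modelling simplifications matter for interpreting green tests: MM
probes carry background only (no probe-sequence-specific
cross-hybridization), and noise is multiplicative on the signal term
only. Injected effects therefore come back essentially unbiased, which
real probe-affinity structure would not guarantee.

The mock genome is deliberately *not* mostly silent: neutral
"background transcription" units tile the gaps between designed
features at log-spaced baselines (0.3–6). Rank-based normalization
presumes a mostly unchanged intensity distribution, and a genome where
only the affected genes are expressed would misrepresent how the method
behaves on real, pervasively transcribed chromatin.

Designed features include sn/snoRNA genes with per-strain readthrough
fractions spanning 0–0.6 (the sen1-like strain broadest, nrd1/nab3
overlapping, rpb11 mostly private — mirroring the biology the pipeline
is meant to resolve), a Pol III-like negative control, a gene with a
readthrough-confounding CUT 50 bp downstream, an exact log2 fold change
of 1.5, an elongation-gradient ("sawtooth") gene, a meiotic-style gene
whose upstream half derepresses, and a planted ST-SS attenuator (ATG-free
350-bp 5'-UTR, single TATA box, Nab3/Nrd1 sites, upstream poly(A)
cluster, 3-fold release in the sen1-like strain). The ground-truth
table carries both the injected parameters and the realized net fold
per feature and strain (computed from the abundance model itself), so
threshold-recovery tests compare against what was actually injected.

`nullScenario()` is a 60-kb no-effect panel used for calibration: the
differential detection score should cross the p < 0.05 line at ~5% of
positions and the metagene should be flat. One reading note: "flat
within 2 SE in every bin" is statistically self-defeating with 110 bins
(~5 bins are expected outside by chance), so the calibration check
asserts the nominal rate (at most 10% of bins outside 2 SE) and a grand
mean indistinguishable from zero. The calibration and determinism
checks run on this smaller scenario because a false-positive *rate* and
byte-identity of reruns are size-independent properties; recovery
checks run on the full default scenario.

## Numerical and degenerate-input choices

* Windows are defined in base pairs, truncated at chromosome ends; the
  centre probe always qualifies, so windows are never empty.
* An all-zero window yields p = 1, score 0, RNA level 0.
* Reversed interval bounds in input coordinates (which occur in
  published genome coordinates) are normalized with a warning.
* Readthrough ratios with a zero body mean are recorded as undefined,
  never thrown.
* bedGraph output merges runs of adjacent equal-valued single-base
  records and omits masked probes; TSV output keeps all probes with NA.
* The pipeline writes a manifest of MD5 checksums (inputs included);
  reruns under identical configuration and inputs are byte-identical.

## Limitations

Real CEL/BPMAP parsing, probe-sequence hybridization models, FDR
control on detection scores, GO enrichment, and browser visualization
are out of scope; tracks are exported as bedGraph for any genome
browser. Published headline numbers that depend on the original raw
arrays (pairwise correlation coefficients, per-gene fold tables) are
not reproducible without those arrays; the package's validation surface
is parameter recovery on the synthetic world described above.
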