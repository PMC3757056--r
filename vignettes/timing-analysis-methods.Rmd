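---
title: "Methods: comparing the timing of transcriptional and H3K27me3 change"
author: "epiTempo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing the timing of transcriptional and H3K27me3 change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiTempo)
```

# The question and the design

H3K27me3 is a repressive mark deposited by PRC2. Whether a
signal-induced change in this mark causes, or merely records, a change in
transcription cannot be decided from end-point correlation: both
hypotheses predict that repressed genes gain the mark. Sampling both
signals along a time course separates them, because a cause must move
first. `epiTempo` operationalizes this comparison for a design with a
small number of sampled days (by default 0, 2, 4, 7 and 12 after signal
onset), per-gene expression values (FPKM), and binned genome-wide ChIP
coverage per day.

The pipeline (`runPipeline()`) is: quantify → differential → intersect →
cluster → t-half → report. Each stage is also exported as a standalone
function operating on files or in-memory objects, so the stages compose in
scripts exactly as they do inside the pipeline; this function surface is
the package's command-line story, with `readPipelineConfig()` /
`writePipelineConfig()` handling the flat key=value configuration format.

# Coordinates and quantification

All interval arithmetic is 0-based half-open (BED native; GTF converted on
read); the `GRanges` containers used for storage are converted at exactly
one boundary (`readGeneModels()` and the writers). The gene body is the
full TSS-to-TTS span, introns included. The TSS window is ±2.5 kb around
the strand-aware TSS. Flanks for metagene profiles are one gene length on
either side, strand-oriented (upstream means 5′ of the TSS); this
orientation is the natural reading of upstream/downstream segment labels
and is the package's choice where the convention is genuinely open.
Flanks and windows are clipped at chromosome bounds; a window entirely off
the chromosome is an error, a clipped-away flank yields missing profile
positions rather than zeros (zero-filling would bias edge genes toward
apparent depletion; missing positions are excluded pairwise from profile
statistics).

Coverage is held in fixed-width bins (`SignalTrack`), 1 kb by default —
the resolution at which broad H3K27me3 domains are typically quantified —
and configurable. A region mean is the overlap-length-weighted mean of the
bins a region touches, which equals the per-base mean of the
piecewise-constant coverage; partial edge bins count fractionally. The
unit tests hold this equal to a brute-force per-base oracle to 1e-9.

Metagene profiles resample a track onto 200 points per segment (600 per
gene). Each normalized position takes the length-weighted mean of the
coverage over its genomic span — an interval average, not a point sample.
The alternative (assigning each bin to the nearest normalized position)
loses mass for genes shorter than 200 bins and double-counts for longer
ones; interval averaging is exact in both regimes and is what the
per-base oracle verifies.

# Normalization and smoothing

Tracks from libraries of different depths are rescaled to a common
effective total (`normalizeLibrary()`, `normalizeLibraries()`), the
equal-read-count convention. One property of this convention is worth
stating: if the genome-wide mass of the mark genuinely grows over the
time course, equalizing totals redistributes part of that growth into an
apparent global scale change, slightly compressing per-gene fold changes
and shifting apparent transition times earlier. At genome scale the
changed fraction is tiny and the effect negligible; on the compact
synthetic genome used here it is visible (a few percent on the recovered
H3K27me3 medians) and is accepted as faithful behavior of the method
rather than corrected away.

`lowessSmooth()` applies `stats::lowess` along bin indices per
chromosome, span 0.01 of the chromosome's bins by default — wide enough to
denoise, narrow enough to preserve domains of tens of kilobases — with
negative fitted values floored at zero. Chromosomes with fewer than three
bins are returned unchanged with a warning.

Expression tables can be rescaled so a reference transcript (e.g. *Arbp*)
is constant across samples (`normalizeExpressionToReference()`), the
standard qPCR-style anchor for comparing RNA levels across conditions.

# Differential calling and the joint set

Fold change per gene and day is `(v_t + c) / (v_0 + c)` with pseudocount
`c = 0.5` signal units (counts per bin). The pseudocount exists only to
make zero-baseline genes well-defined; at the default depth of 30
counts/bin it is negligible for any measured gene. A gene is
differentially methylated when any post-baseline day shows a two-sided
≥2-fold change; the criterion is deliberately two-sided because both
gains and losses of the mark are biologically expected, and it is monotone
in the threshold (a property the tests check). Differential expression is
an input: real analyses supply an externally derived gene list, and the
built-in caller (`simpleExpressionChangeCaller()`: max/min FPKM ratio ≥ 2
with peak FPKM ≥ 1) exists so synthetic runs need no external tool. The
joint regulated set is the plain intersection, with the counts needed for
a Venn summary.

# Clustering

Spatial (600-point) or temporal (per-day region means) profiles are
z-scored per gene — clustering should group shapes, not absolute levels;
flat rows cannot be z-scored and are dropped with a message — and
clustered with Euclidean distance and Ward linkage (`ward.D2`), cut into
k = 3 groups. Metric, linkage and k are configurable; Euclidean/Ward is
the standard choice for shape clustering of normalized profiles, and
nothing downstream depends on exact dendrogram identity — recovery is
always judged against known labels or by cluster-level summaries.
`hclust` is deterministic for fixed input; ties are resolved by its
documented merge order.

# The t-half statistic

For values `v` at days `t_1 < … < t_n`, the midpoint is
`m = (v_1 + v_n)/2` and t-half is the time of the first crossing of `m`,
linearly interpolated within the bracketing segment. Choices a user should
know:

* **First versus last crossing.** Monotone series cross once; for noisy,
  non-monotone series the first crossing is the default (earliest time at
  which half the net change has been reached), with `crossing = "last"`
  available.
* **Exact hits.** A sampled value equal to `m` returns that sampled day
  uninterpolated.
* **Flat series.** When the total relative change
  `|v_n − v_1| / max(|v_1|, 1e-8)` is below 1% the series is flagged
  `flat` and excluded from medians — t-half is only meaningful for genes
  that actually change, and the pipeline computes it on the jointly
  regulated set where flat series are rare by construction.
* **Invariance.** The crossing time is invariant under affine transforms
  of the values; the flatness guard, being relative, is not, so strict
  invariance checks disable it.

Cohort summaries are medians over valid results (even counts average the
central pair), and `compareTiming()` reports per-gene
`t_half(me3) − t_half(expr)`, its median, and the fraction of genes with
the chromatin change later. Cluster-level timing can be taken either as
the median of per-gene values (the default reported here) or by running
`tHalf()` on a cluster-averaged profile; both modes are available because
the choice is genuinely open — medians are robust to outlier genes,
averaged profiles match what a dashed line through a mean time course
shows.

Linear interpolation on a coarse day grid biases t-half slightly toward
the center of the bracketing segment: a logistic transition with midpoint
1.1 d sampled at days 0 and 2 crosses its sampled midpoint at ≈1.3 d.
This is a property of the statistic itself, shared by any analysis that
interpolates the same sampled days, and is well inside the ±0.5 d
recovery band the tests enforce.

# Intergenic candidate transcripts

`intergenicMask()` is the complement of the union of gene bodies.
`scanCandidates()` flags maximal runs (≥2 bins) of intergenic bins where
H3K27me3 differs ≥2-fold between two conditions *and* a strand-specific
RNA signal does too, with local signal above 5 counts/bin to keep
noise-floor ratios out. The joint H3K27me3+RNA requirement is the default
because a candidate unannotated transcript is defined by both observations
coinciding; `evidence = "me3"` or `"rna"` relax it. All thresholds are
package decisions — there is no established numeric convention for this
screen — and they are validated by recovery/false-positive measurements on
planted domains rather than by appeal to a reference. Nearest-gene
annotation breaks distance ties toward the gene downstream of the
candidate in its dominant-strand orientation, so an upstream antisense
candidate is attributed to the gene it points at.

# The synthetic cohort

The generator exists to give every stage a ground truth. Its defaults are
the study conditions the package is designed around: 200 genes — 60 broad
gene-body H3K27me3 gains with expression repression, 40 broad losses with
induction, 20 TSS-focal gains (Gaussian bump, sd 1 kb) with repression,
80 unchanged — plus 10 intergenic differential domains (3–6 bins) with
strand-specific unannotated transcription. All transitions are logistic in
time with steepness 1.5/day: the canonical monotone saturating change,
matching how signal-induced transitions are usually drawn and leaving the
half-transition time well-defined. Expression midpoints are 1.1 d
(repression) and 3.3 d (induction); H3K27me3 midpoints 6.9 d (gain) and
4.8 d (loss) — so transcription leads chromatin by construction, and
recovery tests are anchored to those values. Counts are Poisson at a
background depth of 30/bin with 4-fold effects, placing the ≥2-fold
caller comfortably above the noise floor at 1-kb bins; FPKM noise is
multiplicative lognormal (sd 0.1). Gene lengths are log-uniform 2–50 kb
with uniform 2–20 kb gaps on two 8-Mb chromosomes — a genic fraction of
roughly 20%, chosen so genome-wide totals are background-dominated and
equal-read normalization behaves as it does at genome scale.

What the generator does *not* emulate: mappability and GC bias,
fragment-size effects, input-chromatin structure, isoform complexity,
replicate variability, and autocorrelated biological noise. Passing
recovery tests therefore demonstrates that the implementation measures
what it claims on data whose generative structure matches the model's
assumptions — not that those assumptions hold for any given real dataset.

# Problem sizes and determinism

The shipped tests and the acceptance script run the default 200-gene
cohort (two 8-Mb chromosomes, 16,000 bins, five days) plus smaller
cohorts for unit-level checks; a full run takes seconds on one CPU, and
all randomness flows from a single integer seed per simulation
(regenerating a fixture bundle with the same seed reproduces every file
byte for byte). Oracle comparisons (per-base region means and metagene
resampling) are exact to 1e-9; WIG/bedGraph round-trips to 1e-6.

# Known limitations

* Library normalization supports equal-total scaling only; no
  input-chromatin correction is applied (an explicit subtraction/ratio
  mode is a natural extension).
* Differential expression testing is out of scope by design; the built-in
  caller is a driver for synthetic runs, not a statistical test.
* t-half assumes the first and last sampled days bracket the transition;
  transitions still in progress at the last day are reported as crossings
  of the observed (partial) change.
* The intergenic scan reports bin-resolution intervals and does not
  assemble transcripts or resolve splice structure.
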