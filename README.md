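# epiTempo

Does a repressive chromatin mark drive transcriptional change, or trail
behind it? When an oncogenic signal (e.g. constitutively active Ras)
reshapes both the transcriptome and the H3K27me3 landscape of a cell over a
multi-day time course, the order of events is the evidence: a mark that is
a *trigger* must move before transcription, a mark that is a *consequence*
moves after. `epiTempo` implements the genome-wide timing analysis that
answers this question from binned ChIP-seq coverage and per-gene expression
tables sampled at a handful of days, for epigenomics groups who have such
time-course data and want the comparison to be reproducible rather than a
one-off script.

## What it computes

**Length-normalized metagene profiles.** Each gene body (TSS to TTS,
introns included) is mapped onto a common axis by rescaling bin positions,

    r = (b - g_s) / (g_e - g_s),

where `g_s` and `g_e` are the TSS and TTS and `b` a bin coordinate. The
same rescaling applied to flanks of one gene length on either side yields
600 ordered points per gene (200 upstream, 200 body, 200 downstream),
always in 5'→3' orientation, so enrichment shapes of genes of different
sizes can be averaged, z-scored and clustered.

**Region means and differential calling.** Mean coverage over the gene
body and over the TSS ±2.5 kb window at every time point, fold changes
relative to day 0, and a two-sided ≥2-fold criterion at any time point to
call a gene differentially methylated. The joint set with differentially
expressed genes (an external list, or a built-in fold-change caller for
synthetic runs) is the cohort whose timing is analyzed.

**The t-half statistic.** For a sampled series `v(t)` on days
`t = 0, 2, 4, 7, 12`, t-half is the time at which the series crosses

    m = (v(0) + v(12)) / 2,

linearly interpolated between the bracketing sampled days — the time at
which half of the total change has occurred. Cohort medians of t-half for
expression versus H3K27me3, and the per-gene difference, quantify the
lead/lag between transcription and chromatin.

**Supporting stages.** Hierarchical clustering of spatial and temporal
profiles (Euclidean/Ward on z-scored rows by default), lowess smoothing and
equal-read-count normalization of coverage tracks, bedGraph/WIG I/O, an
intergenic scan for candidate unannotated transcripts (strand-split RNA
coverage plus differential H3K27me3 outside any gene body), 2^-ΔΔCt and
percent-of-input qPCR helpers, and a synthetic-data generator with known
lead/lag ground truth that exercises every stage.

## Worked example

Simulate a cohort with known timing structure (expression midpoints 1.1 and
3.3 days, H3K27me3 midpoints 6.9 and 4.8 days), write it as ordinary files
(BED, bedGraph, FPKM table), and run the pipeline on them:

```r
library(epiTempo)

cfg <- simulationConfig(seed = 7, nBroadGain = 15, nBroadLoss = 10,
                        nTssGain = 5, nUnchanged = 20, nIntergenic = 4,
                        chromLengths = c(chr1 = 2e6, chr2 = 2e6))
bundle <- simulateBundle(cfg)
dir <- file.path(tempdir(), "bundle")
writeFixtureBundle(bundle, dir)
res <- runPipeline(bundlePipelineConfig(dir), file.path(tempdir(), "out"))

res$jointBody$n_joint
#> [1] 25
read.table(file.path(tempdir(), "out", "timing_summary.tsv"),
           header = TRUE, sep = "\t")
#>   median_thalf_expression median_thalf_h3k27me3 median_lag_days
#> 1                1.363194              6.316925        4.946617
#>   fraction_me3_later n_pairs
#> 1                  1      25
```

25 genes are jointly regulated in H3K27me3 (gene body) and expression; the
median half-transition of expression (1.36 d) precedes that of H3K27me3
(6.32 d) by ~4.9 days, and the chromatin change comes later for every one
of the 25 genes — the generator's transcription-first ordering, recovered
from the coverage files alone.

The statistic itself is one call:

```r
tHalf(c(12.1, 6.3, 3.9, 3.2, 3.0))   # days 0, 2, 4, 7, 12
#> $t_half
#> [1] 1.568966       # crosses (12.1 + 3.0)/2 between days 0 and 2
#> $status
#> [1] "ok"
```

and so is the published read-filter arithmetic:

```r
mappingFilterSummary(174644447, 870116495)
#> pct_discarded  pct_retained
#>         16.72         83.28
```

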