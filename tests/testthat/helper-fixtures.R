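suppressPackageStartupMessages(library(GenomicRanges))

## Single-gene GRanges on a given strand, 0-based half-open coordinates.
makeGene <- function(start0, end0, strand = "+", chrom = "chr1",
                     id = "geneA") {
  readGeneModelsFromDf(data.frame(gene_id = id, chrom = chrom,
                                  start = start0, end = end0,
                                  strand = strand))
}

makeTrack <- function(values, binSize = 1000, chrom = "chr1",
                      chromLen = length(values) * binSize, label = "t") {
  bins <- setNames(list(as.numeric(values)), chrom)
  SignalTrack(bins, binSize, setNames(chromLen, chrom), label)
}

## Per-base expansion of a binned track on one chromosome.
expandPerBase <- function(values, binSize, chromLen) {
  rep(values, each = binSize)[seq_len(chromLen)]
}

## Brute-force per-base mean over the integer 0-based span [s0, e0).
perBaseRegionMean <- function(values, binSize, chromLen, s0, e0) {
  v <- expandPerBase(values, binSize, chromLen)
  mean(v[(s0 + 1):e0])
}

## Brute-force per-base metagene oracle: for each normalized position the
## weighted per-base mean over its (fractional) genomic span, clipped at the
## chromosome; NA when the clipped span is empty. Independent of the
## bin-overlap arithmetic used by buildMetageneProfile.
perBaseMetagene <- function(values, binSize, chromLen, s0, e0, strand,
                            pps = 200) {
  v <- expandPerBase(values, binSize, chromLen)
  len <- e0 - s0
  segs <- if (strand == "+") {
    list(c(s0 - len, s0), c(s0, e0), c(e0, e0 + len))
  } else {
    list(c(e0, e0 + len), c(s0, e0), c(s0 - len, s0))
  }
  unlist(lapply(segs, function(seg) {
    a <- seg[1]; b <- seg[2]
    sapply(seq_len(pps), function(j) {
      if (strand == "+") {
        lo <- a + (j - 1) * (b - a) / pps; hi <- a + j * (b - a) / pps
      } else {
        lo <- b - j * (b - a) / pps; hi <- b - (j - 1) * (b - a) / pps
      }
      lo <- max(lo, 0); hi <- min(hi, chromLen)
      if (hi <= lo) return(NA_real_)
      bases <- floor(lo):(ceiling(hi) - 1)
      w <- pmin(hi, bases + 1) - pmax(lo, bases)
      sum(v[bases + 1] * w) / sum(w)
    })
  }), use.names = FALSE)
}

## Small simulated cohort shared by slower tests (built once per run).
smallBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateBundle(simulationConfig(
        seed = 11, nBroadGain = 15, nBroadLoss = 10, nTssGain = 5,
        nUnchanged = 20, nIntergenic = 4,
        chromLengths = c(chr1 = 1.4e6, chr2 = 1.4e6)))
    cache
  }
})
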