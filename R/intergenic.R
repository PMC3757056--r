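#' Intergenic mask
#'
#' The per-chromosome complement of the union of gene bodies: every interval
#' that overlaps no annotated gene.
#'
#' @param genes Named `GRanges` of gene models.
#' @param seqlengths Named vector of chromosome lengths.
#' @return `GRanges` of intergenic intervals with a `region` metadata column
#'   set to `"intergenic"`.
#' @examples
#' g <- readGeneModelsFromDf(data.frame(gene_id = "g", chrom = "chr1",
#'                                      start = 10, end = 20, strand = "+"))
#' intergenicMask(g, c(chr1 = 100))   # [0,10) and [20,100)
#' @export
intergenicMask <- function(genes, seqlengths) {
  whole <- .gr0(names(seqlengths), rep(0, length(seqlengths)),
                unname(seqlengths))
  covered <- reduce(.gr0(as.character(seqnames(genes)), .start0(genes),
                         .end0(genes)))
  mask <- GenomicRanges::setdiff(whole, covered)
  mcols(mask)$region <- rep("intergenic", length(mask))
  mask
}

.ratioHit <- function(a, b, minFold, pseudocount) {
  r <- (b + pseudocount) / (a + pseudocount)
  r >= minFold | r <= 1 / minFold
}

#' Scan for intergenic candidate transcript regions
#'
#' Systematic replacement for manual browser inspection: finds maximal runs
#' of at least `minWidth` intergenic bins in which the H3K27me3 signal and a
#' strand-specific RNA signal both differ between two conditions by at least
#' `minFold` (in either direction) and the local signal rises above
#' `minSignal`. Each run is reported once, with its dominant RNA strand
#' (watson = `+`, crick = `-`) and the run-level fold changes.
#'
#' @param me3A,me3B [SignalTrack-class] H3K27me3 tracks for the two
#'   conditions (A = reference).
#' @param rnaA,rnaB Lists with elements `watson` and `crick`: strand-split
#'   RNA coverage [SignalTrack-class] tracks per condition.
#' @param mask Intergenic `GRanges` from [intergenicMask()]; only bins fully
#'   inside the mask are scanned.
#' @param minFold Minimum between-condition fold change (default 2, either
#'   direction).
#' @param minSignal Minimum peak signal per bin, in track units (default 5),
#'   applied to both the H3K27me3 and the RNA evidence.
#' @param minWidth Minimum run length in bins (default 2).
#' @param pseudocount Pseudocount for the ratios (default 0.5).
#' @param evidence Which differential evidence is required: `"both"`
#'   (default; H3K27me3 and RNA), `"me3"`, or `"rna"`.
#' @return `GRanges` of candidate regions with strand set to the dominant
#'   RNA strand and metadata columns `me3_fold` and `rna_fold`.
#' @export
scanCandidates <- function(me3A, me3B, rnaA, rnaB, mask, minFold = 2,
                           minSignal = 5, minWidth = 2, pseudocount = 0.5,
                           evidence = c("both", "me3", "rna")) {
  evidence <- match.arg(evidence)
  tracks <- list(me3A, me3B, rnaA$watson, rnaA$crick, rnaB$watson,
                 rnaB$crick)
  bs <- unique(vapply(tracks, binSize, integer(1)))
  if (length(bs) != 1L) stop("tracks do not share a bin grid")
  out <- GenomicRanges::GRanges()
  for (chrom in names(binValues(me3A))) {
    ma <- binValues(me3A)[[chrom]]; mb <- binValues(me3B)[[chrom]]
    wa <- binValues(rnaA$watson)[[chrom]]
    wb <- binValues(rnaB$watson)[[chrom]]
    ca <- binValues(rnaA$crick)[[chrom]]
    cb <- binValues(rnaB$crick)[[chrom]]
    n <- length(ma)
    inMask <- logical(n)
    mk <- mask[as.character(seqnames(mask)) == chrom]
    for (j in seq_along(mk)) {
      first <- ceiling(.start0(mk)[j] / bs)        # first fully inside bin
      last <- floor(.end0(mk)[j] / bs) - 1         # last fully inside bin
      if (last >= first) inMask[(first:last) + 1L] <- TRUE
    }
    me3Hit <- .ratioHit(ma, mb, minFold, pseudocount) &
      pmax(ma, mb) >= minSignal
    wHit <- .ratioHit(wa, wb, minFold, pseudocount) &
      pmax(wa, wb) >= minSignal
    cHit <- .ratioHit(ca, cb, minFold, pseudocount) &
      pmax(ca, cb) >= minSignal
    flag <- switch(evidence,
                   both = me3Hit & (wHit | cHit),
                   me3 = me3Hit,
                   rna = wHit | cHit) & inMask
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= minWidth)) {
      i0 <- starts[j]; i1 <- ends[j]
      idx <- i0:i1
      me3Fold <- (mean(mb[idx]) + pseudocount) /
        (mean(ma[idx]) + pseudocount)
      wFold <- (mean(wb[idx]) + pseudocount) / (mean(wa[idx]) + pseudocount)
      cFold <- (mean(cb[idx]) + pseudocount) / (mean(ca[idx]) + pseudocount)
      watson <- abs(log2(wFold)) >= abs(log2(cFold))
      cand <- .gr0(chrom, (i0 - 1) * bs,
                   min(i1 * bs, seqlengths(me3A)[[chrom]]),
                   if (watson) "+" else "-")
      mcols(cand)$me3_fold <- me3Fold
      mcols(cand)$rna_fold <- if (watson) wFold else cFold
      out <- c(out, cand)
    }
  }
  out
}

#' Annotate candidate regions with their nearest gene
#'
#' Nearest gene by edge distance (0 for overlap); equidistant ties are
#' broken toward the gene downstream of the region in its dominant-strand
#' orientation.
#'
#' @param candidates `GRanges` of candidate regions (strand = dominant RNA
#'   strand).
#' @param genes Named `GRanges` of gene models.
#' @return `candidates` with metadata columns `nearest_gene` and
#'   `distance` (bp).
#' @export
annotateNearestGene <- function(candidates, genes) {
  nearest <- character(length(candidates))
  dists <- numeric(length(candidates))
  gChrom <- as.character(seqnames(genes))
  gS <- .start0(genes); gE <- .end0(genes)
  for (i in seq_along(candidates)) {
    chrom <- as.character(seqnames(candidates))[i]
    sel <- which(gChrom == chrom)
    if (!length(sel)) {
      nearest[i] <- NA_character_; dists[i] <- NA_real_
      next
    }
    cS <- .start0(candidates)[i]; cE <- .end0(candidates)[i]
    d <- pmax(0, pmax(gS[sel] - cE, cS - gE[sel]))
    best <- sel[d == min(d)]
    if (length(best) > 1L) {
      after <- gS[best] >= cE
      prefer <- if (as.character(strand(candidates))[i] == "-") !after
                else after
      if (any(prefer)) best <- best[prefer]
    }
    nearest[i] <- names(genes)[best[1]]
    dists[i] <- min(d)
  }
  mcols(candidates)$nearest_gene <- nearest
  mcols(candidates)$distance <- dists
  candidates
}

#' Write candidate regions as extended BED
#'
#' BED6 plus `me3_fold`, `rna_fold`, `nearest_gene` and `distance` columns;
#' the dominant RNA strand is encoded in the BED strand field.
#'
#' @param candidates Annotated `GRanges` from [annotateNearestGene()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeCandidateBed <- function(candidates, path) {
  df <- data.frame(
    chrom = as.character(seqnames(candidates)),
    start = format(.start0(candidates), scientific = FALSE, trim = TRUE),
    end = format(.end0(candidates), scientific = FALSE, trim = TRUE),
    name = sprintf("candidate_%d", seq_along(candidates)),
    score = 0,
    strand = as.character(strand(candidates)),
    me3_fold = mcols(candidates)$me3_fold,
    rna_fold = mcols(candidates)$rna_fold,
    nearest_gene = mcols(candidates)$nearest_gene,
    distance = mcols(candidates)$distance)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
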