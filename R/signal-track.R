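#' @importFrom S4Vectors DataFrame
NULL

## Length-weighted mean of bin values over the (possibly fractional) 0-based
## span [s0, e0) on one chromosome. Returns c(mean, nBins); NA mean when the
## clipped span is empty.
.spanMean <- function(values, binSize, s0, e0, seqlen) {
  s0 <- max(s0, 0)
  e0 <- min(e0, seqlen)
  if (e0 <= s0) return(c(NA_real_, 0))
  i0 <- floor(s0 / binSize)            # first bin index, 0-based
  i1 <- ceiling(e0 / binSize) - 1      # last bin index
  idx <- i0:i1
  binStart <- idx * binSize
  w <- pmin(e0, binStart + binSize) - pmax(s0, binStart)
  v <- values[idx + 1L]
  c(sum(v * w) / sum(w), length(idx))
}

#' Bin read positions into a coverage track
#'
#' Counts reads (given as single genomic positions, e.g. fragment midpoints)
#' into fixed-width bins per chromosome using the half-open convention: a
#' position `p` falls in bin `floor(p / binSize)`. Positions outside
#' `[0, chromosome length)` or on unknown chromosomes are rejected, with a
#' warning stating how many.
#'
#' @param positions Data frame with columns `chrom` and `pos` (0-based bp).
#' @param binSize Bin width in bp.
#' @param seqlengths Named vector of chromosome lengths.
#' @param sampleLabel Label stored on the resulting track.
#' @return A [SignalTrack-class]; its `librarySize` equals the number of
#'   accepted positions.
#' @examples
#' pos <- data.frame(chrom = "chr1", pos = c(100, 500, 999, 1000))
#' tr <- binCounts(pos, 1000, c(chr1 = 2000))
#' binValues(tr)$chr1   # c(3, 1): position 1000 falls in the second bin
#' @export
binCounts <- function(positions, binSize, seqlengths, sampleLabel = "") {
  stopifnot(binSize > 0, all(c("chrom", "pos") %in% names(positions)))
  known <- positions$chrom %in% names(seqlengths)
  inb <- known & positions$pos >= 0 &
    positions$pos < unname(seqlengths[positions$chrom])
  inb[is.na(inb)] <- FALSE
  nRej <- sum(!inb)
  if (nRej > 0)
    warning(nRej, " position(s) outside chromosome bounds rejected")
  positions <- positions[inb, , drop = FALSE]
  bins <- lapply(names(seqlengths), function(chrom) {
    n <- as.integer(ceiling(seqlengths[[chrom]] / binSize))
    p <- positions$pos[positions$chrom == chrom]
    if (!length(p)) return(numeric(n))
    as.numeric(tabulate(floor(p / binSize) + 1L, nbins = n))
  })
  names(bins) <- names(seqlengths)
  SignalTrack(bins, binSize, seqlengths, sampleLabel,
              librarySize = nrow(positions))
}

#' Equalize library sizes between two tracks
#'
#' Linearly rescales the deeper of the two libraries so both tracks report
#' the same effective total; the smaller library is left unchanged. Within a
#' track, per-bin ratios are unaffected.
#'
#' @param trackA,trackB [SignalTrack-class] objects with positive library
#'   sizes.
#' @return A list with elements `a` and `b`, the (possibly rescaled) tracks.
#' @export
normalizeLibrary <- function(trackA, trackB) {
  if (librarySize(trackA) <= 0 || librarySize(trackB) <= 0)
    stop("both tracks must have positive librarySize")
  la <- librarySize(trackA); lb <- librarySize(trackB)
  target <- min(la, lb)
  list(a = .scaleTrack(trackA, target / la),
       b = .scaleTrack(trackB, target / lb))
}

#' Equalize library sizes across a list of tracks
#'
#' All tracks are rescaled to the smallest library size in the set, so every
#' time point reports the same effective total.
#'
#' @param tracks List of [SignalTrack-class] objects.
#' @return List of rescaled tracks, same names and order.
#' @export
normalizeLibraries <- function(tracks) {
  sizes <- vapply(tracks, librarySize, numeric(1))
  if (any(sizes <= 0)) stop("all tracks must have positive librarySize")
  target <- min(sizes)
  lapply(tracks, function(tr) .scaleTrack(tr, target / librarySize(tr)))
}

.scaleTrack <- function(track, factor) {
  if (factor == 1) return(track)
  SignalTrack(lapply(binValues(track), `*`, factor), binSize(track),
              seqlengths(track), sampleLabel(track),
              librarySize = librarySize(track) * factor)
}

#' Lowess-smooth a coverage track
#'
#' Applies locally weighted regression of bin value on bin index, per
#' chromosome, using `stats::lowess`. Negative smoothed values are floored
#' at zero. Chromosomes with fewer than 3 bins are returned unchanged with a
#' warning.
#'
#' @param track A [SignalTrack-class].
#' @param spanFraction Smoother span as a fraction of the bins on each
#'   chromosome (default 0.01); the effective window never drops below two
#'   bins.
#' @return A smoothed [SignalTrack-class] of identical shape.
#' @export
lowessSmooth <- function(track, spanFraction = 0.01) {
  stopifnot(spanFraction > 0, spanFraction <= 1)
  bins <- lapply(names(binValues(track)), function(chrom) {
    v <- binValues(track)[[chrom]]
    n <- length(v)
    if (n < 3L) {
      warning("chromosome ", chrom, " has fewer than 3 bins; not smoothed")
      return(v)
    }
    f <- max(spanFraction, 2 / n)
    pmax(lowess(seq_len(n), v, f = f)$y, 0)
  })
  names(bins) <- names(binValues(track))
  SignalTrack(bins, binSize(track), seqlengths(track), sampleLabel(track),
              librarySize = librarySize(track))
}

#' Mean signal over genomic regions
#'
#' For each region, the mean of the track bins it overlaps, weighted by the
#' overlap length between bin and region (partial edge bins count
#' fractionally). This equals the per-base average of the piecewise-constant
#' coverage over the region.
#'
#' @param track A [SignalTrack-class].
#' @param regions A `GRanges` (e.g. from [geneBody()] or [tssWindow()]);
#'   names identify the genes, and a `region` metadata column, if present,
#'   is carried through.
#' @return A `DataFrame` with columns `gene_id`, `region`, `mean_signal`,
#'   `n_bins`.
#' @examples
#' tr <- SignalTrack(list(chr1 = c(2, 4)), 1000, c(chr1 = 2000))
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
#' meanRegionSignal(tr, r)$mean_signal   # 3
#' @export
meanRegionSignal <- function(track, regions) {
  chrom <- as.character(seqnames(regions))
  bad <- !chrom %in% names(binValues(track))
  if (any(bad))
    stop("region(s) on chromosomes absent from track: ",
         paste(unique(chrom[bad]), collapse = ", "))
  res <- vapply(seq_along(regions), function(i) {
    .spanMean(binValues(track)[[chrom[i]]], binSize(track),
              .start0(regions)[i], .end0(regions)[i],
              seqlengths(track)[[chrom[i]]])
  }, numeric(2))
  if (any(is.na(res[1, ]))) {
    lab <- names(regions)[is.na(res[1, ])]
    if (is.null(lab)) lab <- which(is.na(res[1, ]))
    stop("region(s) with no track overlap: ",
         paste(utils::head(lab, 5), collapse = ", "))
  }
  DataFrame(
    gene_id = if (is.null(names(regions))) as.character(seq_along(regions))
              else names(regions),
    region = if ("region" %in% names(mcols(regions)))
               mcols(regions)$region else NA_character_,
    mean_signal = res[1, ],
    n_bins = as.integer(res[2, ]))
}

#' Mean signal per gene region across a time course of tracks
#'
#' Convenience wrapper: applies [meanRegionSignal()] to each track in a list
#' and binds the means into a genes x samples matrix.
#'
#' @param tracks Named list of [SignalTrack-class] objects (e.g. one per
#'   day).
#' @param regions `GRanges` of quantification regions, one per gene.
#' @return Numeric matrix, rows = genes, columns = tracks.
#' @export
regionSignalMatrix <- function(tracks, regions) {
  m <- vapply(tracks, function(tr) meanRegionSignal(tr, regions)$mean_signal,
              numeric(length(regions)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(regions))
  rownames(m) <- names(regions)
  colnames(m) <- names(tracks)
  m
}

#' Summarize a read-mapping filter
#'
#' Percentages of reads discarded and retained by a mapping filter, rounded
#' to two decimals.
#'
#' @param discarded,retained Non-negative read counts; their sum must be
#'   positive.
#' @return Named numeric vector `c(pct_discarded, pct_retained)`.
#' @examples
#' mappingFilterSummary(174644447, 870116495)  # 16.72 / 83.28
#' @export
mappingFilterSummary <- function(discarded, retained) {
  stopifnot(discarded >= 0, retained >= 0)
  total <- discarded + retained
  if (total <= 0) stop("discarded + retained must be positive")
  c(pct_discarded = round(100 * discarded / total, 2),
    pct_retained = round(100 * retained / total, 2))
}

#' Read a bedGraph file into a SignalTrack
#'
#' Four tab-separated columns (chrom, start, end, value; 0-based half-open).
#' Intervals are resampled onto the track's fixed bin grid by length-weighted
#' averaging: each bin takes the average of the interval values covering it,
#' weighted by covered length (an interval spanning two bins contributes its
#' value to both). Bins with no coverage are 0. Overlapping intervals are an
#' error.
#'
#' @param path Path to the bedGraph file.
#' @param binSize Target bin width in bp.
#' @param seqlengths Named chromosome lengths.
#' @param sampleLabel Label stored on the track.
#' @return A [SignalTrack-class]; `librarySize` is the total signal
#'   (sum of value x covered length / binSize).
#' @export
readBedGraph <- function(path, binSize, seqlengths, sampleLabel = "") {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric",
                                  "numeric"),
                   comment.char = "#")
  df <- df[!grepl("^(track|browser)", df$chrom), , drop = FALSE]
  bins <- lapply(names(seqlengths), function(chrom) {
    n <- as.integer(ceiling(seqlengths[[chrom]] / binSize))
    num <- numeric(n); den <- numeric(n)
    d <- df[df$chrom == chrom, , drop = FALSE]
    if (nrow(d)) {
      d <- d[order(d$start), , drop = FALSE]
      if (any(d$start[-1] < d$end[-nrow(d)]))
        stop("overlapping bedGraph intervals on ", chrom)
      for (j in seq_len(nrow(d))) {
        s0 <- max(d$start[j], 0); e0 <- min(d$end[j], seqlengths[[chrom]])
        if (e0 <= s0) next
        i0 <- floor(s0 / binSize); i1 <- ceiling(e0 / binSize) - 1
        idx <- i0:i1
        w <- pmin(e0, (idx + 1) * binSize) - pmax(s0, idx * binSize)
        num[idx + 1L] <- num[idx + 1L] + d$value[j] * w
        den[idx + 1L] <- den[idx + 1L] + w
      }
    }
    ifelse(den > 0, num / den, 0)
  })
  names(bins) <- names(seqlengths)
  SignalTrack(bins, binSize, seqlengths, sampleLabel)
}

#' Write a SignalTrack as fixedStep WIG
#'
#' One `fixedStep` block per chromosome with `step` and `span` equal to the
#' bin size (WIG positions are 1-based). Values round-trip through
#' [readWig()] within 1e-6.
#'
#' @param track A [SignalTrack-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeWig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(binValues(track))) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       chrom, binSize(track), binSize(track)), con)
    writeLines(sprintf("%.10g", binValues(track)[[chrom]]), con)
  }
  invisible(path)
}

#' Read a fixedStep WIG file written by [writeWig()]
#'
#' @param path Path to the WIG file.
#' @param seqlengths Named chromosome lengths (defines the bin grid).
#' @param sampleLabel Label stored on the track.
#' @return A [SignalTrack-class].
#' @export
readWig <- function(path, seqlengths, sampleLabel = "") {
  lines <- readLines(path)
  hdr <- grep("^fixedStep", lines)
  if (!length(hdr)) stop("no fixedStep header in ", path)
  binSize <- as.integer(sub(".*step=([0-9]+).*", "\\1", lines[hdr[1]]))
  bins <- lapply(names(seqlengths),
                 function(chrom) numeric(ceiling(seqlengths[[chrom]] /
                                                   binSize)))
  names(bins) <- names(seqlengths)
  bounds <- c(hdr, length(lines) + 1L)
  for (h in seq_along(hdr)) {
    chrom <- sub(".*chrom=([^ ]+).*", "\\1", lines[hdr[h]])
    if (!chrom %in% names(seqlengths))
      stop("unknown chromosome in WIG: ", chrom)
    vals <- as.numeric(lines[(hdr[h] + 1L):(bounds[h + 1L] - 1L)])
    if (length(vals) != length(bins[[chrom]]))
      stop("WIG block length does not match bin grid for ", chrom)
    bins[[chrom]] <- vals
  }
  SignalTrack(bins, binSize, seqlengths, sampleLabel)
}

#' Write a SignalTrack as bedGraph
#'
#' One interval per bin (the last interval is clipped at the chromosome
#' end). Used by the fixture writer so synthetic tracks can be re-read with
#' [readBedGraph()].
#'
#' @param track A [SignalTrack-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeBedGraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(binValues(track))) {
    v <- binValues(track)[[chrom]]
    s0 <- (seq_along(v) - 1) * binSize(track)
    e0 <- pmin(s0 + binSize(track), seqlengths(track)[[chrom]])
    writeLines(sprintf("%s\t%s\t%s\t%.10g", chrom,
                       format(s0, scientific = FALSE, trim = TRUE),
                       format(e0, scientific = FALSE, trim = TRUE), v), con)
  }
  invisible(path)
}
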