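#' Length-normalized bin positions within a gene
#'
#' Maps genomic bin coordinates onto the normalized gene axis
#' `r = (b - g_s) / (g_e - g_s)`, where `g_s` is the TSS and `g_e` the TTS.
#' The mapping is strand-aware: for minus-strand genes the axis runs from
#' `end` to `start`, so position 0 is always the TSS and 1 the TTS. Bin
#' positions in the gene body map to `[0, 1]`, the upstream flank to
#' `[-1, 0]` and the downstream flank to `[1, 2]`.
#'
#' @param gene A length-1 named `GRanges` gene model.
#' @param bins Data frame (or 2-column matrix) with 0-based half-open bin
#'   coordinates `b_start`, `b_end`.
#' @return Data frame with columns `r_start`, `r_end` (with
#'   `r_start < r_end`) and `segment` (`upstream`/`body`/`downstream`,
#'   assigned by interval midpoint).
#' @examples
#' g <- readGeneModelsFromDf(data.frame(gene_id = "g", chrom = "chr1",
#'                                      start = 1000, end = 2000,
#'                                      strand = "+"))
#' normalizeBinPositions(g, data.frame(b_start = 1000, b_end = 1100))
#' @export
normalizeBinPositions <- function(gene, bins) {
  stopifnot(length(gene) == 1L)
  bins <- as.data.frame(bins)
  if (ncol(bins) < 2L) stop("bins must have two coordinate columns")
  bs <- bins[[1]]; be <- bins[[2]]
  s0 <- .start0(gene); e0 <- .end0(gene)
  len <- e0 - s0
  if (len <= 0) stop("zero-length gene")
  if (as.character(strand(gene)) == "+") {
    r1 <- (bs - s0) / len; r2 <- (be - s0) / len
  } else {
    r1 <- (e0 - be) / len; r2 <- (e0 - bs) / len
  }
  mid <- (r1 + r2) / 2
  segment <- ifelse(mid < 0, "upstream", ifelse(mid > 1, "downstream",
                                                "body"))
  data.frame(r_start = r1, r_end = r2, segment = segment)
}

#' Build a length-normalized metagene profile for one gene
#'
#' Resamples a binned coverage track onto `3 * pointsPerSegment` normalized
#' positions spanning the upstream flank, the gene body (TSS to TTS, introns
#' included) and the downstream flank; both flanks are as long as the gene
#' body. Each normalized position carries the length-weighted mean of the
#' track bins overlapping its genomic span (equivalently, the per-base mean
#' of the piecewise-constant coverage). Segments are ordered in
#' transcriptional 5' to 3' orientation, so minus-strand genes are mirrored
#' onto the same axis as plus-strand genes. Positions whose span lies
#' entirely off the chromosome are `NA` and excluded from the profile mean
#' and standard deviation.
#'
#' @param track A [SignalTrack-class].
#' @param gene A length-1 named `GRanges` gene model.
#' @param pointsPerSegment Points per segment (default 200, for 600 points
#'   per gene).
#' @return A [MetageneProfile-class].
#' @export
buildMetageneProfile <- function(track, gene, pointsPerSegment = 200) {
  stopifnot(length(gene) == 1L, pointsPerSegment >= 1)
  chrom <- as.character(seqnames(gene))
  if (!chrom %in% names(binValues(track)))
    stop("gene chromosome absent from track: ", chrom)
  s0 <- .start0(gene); e0 <- .end0(gene)
  len <- e0 - s0
  plus <- as.character(strand(gene)) == "+"
  ## unclipped genomic segment bounds in transcriptional order
  segs <- if (plus) {
    list(c(s0 - len, s0), c(s0, e0), c(e0, e0 + len))
  } else {
    list(c(e0, e0 + len), c(s0, e0), c(s0 - len, s0))
  }
  vals <- binValues(track)[[chrom]]
  sl <- seqlengths(track)[[chrom]]
  bs <- binSize(track)
  pps <- as.integer(pointsPerSegment)
  out <- unlist(lapply(segs, function(seg) {
    a <- seg[1]; b <- seg[2]
    j <- seq_len(pps)
    if (plus) {
      lo <- a + (j - 1) * (b - a) / pps
      hi <- a + j * (b - a) / pps
    } else {
      lo <- b - j * (b - a) / pps
      hi <- b - (j - 1) * (b - a) / pps
    }
    vapply(seq_len(pps),
           function(i) .spanMean(vals, bs, lo[i], hi[i], sl)[1],
           numeric(1))
  }), use.names = FALSE)
  MetageneProfile(names(gene), out, pps)
}

#' Metagene profiles for many genes as a matrix
#'
#' @param track A [SignalTrack-class].
#' @param genes Named `GRanges` of gene models.
#' @param pointsPerSegment Points per segment (default 200).
#' @return Numeric matrix, one row per gene, `3 * pointsPerSegment` columns.
#' @export
metageneMatrix <- function(track, genes, pointsPerSegment = 200) {
  m <- t(vapply(seq_along(genes), function(i)
    profileValues(buildMetageneProfile(track, genes[i], pointsPerSegment)),
    numeric(3L * pointsPerSegment)))
  rownames(m) <- names(genes)
  m
}

#' Z-score a metagene profile
#'
#' Rescales the profile so its mean is 0 and its standard deviation 1
#' (computed over non-missing positions). Flat profiles (sd of 0) cannot be
#' z-scored; they are excluded with a warning and `NULL` is returned.
#'
#' @param profile A [MetageneProfile-class].
#' @return A z-scored [MetageneProfile-class], or `NULL` for a flat profile.
#' @export
zscoreProfile <- function(profile) {
  v <- profileValues(profile)
  ok <- !is.na(v)
  if (sum(ok) < 2L || sd(v[ok]) == 0) {
    warning("flat profile for gene '", geneId(profile),
            "' excluded from z-scoring")
    return(NULL)
  }
  z <- (v - mean(v[ok])) / sd(v[ok])
  MetageneProfile(geneId(profile), z, pointsPerSegment(profile))
}

#' Random gene subsample
#'
#' Uniform sample of genes without replacement, reproducible for a fixed
#' seed.
#'
#' @param genes Named `GRanges` of gene models.
#' @param n Number of genes to draw (default 2000).
#' @param seed Integer seed.
#' @return A `GRanges` subset of `genes`.
#' @export
sampleGenes <- function(genes, n = 2000, seed = 1) {
  if (n > length(genes))
    stop("cannot sample ", n, " from ", length(genes), " genes")
  set.seed(seed)
  genes[sort(sample(length(genes), n))]
}

#' Five-level expression class from FPKM
#'
#' Classes: unexpressed (FPKM = 0), then (0,1], (1,10], (10,100] and >100,
#' upper-inclusive.
#'
#' @param fpkm Numeric vector of non-negative FPKM values.
#' @return Factor with levels `FPKM=0`, `0<FPKM<=1`, `1<FPKM<=10`,
#'   `10<FPKM<=100`, `FPKM>100`.
#' @export
expressionClass <- function(fpkm) {
  if (any(fpkm < 0, na.rm = TRUE)) stop("negative FPKM")
  lv <- c("FPKM=0", "0<FPKM<=1", "1<FPKM<=10", "10<FPKM<=100", "FPKM>100")
  idx <- ifelse(fpkm == 0, 1L,
         ifelse(fpkm <= 1, 2L,
         ifelse(fpkm <= 10, 3L,
         ifelse(fpkm <= 100, 4L, 5L))))
  factor(lv[idx], levels = lv)
}

#' Mean metagene profile per expression class
#'
#' Averages per-gene profiles position-wise within each of the five FPKM
#' classes. Empty classes are reported with a count of 0 and an all-`NA`
#' mean row, not as an error.
#'
#' @param profileMatrix Numeric matrix of per-gene profiles (rows named by
#'   gene).
#' @param fpkm Named numeric vector of FPKM values covering every profiled
#'   gene.
#' @return List with `classMeans` (5 x ncol matrix, one row per class) and
#'   `counts` (genes per class).
#' @export
aggregateByExpressionClass <- function(profileMatrix, fpkm) {
  genes <- rownames(profileMatrix)
  if (is.null(genes) || !all(genes %in% names(fpkm)))
    stop("every profiled gene needs an FPKM value")
  cls <- expressionClass(unname(fpkm[genes]))
  lv <- levels(cls)
  classMeans <- t(vapply(lv, function(l) {
    rows <- which(cls == l)
    if (!length(rows)) return(rep(NA_real_, ncol(profileMatrix)))
    colMeans(profileMatrix[rows, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(profileMatrix))))
  rownames(classMeans) <- lv
  list(classMeans = classMeans, counts = table(cls))
}

#' Export a profile matrix as tab-delimited text
#'
#' Writes the per-gene profile matrix with a segment header row
#' (`upstream`/`body`/`downstream` per column) for external plotting.
#'
#' @param profileMatrix Numeric matrix of profiles, rows named by gene.
#' @param path Output path.
#' @param pointsPerSegment Points per segment used to build the profiles.
#' @return Invisibly, `path`.
#' @export
writeProfileMatrix <- function(profileMatrix, path,
                               pointsPerSegment = ncol(profileMatrix) / 3) {
  seg <- rep(c("upstream", "body", "downstream"),
             each = pointsPerSegment)[seq_len(ncol(profileMatrix))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", seg), collapse = "\t"), con)
  write.table(data.frame(gene_id = rownames(profileMatrix), profileMatrix),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
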