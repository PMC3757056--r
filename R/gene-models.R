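#' @importFrom GenomicRanges GRanges strand start end seqnames mcols
#'   mcols<- strand<- reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

## Coordinates are 0-based half-open at the file and arithmetic level (BED
## native); GRanges storage is 1-based closed, converted by the two helpers
## below and nowhere else.
.gr0 <- function(chrom, start0, end0, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand)
}
.start0 <- function(gr) GenomicRanges::start(gr) - 1
.end0 <- function(gr) GenomicRanges::end(gr)

#' Read gene models from BED6 or minimal GTF
#'
#' Parses an annotation file into a `GRanges` of stranded gene spans, one per
#' `gene_id` (names of the result). Records with `end <= start` or with a
#' strand other than `+`/`-` are rejected with a warning that names the
#' offending line; duplicate gene ids are collapsed to the longest span, with
#' a warning. GTF coordinates (1-based closed) are converted to the internal
#' 0-based half-open convention on read; only `gene`-level GTF records are
#' used (all records if none are typed `gene`).
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` (BED6: chrom, start, end, name, score, strand) or
#'   `"gtf"`.
#' @param seqlengths Optional named vector of chromosome lengths, attached to
#'   the result for downstream clipping.
#' @return A named `GRanges`, one range per gene.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t1000\t2000\tgeneA\t0\t+", bed)
#' readGeneModels(bed)
#' @export
readGeneModels <- function(path, format = c("bed", "gtf"),
                           seqlengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  recs <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    rec <- if (format == "bed") .parseBedLine(f, i) else .parseGtfLine(f, i)
    if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  }
  if (!length(recs)) {
    gr <- GenomicRanges::GRanges()
    return(gr)
  }
  df <- do.call(rbind, lapply(recs, as.data.frame,
                              stringsAsFactors = FALSE))
  ## collapse duplicate gene ids to the longest span
  if (anyDuplicated(df$gene_id)) {
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    warning("collapsing ", length(dup),
            " duplicated gene id(s) to longest span: ",
            paste(utils::head(dup, 5), collapse = ", "))
    df <- df[order(df$gene_id, -(df$end - df$start)), ]
    df <- df[!duplicated(df$gene_id), ]
    df <- df[order(df$chrom, df$start), ]
  }
  gr <- .gr0(df$chrom, df$start, df$end, df$strand)
  names(gr) <- df$gene_id
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlengths(gr) <-
      seqlengths[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

.parseBedLine <- function(f, lineno) {
  if (length(f) < 6L) {
    warning("line ", lineno, ": malformed BED record (fewer than 6 fields), skipped")
    return(NULL)
  }
  start <- suppressWarnings(as.numeric(f[2]))
  end <- suppressWarnings(as.numeric(f[3]))
  if (is.na(start) || is.na(end)) {
    warning("line ", lineno, ": non-numeric coordinates, skipped")
    return(NULL)
  }
  if (end <= start) {
    warning("line ", lineno, ": end <= start, record rejected")
    return(NULL)
  }
  if (!f[6] %in% c("+", "-")) {
    warning("line ", lineno, ": invalid strand '", f[6], "', skipped")
    return(NULL)
  }
  list(gene_id = f[4], chrom = f[1], start = start, end = end,
       strand = f[6])
}

.parseGtfLine <- function(f, lineno) {
  if (length(f) < 9L) {
    warning("line ", lineno, ": malformed GTF record, skipped")
    return(NULL)
  }
  if (!f[3] %in% c("gene")) return(NULL)
  start <- suppressWarnings(as.numeric(f[4]))
  end <- suppressWarnings(as.numeric(f[5]))
  if (is.na(start) || is.na(end)) {
    warning("line ", lineno, ": non-numeric coordinates, skipped")
    return(NULL)
  }
  start0 <- start - 1   # GTF is 1-based closed
  if (end <= start0) {
    warning("line ", lineno, ": end <= start, record rejected")
    return(NULL)
  }
  if (!f[7] %in% c("+", "-")) {
    warning("line ", lineno, ": invalid strand '", f[7], "', skipped")
    return(NULL)
  }
  m <- regmatches(f[9], regexec('gene_id[ =]+"?([^";]+)"?', f[9]))[[1]]
  if (length(m) < 2L) {
    warning("line ", lineno, ": no gene_id attribute, skipped")
    return(NULL)
  }
  list(gene_id = m[2], chrom = f[1], start = start0, end = end,
       strand = f[7])
}

#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path Path to the file.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  setNames(df$length, df$chrom)
}

#' Quantification regions derived from a gene model
#'
#' `geneBody()` returns the TSS-to-TTS span (introns included), identical for
#' both strands as a genomic interval. `tssWindow()` returns the window of
#' `2 * halfWidth` bp centered on the strand-aware TSS (the `start`
#' coordinate for `+` genes, the `end` coordinate for `-` genes), clipped at
#' chromosome bounds. `flankingRegions()` returns an upstream and a
#' downstream flank, each as long as the gene body, oriented in
#' transcriptional direction (upstream is 5' of the TSS) and clipped at
#' chromosome bounds; a flank clipped away entirely is returned as a
#' zero-width range.
#'
#' @param genes A named `GRanges` of gene spans as returned by
#'   [readGeneModels()].
#' @param halfWidth Half-width of the TSS window in bp (default 2500, i.e.
#'   TSS +/- 2.5 kb).
#' @param seqlengths Optional named chromosome lengths used for clipping; if
#'   missing, taken from `seqlengths(genes)` when set, otherwise no right
#'   clipping is applied.
#' @return A `GRanges` parallel to `genes` (for `flankingRegions()` a list
#'   with elements `upstream` and `downstream`), with a `region` metadata
#'   column labelling the interval.
#' @examples
#' g <- readGeneModelsFromDf(data.frame(gene_id = "g1", chrom = "chr1",
#'                                      start = 10000, end = 20000,
#'                                      strand = "+"))
#' geneBody(g)
#' tssWindow(g)
#' flankingRegions(g)
#' @name gene-regions
NULL

.resolveSeqlengths <- function(genes, seqlengths) {
  if (!is.null(seqlengths)) return(seqlengths)
  sl <- GenomeInfoDb::seqlengths(genes)
  if (length(sl) && !all(is.na(sl))) return(sl)
  NULL
}

.clip0 <- function(s0, e0, chrom, seqlengths) {
  s0 <- pmax(s0, 0)
  if (!is.null(seqlengths)) {
    len <- unname(seqlengths[chrom])
    if (anyNA(len)) stop("missing chromosome length for: ",
                         paste(unique(chrom[is.na(len)]), collapse = ", "))
    e0 <- pmin(e0, len)
  }
  e0 <- pmax(e0, s0)   # zero-width when clipped away
  list(s0 = s0, e0 = e0)
}

#' @rdname gene-regions
#' @export
geneBody <- function(genes) {
  body <- .gr0(as.character(seqnames(genes)), .start0(genes), .end0(genes),
               as.character(strand(genes)))
  names(body) <- names(genes)
  mcols(body)$region <- "gene_body"
  body
}

#' @rdname gene-regions
#' @export
tssWindow <- function(genes, halfWidth = 2500, seqlengths = NULL) {
  stopifnot(halfWidth > 0)
  seqlengths <- .resolveSeqlengths(genes, seqlengths)
  plus <- as.character(strand(genes)) == "+"
  tss0 <- ifelse(plus, .start0(genes), .end0(genes))
  cl <- .clip0(tss0 - halfWidth, tss0 + halfWidth,
               as.character(seqnames(genes)), seqlengths)
  if (any(cl$e0 <= cl$s0))
    stop("TSS window entirely off-chromosome for gene(s): ",
         paste(names(genes)[cl$e0 <= cl$s0], collapse = ", "))
  win <- .gr0(as.character(seqnames(genes)), cl$s0, cl$e0,
              as.character(strand(genes)))
  names(win) <- names(genes)
  mcols(win)$region <- "tss_window"
  win
}

#' @rdname gene-regions
#' @export
flankingRegions <- function(genes, seqlengths = NULL) {
  seqlengths <- .resolveSeqlengths(genes, seqlengths)
  chrom <- as.character(seqnames(genes))
  s0 <- .start0(genes); e0 <- .end0(genes)
  len <- e0 - s0
  plus <- as.character(strand(genes)) == "+"
  ## upstream = 5' of TSS, downstream = 3' of TTS, in transcriptional sense
  upS <- ifelse(plus, s0 - len, e0)
  upE <- ifelse(plus, s0, e0 + len)
  dnS <- ifelse(plus, e0, s0 - len)
  dnE <- ifelse(plus, e0 + len, s0)
  up <- .clip0(upS, upE, chrom, seqlengths)
  dn <- .clip0(dnS, dnE, chrom, seqlengths)
  upstream <- .gr0(chrom, up$s0, up$e0, as.character(strand(genes)))
  downstream <- .gr0(chrom, dn$s0, dn$e0, as.character(strand(genes)))
  names(upstream) <- names(downstream) <- names(genes)
  mcols(upstream)$region <- "upstream"
  mcols(downstream)$region <- "downstream"
  list(upstream = upstream, downstream = downstream)
}

#' Build gene models from a data frame
#'
#' Convenience constructor used by the simulator and in examples; columns
#' `gene_id`, `chrom`, `start`, `end` (0-based half-open), `strand`.
#'
#' @param df Data frame with the columns above.
#' @param seqlengths Optional named chromosome lengths.
#' @return A named `GRanges`.
#' @export
readGeneModelsFromDf <- function(df, seqlengths = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(df)))
  if (any(df$end <= df$start)) stop("end <= start in gene model data frame")
  gr <- .gr0(df$chrom, df$start, df$end, df$strand)
  names(gr) <- df$gene_id
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Write gene models to BED6
#'
#' @param genes Named `GRanges` of gene spans.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGeneModelsBed <- function(genes, path) {
  df <- data.frame(chrom = as.character(seqnames(genes)),
                   start = format(.start0(genes), scientific = FALSE,
                                  trim = TRUE),
                   end = format(.end0(genes), scientific = FALSE,
                                trim = TRUE),
                   name = names(genes), score = 0,
                   strand = as.character(strand(genes)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
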