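#' @import methods
#' @importFrom stats sd median lowess rnorm rpois runif cutree hclust dist
#'   as.dist cor setNames quantile
#' @importFrom utils read.table write.table packageVersion
NULL

#' SignalTrack: binned genome-wide coverage
#'
#' A `SignalTrack` holds one coverage value per fixed-width genomic bin, per
#' chromosome. Bin `i` (1-based index) of a chromosome covers the 0-based
#' half-open interval `[(i-1)*binSize, i*binSize)`; the last bin may be
#' partial. The library size (total read count or total signal) is carried
#' along so tracks from libraries of different depths can be rescaled to a
#' common effective total before comparison.
#'
#' @slot bins Named list of numeric vectors, one per chromosome, one value
#'   per bin.
#' @slot binSize Integer scalar, bin width in bp.
#' @slot librarySize Numeric scalar, total read count or total signal.
#' @slot sampleLabel Character scalar identifying the sample (e.g. a time
#'   point or condition).
#' @slot seqlengths Named numeric vector of chromosome lengths in bp.
#'
#' @aliases SignalTrack-class
#' @exportClass SignalTrack
setClass("SignalTrack",
  representation(
    bins = "list",
    binSize = "integer",
    librarySize = "numeric",
    sampleLabel = "character",
    seqlengths = "numeric"
  )
)

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize <= 0L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (is.null(names(object@bins)) || is.null(names(object@seqlengths)) ||
      !identical(names(object@bins), names(object@seqlengths)))
    msg <- c(msg, "names of bins and seqlengths must match")
  if (length(msg) == 0L) {
    expected <- ceiling(object@seqlengths / as.numeric(object@binSize))
    got <- vapply(object@bins, length, integer(1))
    if (!all(got == expected))
      msg <- c(msg, "each chromosome must have ceiling(seqlength/binSize) bins")
    if (any(vapply(object@bins, function(v) anyNA(v) || any(v < 0),
                   logical(1))))
      msg <- c(msg, "bin values must be non-negative and non-missing")
  }
  if (length(object@librarySize) != 1L || object@librarySize < 0)
    msg <- c(msg, "librarySize must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct a SignalTrack
#'
#' @param bins Named list of per-chromosome numeric bin-value vectors.
#' @param binSize Bin width in bp.
#' @param seqlengths Named vector of chromosome lengths in bp (names must
#'   match `bins`).
#' @param sampleLabel Label for the sample the track was derived from.
#' @param librarySize Total read count or signal; defaults to the sum of all
#'   bin values.
#' @return A [SignalTrack-class] object.
#' @examples
#' SignalTrack(list(chr1 = c(1, 2, 3)), binSize = 1000,
#'             seqlengths = c(chr1 = 3000), sampleLabel = "day0")
#' @export
SignalTrack <- function(bins, binSize, seqlengths, sampleLabel = "",
                        librarySize = sum(unlist(bins, use.names = FALSE))) {
  new("SignalTrack",
      bins = lapply(bins, as.numeric),
      binSize = as.integer(binSize),
      librarySize = as.numeric(librarySize),
      sampleLabel = as.character(sampleLabel),
      seqlengths = setNames(as.numeric(seqlengths), names(seqlengths)))
}

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack '", object@sampleLabel, "': ",
      length(object@bins), " chromosome(s), binSize=", object@binSize,
      " bp, librarySize=", format(object@librarySize), "\n", sep = "")
  tot <- sum(vapply(object@bins, length, integer(1)))
  cat("  ", tot, " bins in total\n", sep = "")
})

#' MetageneProfile: length-normalized per-gene signal vector
#'
#' Signal resampled onto a normalized coordinate axis in which the gene body
#' spans positions `[0, 1]` and each flank spans one gene length (upstream
#' `[-1, 0]`, downstream `[1, 2]`), so genes of different sizes are
#' comparable. With the default 200 points per segment the profile holds
#' exactly 600 ordered values: upstream, body, downstream, always in
#' transcriptional (5' to 3') orientation. Positions whose genomic span falls
#' entirely off the chromosome are `NA` and are excluded from the stored mean
#' and standard deviation.
#'
#' @slot geneId Character scalar.
#' @slot values Numeric vector of length `3 * pointsPerSegment`.
#' @slot pointsPerSegment Integer, points per segment (default 200).
#' @slot mean Numeric, mean of the non-missing values.
#' @slot sd Numeric, standard deviation of the non-missing values.
#'
#' @aliases MetageneProfile-class
#' @exportClass MetageneProfile
setClass("MetageneProfile",
  representation(
    geneId = "character",
    values = "numeric",
    pointsPerSegment = "integer",
    mean = "numeric",
    sd = "numeric"
  )
)

setValidity("MetageneProfile", function(object) {
  msg <- character()
  pps <- object@pointsPerSegment
  if (length(pps) != 1L || pps < 1L)
    msg <- c(msg, "pointsPerSegment must be a single positive integer")
  else if (length(object@values) != 3L * pps)
    msg <- c(msg, "values must have length 3 * pointsPerSegment")
  v <- object@values[!is.na(object@values)]
  if (length(v)) {
    if (abs(mean(v) - object@mean) > 1e-9)
      msg <- c(msg, "stored mean does not match values")
    if (length(v) > 1L && abs(sd(v) - object@sd) > 1e-9)
      msg <- c(msg, "stored sd does not match values")
  }
  if (length(msg)) msg else TRUE
})

MetageneProfile <- function(geneId, values, pointsPerSegment) {
  v <- values[!is.na(values)]
  new("MetageneProfile",
      geneId = as.character(geneId),
      values = as.numeric(values),
      pointsPerSegment = as.integer(pointsPerSegment),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1L) sd(v) else NA_real_)
}

setMethod("show", "MetageneProfile", function(object) {
  cat("MetageneProfile for gene '", object@geneId, "': ",
      length(object@values), " points (", object@pointsPerSegment,
      " per segment), mean=", signif(object@mean, 4),
      ", sd=", signif(object@sd, 4), "\n", sep = "")
})

#' ClusterResult: hierarchical clustering of per-gene profiles
#'
#' Wraps the merge tree, the dendrogram leaf order, and the flat cluster
#' labels obtained by cutting the tree into `k` groups.
#'
#' @slot tree The underlying `hclust` object.
#' @slot labels Named integer vector of cluster ids (1..k), one per gene.
#' @slot order Integer vector: dendrogram leaf order (row indices of the
#'   input matrix).
#' @slot k Integer, number of clusters the tree was cut into.
#'
#' @aliases ClusterResult-class
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(
    tree = "ANY",
    labels = "integer",
    order = "integer",
    k = "integer"
  )
)

setValidity("ClusterResult", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(object@order) != n)
    msg <- c(msg, "order must have one entry per gene")
  if (inherits(object@tree, "hclust") && nrow(object@tree$merge) != n - 1L)
    msg <- c(msg, "tree must contain n - 1 merges")
  if (n && max(object@labels) > object@k)
    msg <- c(msg, "labels must lie in 1..k")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: ", length(object@labels), " genes cut into k=",
      object@k, " clusters\n", sep = "")
  print(table(cluster = object@labels))
})
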