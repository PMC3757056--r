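#' Accessors for SignalTrack
#'
#' `binSize()`, `librarySize()`, `sampleLabel()` and `binValues()` retrieve
#' the corresponding slots; `seqlengths()` (from GenomeInfoDb) returns the
#' chromosome lengths.
#'
#' @param x,object A [SignalTrack-class].
#' @return The slot value; `binValues()` returns the named per-chromosome
#'   list of bin values.
#' @name SignalTrack-accessors
#' @examples
#' tr <- SignalTrack(list(chr1 = c(0, 5)), 1000, c(chr1 = 2000), "day2")
#' binSize(tr)
#' librarySize(tr)
#' binValues(tr)$chr1
NULL

#' @rdname SignalTrack-accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname SignalTrack-accessors
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname SignalTrack-accessors
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @rdname SignalTrack-accessors
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))

#' @rdname SignalTrack-accessors
#' @export
setMethod("binSize", "SignalTrack", function(x) x@binSize)

#' @rdname SignalTrack-accessors
#' @export
setMethod("librarySize", "SignalTrack", function(x) x@librarySize)

#' @rdname SignalTrack-accessors
#' @export
setMethod("sampleLabel", "SignalTrack", function(x) x@sampleLabel)

#' @rdname SignalTrack-accessors
#' @export
setMethod("binValues", "SignalTrack", function(x) x@bins)

#' @rdname SignalTrack-accessors
#' @importFrom GenomeInfoDb seqlengths
#' @exportMethod seqlengths
setMethod("seqlengths", "SignalTrack", function(x) x@seqlengths)

#' Accessors for MetageneProfile
#'
#' @param x A [MetageneProfile-class].
#' @return `profileValues()` the ordered value vector; `geneId()` the gene
#'   identifier; `pointsPerSegment()` the per-segment resolution.
#' @name MetageneProfile-accessors
NULL

#' @rdname MetageneProfile-accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname MetageneProfile-accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname MetageneProfile-accessors
#' @export
setGeneric("pointsPerSegment", function(x) standardGeneric("pointsPerSegment"))

#' @rdname MetageneProfile-accessors
#' @export
setMethod("profileValues", "MetageneProfile", function(x) x@values)

#' @rdname MetageneProfile-accessors
#' @export
setMethod("geneId", "MetageneProfile", function(x) x@geneId)

#' @rdname MetageneProfile-accessors
#' @export
setMethod("pointsPerSegment", "MetageneProfile", function(x) x@pointsPerSegment)

#' Accessors for ClusterResult
#'
#' @param x A [ClusterResult-class].
#' @return `clusterLabels()` the named integer label vector; `leafOrder()`
#'   the dendrogram leaf order; `clusterTree()` the underlying `hclust`.
#' @name ClusterResult-accessors
NULL

#' @rdname ClusterResult-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterResult-accessors
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))

#' @rdname ClusterResult-accessors
#' @export
setGeneric("clusterTree", function(x) standardGeneric("clusterTree"))

#' @rdname ClusterResult-accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname ClusterResult-accessors
#' @export
setMethod("leafOrder", "ClusterResult", function(x) x@order)

#' @rdname ClusterResult-accessors
#' @export
setMethod("clusterTree", "ClusterResult", function(x) x@tree)
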