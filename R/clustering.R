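#' Hierarchical clustering of per-gene profiles
#'
#' Clusters rows of a genes x features matrix (a spatial metagene profile or
#' a temporal region-mean profile) with agglomerative hierarchical
#' clustering, and cuts the tree into `k` flat clusters. The result is
#' deterministic for a fixed input and settings.
#'
#' @param mat Numeric matrix without missing values, rows named by gene.
#' @param metric `"euclidean"` or `"correlation"` (distance `1 - r`);
#'   constant rows are rejected for the correlation metric.
#' @param linkage `"ward"` (Ward's method on squared distances, `ward.D2`),
#'   `"average"` or `"complete"`.
#' @param k Number of clusters to cut the tree into (default 3).
#' @return A [ClusterResult-class].
#' @examples
#' m <- rbind(a = c(0, 0, 1), b = c(0, 0.1, 1.1), c = c(5, 5, 5.2))
#' clusterLabels(hierarchicalCluster(m, k = 2))
#' @export
hierarchicalCluster <- function(mat, metric = c("euclidean", "correlation"),
                                linkage = c("ward", "average", "complete"),
                                k = 3) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  if (anyNA(mat)) stop("matrix contains missing values")
  if (nrow(mat) < k) stop("fewer rows (", nrow(mat), ") than clusters (",
                          k, ")")
  d <- if (metric == "euclidean") {
    dist(mat)
  } else {
    if (any(apply(mat, 1, sd) == 0))
      stop("constant rows are not usable with the correlation metric")
    as.dist(1 - cor(t(mat)))
  }
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  tree <- hclust(d, method = method)
  labels <- cutree(tree, k = k)
  new("ClusterResult", tree = tree,
      labels = setNames(as.integer(labels), rownames(mat)),
      order = as.integer(tree$order), k = as.integer(k))
}

#' Temporal profile matrix for clustering
#'
#' Z-scores each gene's time course of region-mean signal (row mean 0, sd 1)
#' so that clustering groups genes by the shape of their temporal change
#' rather than by absolute level. Flat rows (sd of 0) cannot be z-scored and
#' are dropped with a message.
#'
#' @param signalMatrix Numeric matrix, rows = genes (named), columns = time
#'   points; every gene must have a value at every time point.
#' @return Z-scored matrix, possibly with fewer rows.
#' @export
temporalProfileMatrix <- function(signalMatrix) {
  if (anyNA(signalMatrix)) stop("missing values in signal matrix")
  sds <- apply(signalMatrix, 1, sd)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " flat gene row(s): ",
            paste(utils::head(rownames(signalMatrix)[sds == 0], 5),
                  collapse = ", "))
    signalMatrix <- signalMatrix[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (signalMatrix - rowMeans(signalMatrix)) / sds
}

#' Export a clustered heat-map matrix
#'
#' Writes the clustered matrix in dendrogram leaf order as tab-delimited
#' text, with the cluster label and, optionally, a per-gene expression
#' direction annotation, for external heat-map plotting.
#'
#' @param result A [ClusterResult-class].
#' @param mat The matrix that was clustered (rows named by gene).
#' @param annotation Optional named character vector (e.g. expression
#'   direction `"up"`/`"down"`) covering all genes.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
exportHeatmapMatrix <- function(result, mat, annotation = NULL, path) {
  ord <- leafOrder(result)
  genes <- rownames(mat)[ord]
  df <- data.frame(gene_id = genes,
                   cluster = unname(clusterLabels(result)[genes]),
                   mat[ord, , drop = FALSE], row.names = NULL,
                   check.names = FALSE)
  if (!is.null(annotation)) {
    if (!all(genes %in% names(annotation)))
      stop("annotation must cover all clustered genes")
    df$expr_direction <- unname(annotation[genes])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
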