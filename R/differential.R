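#' Fold-change series relative to the first time point
#'
#' Ratios `(v_t + pseudocount) / (v_0 + pseudocount)` for every time point of
#' a series; the ratio at the baseline is exactly 1. The pseudocount guards
#' genes with a zero baseline.
#'
#' @param values Non-negative numeric series (signal or FPKM), baseline
#'   first.
#' @param pseudocount Added to numerator and denominator (default 0.5 signal
#'   units).
#' @return Numeric vector of per-time ratios, same length and names as
#'   `values`.
#' @examples
#' foldChangeSeries(c(2, 2, 2, 2, 4), pseudocount = 0)   # 1 1 1 1 2
#' foldChangeSeries(c(0, 0, 0, 1, 2), pseudocount = 0.5) # 1 1 1 3 5
#' @export
foldChangeSeries <- function(values, pseudocount = 0.5) {
  if (any(values < 0)) stop("negative values in time course")
  if (values[1] + pseudocount <= 0)
    stop("baseline + pseudocount must be positive")
  (values + pseudocount) / (values[1] + pseudocount)
}

#' Call a gene differentially methylated from its fold-change series
#'
#' A gene is differential when some post-baseline time point shows at least
#' a `threshold`-fold change in either direction (ratio >= `threshold` or
#' <= `1/threshold`).
#'
#' @param ratios Per-time fold-change ratios (baseline first, equal to 1).
#' @param threshold Fold-change cutoff > 1 (default 2).
#' @return List with `fold_changes`, `max_abs_log2fc`, `is_differential`
#'   and `direction` (`"up"`, `"down"`, `"mixed"`, or `"none"`).
#' @examples
#' callDifferential(c(1, 1.1, 1.5, 2.1))$is_differential   # TRUE, up
#' callDifferential(c(1, 0.9, 0.8, 0.6))$is_differential   # FALSE at 2-fold
#' @export
callDifferential <- function(ratios, threshold = 2) {
  stopifnot(threshold > 1)
  post <- ratios[-1]
  up <- any(post >= threshold)
  down <- any(post <= 1 / threshold)
  list(fold_changes = ratios,
       max_abs_log2fc = max(abs(log2(ratios))),
       is_differential = up || down,
       direction = if (up && down) "mixed" else if (up) "up"
                   else if (down) "down" else "none")
}

#' Differential-methylation calls for a region signal matrix
#'
#' Applies [foldChangeSeries()] and [callDifferential()] row-wise to a genes
#' x time-points matrix of region means.
#'
#' @param signalMatrix Numeric matrix, rows = genes (named), columns = time
#'   points, baseline first.
#' @param threshold Fold-change cutoff (default 2).
#' @param pseudocount Pseudocount for the ratios (default 0.5).
#' @return Data frame with one row per gene: per-time fold changes,
#'   `max_abs_log2fc`, `is_differential`, `direction`.
#' @export
differentialTable <- function(signalMatrix, threshold = 2,
                              pseudocount = 0.5) {
  calls <- lapply(seq_len(nrow(signalMatrix)), function(i)
    callDifferential(foldChangeSeries(signalMatrix[i, ], pseudocount),
                     threshold))
  fc <- t(vapply(calls, `[[`, numeric(ncol(signalMatrix)), "fold_changes"))
  colnames(fc) <- paste0("fc_", colnames(signalMatrix))
  data.frame(gene_id = rownames(signalMatrix), fc,
             max_abs_log2fc = vapply(calls, `[[`, numeric(1),
                                     "max_abs_log2fc"),
             is_differential = vapply(calls, `[[`, logical(1),
                                      "is_differential"),
             direction = vapply(calls, `[[`, character(1), "direction"),
             row.names = NULL)
}

#' Intersect differentially methylated and differentially expressed genes
#'
#' @param me3Genes Character vector of differentially methylated gene ids.
#' @param deGenes Character vector of differentially expressed gene ids.
#' @return List with `joint` (intersection), and the Venn counts `n_me3`,
#'   `n_de`, `n_joint`.
#' @examples
#' intersectRegulated(c("a", "b", "c"), c("b", "c", "d"))$joint  # b, c
#' @export
intersectRegulated <- function(me3Genes, deGenes) {
  joint <- intersect(me3Genes, deGenes)
  list(joint = joint, n_me3 = length(unique(me3Genes)),
       n_de = length(unique(deGenes)), n_joint = length(joint))
}

#' Simple fold-change expression caller
#'
#' Flags genes whose FPKM range over the time course spans at least
#' `minFold` (max/min ratio with pseudocount) and whose peak FPKM reaches
#' `minFpkm`. This is a deliberately plain caller used to drive synthetic
#' runs end to end; analyses of real data should supply an externally
#' derived differentially-expressed gene list instead.
#'
#' @param fpkmMatrix Numeric matrix, rows = genes (named), columns = time
#'   points.
#' @param minFold Minimum max/min fold change (default 2).
#' @param minFpkm Minimum peak FPKM (default 1).
#' @param pseudocount Pseudocount for the ratio (default 0.5).
#' @return Character vector of called gene ids.
#' @export
simpleExpressionChangeCaller <- function(fpkmMatrix, minFold = 2,
                                         minFpkm = 1, pseudocount = 0.5) {
  if (any(fpkmMatrix < 0)) stop("negative FPKM")
  hi <- apply(fpkmMatrix, 1, max)
  lo <- apply(fpkmMatrix, 1, min)
  called <- (hi + pseudocount) / (lo + pseudocount) >= minFold &
    hi >= minFpkm
  rownames(fpkmMatrix)[called]
}

#' Normalize an expression table to a reference gene
#'
#' Rescales each sample (column) so the reference gene has the same value in
#' every sample (that of the first sample); within-sample ratios are
#' unchanged.
#'
#' @param exprTable Numeric matrix, rows = genes (named), columns = samples.
#' @param referenceGene Gene id of the reference (e.g. `"Arbp"`); must be
#'   present with a positive value in every sample.
#' @return Rescaled matrix of the same shape.
#' @export
normalizeExpressionToReference <- function(exprTable, referenceGene) {
  if (!referenceGene %in% rownames(exprTable))
    stop("reference gene '", referenceGene, "' absent from table")
  ref <- exprTable[referenceGene, ]
  if (any(ref <= 0)) stop("reference gene must be positive in every sample")
  sweep(exprTable, 2, ref[1] / ref, `*`)
}
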