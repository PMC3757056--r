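#' Relative expression by the 2^-ddCt method
#'
#' Computes `2^-[(Ct_target,test - Ct_ref,test) - (Ct_target,cal -
#' Ct_ref,cal)]`: the expression of a target gene in a test sample relative
#' to a calibrator sample, each normalized to a reference gene (e.g. Arbp).
#' Amplification efficiency is taken as 2 per cycle.
#'
#' @param ctTargetTest,ctRefTest Ct of target and reference gene in the
#'   test sample.
#' @param ctTargetCal,ctRefCal Ct of target and reference gene in the
#'   calibrator sample.
#' @return Fold change (unitless).
#' @examples
#' ddctFoldChange(20, 18, 22, 19)  # ddCt = -1 -> 2
#' @export
ddctFoldChange <- function(ctTargetTest, ctRefTest, ctTargetCal, ctRefCal) {
  stopifnot(ctTargetTest > 0, ctRefTest > 0, ctTargetCal > 0, ctRefCal > 0)
  ddct <- (ctTargetTest - ctRefTest) - (ctTargetCal - ctRefCal)
  2^(-ddct)
}

#' ChIP enrichment as percent of input
#'
#' `100 * 2^-(Ct_IP - (Ct_input - dilutionCorrection))`. The default of 0
#' correction cycles assumes the input Ct has already been adjusted for any
#' input dilution; pass e.g. `log2(100/1)` cycles for a 1% input aliquot.
#' Strictly decreasing in the IP Ct.
#'
#' @param ctIp Ct of the immunoprecipitated sample.
#' @param ctInput Ct of the input sample.
#' @param dilutionCorrection Cycles subtracted from the input Ct (default
#'   0).
#' @return Percent of input.
#' @examples
#' percentInput(25, 25)      # 100
#' percentInput(35, 25)      # ~0.0977
#' @export
percentInput <- function(ctIp, ctInput, dilutionCorrection = 0) {
  stopifnot(ctIp > 0, ctInput > 0)
  100 * 2^(-(ctIp - (ctInput - dilutionCorrection)))
}

#' Read or write a Ct table
#'
#' Tab-delimited with columns `sample_id`, `target`, `ct`.
#'
#' @param path Path to the file.
#' @return `readCtTable()` a data frame; `writeCtTable()` invisibly `path`.
#' @export
readCtTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "numeric"))
  if (!all(c("sample_id", "target", "ct") %in% names(df)))
    stop("Ct table must have columns sample_id, target, ct")
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  df
}

#' @rdname readCtTable
#' @param ctTable Data frame with columns `sample_id`, `target`, `ct`.
#' @export
writeCtTable <- function(ctTable, path) {
  write.table(ctTable, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
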