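#' Read and write a flat key=value pipeline configuration
#'
#' One `key=value` pair per line; comma-separated values become vectors and
#' fully numeric values are converted to numbers. `writePipelineConfig()`
#' and `readPipelineConfig()` round-trip a configuration losslessly.
#'
#' @param path Path to the configuration file.
#' @return Named list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  cfg <- lapply(kv, function(p) {
    v <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(cfg) <- vapply(kv, function(p) trimws(p[1]), character(1))
  cfg
}

#' @rdname readPipelineConfig
#' @param config Named list of scalar or vector values.
#' @export
writePipelineConfig <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) paste(sprintf("%.15g", v), collapse = ",")
    else paste(v, collapse = ",")
  }, character(1))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

.defaultPipelineSettings <- function() {
  list(bin_size = 1000, tss_half_width = 2500, fold_threshold = 2,
       pseudocount = 0.5, cluster_k = 3, flat_tolerance = 0.01,
       min_fpkm = 1, seed = 1, times = c(0, 2, 4, 7, 12))
}

.validatePipelineConfig <- function(config) {
  for (f in c("annotation", "chrom_sizes", "fpkm", "me3_tracks"))
    if (is.null(config[[f]]))
      stop("configuration field '", f, "' is required")
  for (f in c("bin_size", "tss_half_width", "fold_threshold",
              "pseudocount", "cluster_k", "flat_tolerance", "min_fpkm"))
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1L ||
        config[[f]] <= 0)
      stop("configuration field '", f, "' must be a positive number")
  if (length(config$me3_tracks) != length(config$times))
    stop("configuration must name one me3 track per time point")
  for (p in c(config$annotation, config$chrom_sizes, config$fpkm,
              config$me3_tracks, config$de_genes))
    if (!file.exists(p)) stop("input file not found: ", p)
  config
}

#' Read an FPKM table
#'
#' Tab-delimited, first column `gene_id`, one column per time point.
#'
#' @param path Path to the table.
#' @return Numeric matrix, rows named by gene.
#' @export
readFpkmTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("negative FPKM in ", path)
  m
}

#' Run the timing-analysis pipeline
#'
#' Executes the full analysis on file inputs: quantify mean H3K27me3 over
#' gene bodies and TSS windows at every time point (after equalizing
#' library sizes), call differentially methylated genes by fold change,
#' intersect them with differentially expressed genes, cluster the temporal
#' profiles of the jointly regulated genes, compute per-gene t-half for
#' expression and H3K27me3, and summarize the lead/lag. Per-stage tables, a
#' Venn summary, cluster assignments, t-half tables and a run log (package
#' version, configuration, seed) are written to the output directory. A
#' stage failure leaves a `FAILED` marker naming the stage.
#'
#' @param config Named list or path to a key=value file (see
#'   [readPipelineConfig()]). Required fields: `annotation` (BED),
#'   `chrom_sizes`, `fpkm` (table), `me3_tracks` (bedGraph paths, one per
#'   time point, in time order). Optional: `de_genes` (one gene id per
#'   line; without it the built-in fold-change expression caller is used),
#'   `times`, `bin_size`, `tss_half_width`, `fold_threshold`,
#'   `pseudocount`, `cluster_k`, `flat_tolerance`, `min_fpkm`, `seed`.
#' @param outDir Output directory.
#' @return Invisibly, a list with the per-stage results (`bodySignal`,
#'   `tssSignal`, `bodyDifferential`, `tssDifferential`, `deGenes`,
#'   `jointBody`, `jointTss`, `clusters`, `exprTHalf`, `me3THalf`,
#'   `timing`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- readPipelineConfig(config)
  defaults <- .defaultPipelineSettings()
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config <- .validatePipelineConfig(config)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory ", outDir)
  stage <- "setup"
  res <- tryCatch({
    stage <- "load"
    sizes <- readChromSizes(config$chrom_sizes)
    genes <- readGeneModels(config$annotation, "bed", seqlengths = sizes)
    fpkm <- readFpkmTable(config$fpkm)
    tracks <- lapply(seq_along(config$me3_tracks), function(i)
      readBedGraph(config$me3_tracks[i], config$bin_size, sizes,
                   sampleLabel = paste0("day", config$times[i])))
    names(tracks) <- paste0("day", config$times)

    stage <- "quantify"
    tracks <- normalizeLibraries(tracks)
    body <- geneBody(genes)
    tss <- tssWindow(genes, halfWidth = config$tss_half_width,
                     seqlengths = sizes)
    bodyMat <- regionSignalMatrix(tracks, body)
    tssMat <- regionSignalMatrix(tracks, tss)
    .writeTsv(data.frame(gene_id = rownames(bodyMat), bodyMat),
              file.path(outDir, "region_means_gene_body.tsv"))
    .writeTsv(data.frame(gene_id = rownames(tssMat), tssMat),
              file.path(outDir, "region_means_tss_window.tsv"))

    stage <- "differential"
    bodyDiff <- differentialTable(bodyMat, config$fold_threshold,
                                  config$pseudocount)
    tssDiff <- differentialTable(tssMat, config$fold_threshold,
                                 config$pseudocount)
    .writeTsv(bodyDiff, file.path(outDir, "differential_gene_body.tsv"))
    .writeTsv(tssDiff, file.path(outDir, "differential_tss_window.tsv"))
    deGenes <- if (!is.null(config$de_genes)) {
      readLines(config$de_genes)
    } else {
      simpleExpressionChangeCaller(fpkm, minFold = config$fold_threshold,
                                   minFpkm = config$min_fpkm,
                                   pseudocount = config$pseudocount)
    }
    writeLines(deGenes, file.path(outDir, "de_genes.txt"))

    stage <- "intersect"
    jointBody <- intersectRegulated(
      bodyDiff$gene_id[bodyDiff$is_differential], deGenes)
    jointTss <- intersectRegulated(
      tssDiff$gene_id[tssDiff$is_differential], deGenes)
    .writeVenn(jointBody, file.path(outDir, "venn_gene_body.txt"))
    .writeVenn(jointTss, file.path(outDir, "venn_tss_window.txt"))

    stage <- "cluster"
    clusters <- NULL
    jb <- jointBody$joint
    if (length(jb) >= config$cluster_k) {
      z <- temporalProfileMatrix(bodyMat[jb, , drop = FALSE])
      clusters <- hierarchicalCluster(z, k = config$cluster_k)
      dir <- setNames(ifelse(fpkm[, ncol(fpkm)] >= fpkm[, 1], "up",
                             "down"), rownames(fpkm))
      exportHeatmapMatrix(clusters, z, annotation = dir,
                          path = file.path(outDir,
                                           "clusters_gene_body.tsv"))
    }

    stage <- "thalf"
    timing <- NULL; exprTh <- NULL; me3Th <- NULL
    if (length(jb) >= 1L) {
      exprTh <- tHalfCohort(fpkm[jb, , drop = FALSE], config$times,
                            flatTolerance = config$flat_tolerance)
      me3Th <- tHalfCohort(bodyMat[jb, , drop = FALSE], config$times,
                           flatTolerance = config$flat_tolerance)
      both <- rbind(cbind(signal = "expression", exprTh),
                    cbind(signal = "h3k27me3", me3Th))
      .writeTsv(both, file.path(outDir, "thalf_gene_body.tsv"))
      timing <- compareTiming(exprTh, me3Th)
      summaryDf <- data.frame(
        median_thalf_expression = medianTHalf(exprTh)$median,
        median_thalf_h3k27me3 = medianTHalf(me3Th)$median,
        median_lag_days = timing$medianDifference,
        fraction_me3_later = timing$fractionPositive,
        n_pairs = timing$nPairs)
      .writeTsv(summaryDf, file.path(outDir, "timing_summary.tsv"))
    }

    stage <- "report"
    log <- c(sprintf("epiTempo version: %s",
                     as.character(packageVersion("epiTempo"))),
             sprintf("seed: %s", config$seed),
             "config:",
             paste0("  ", names(config), "=",
                    vapply(config, paste, character(1), collapse = ",")))
    writeLines(log, file.path(outDir, "run_log.txt"))

    list(bodySignal = bodyMat, tssSignal = tssMat,
         bodyDifferential = bodyDiff, tssDifferential = tssDiff,
         deGenes = deGenes, jointBody = jointBody, jointTss = jointTss,
         clusters = clusters, exprTHalf = exprTh, me3THalf = me3Th,
         timing = timing)
  }, error = function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(outDir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writeVenn <- function(joint, path) {
  writeLines(c(sprintf("n_me3_differential\t%d", joint$n_me3),
               sprintf("n_expression_differential\t%d", joint$n_de),
               sprintf("n_joint\t%d", joint$n_joint)), path)
  invisible(path)
}

#' Pipeline configuration for a simulated fixture bundle
#'
#' Builds a [runPipeline()] configuration pointing at the files written by
#' [writeFixtureBundle()].
#'
#' @param dir Bundle directory.
#' @param ... Overrides for pipeline settings (e.g. `fold_threshold`).
#' @return Named configuration list.
#' @export
bundlePipelineConfig <- function(dir, ...) {
  manifest <- readPipelineConfig(file.path(dir, "manifest.txt"))
  times <- manifest$times
  cfg <- c(list(...), list(
    annotation = file.path(dir, "genes.bed"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    fpkm = file.path(dir, "fpkm.tsv"),
    me3_tracks = file.path(dir, sprintf("me3_day%s.bedgraph", times)),
    times = times,
    bin_size = manifest$binSize,
    seed = manifest$seed))
  cfg[!duplicated(names(cfg))]     # overrides win over bundle defaults
}
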