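#' Simulation configuration
#'
#' Collects every parameter of the synthetic cohort in one list. The
#' defaults encode the study conditions the package is designed around: five
#' sampling days (0, 2, 4, 7, 12), 1-kb bins, a background sequencing depth
#' of 30 expected counts per bin with Poisson noise, 4-fold enrichment
#' effects, and a cohort of 200 genes — 60 with a broad gene-body H3K27me3
#' gain (expression down), 40 with a broad loss (expression up), 20 with a
#' TSS-focal gain (expression down) and 80 unchanged. Transitions are
#' logistic in time; transcription leads chromatin, with expression
#' midpoints of 1.1 d (down genes) and 3.3 d (up genes) against H3K27me3
#' midpoints of 6.9 d (gain) and 4.8 d (loss). Intergenic differential
#' domains with strand-specific unannotated transcription are planted in
#' gene-free zones.
#'
#' @param seed Integer seed fixing all randomness end-to-end.
#' @param nBroadGain,nBroadLoss,nTssGain,nUnchanged Genes per archetype.
#' @param nIntergenic Number of planted intergenic differential domains.
#' @param chromLengths Named vector of chromosome lengths in bp.
#' @param binSize Bin width in bp.
#' @param times Sampling times in days.
#' @param depth Background ChIP depth, expected counts per bin.
#' @param effectFold Enrichment effect size (ratio).
#' @param exprMidDown,exprMidUp Expression transition midpoints (days) for
#'   down- and up-regulated genes.
#' @param me3MidGain,me3MidLoss H3K27me3 transition midpoints (days).
#' @param steepness Logistic steepness k in 1/day.
#' @param exprNoiseSd Standard deviation of the multiplicative lognormal
#'   FPKM noise.
#' @param rnaDepth Background strand-specific RNA coverage, counts per bin.
#' @param rnaAmplitude RNA coverage added by a transcribed intergenic
#'   domain, counts per bin.
#' @param tssSd Standard deviation of the TSS-focal enrichment bump, bp.
#' @param geneLengthRange,gapRange Log-uniform gene length and uniform
#'   intergenic gap ranges, bp.
#' @param baselineFpkmRange Log-uniform baseline FPKM range for regulated
#'   genes.
#' @return Named list of class `simConfig`.
#' @export
simulationConfig <- function(seed = 1,
                             nBroadGain = 60, nBroadLoss = 40,
                             nTssGain = 20, nUnchanged = 80,
                             nIntergenic = 10,
                             chromLengths = c(chr1 = 8e6, chr2 = 8e6),
                             binSize = 1000,
                             times = c(0, 2, 4, 7, 12),
                             depth = 30, effectFold = 4,
                             exprMidDown = 1.1, exprMidUp = 3.3,
                             me3MidGain = 6.9, me3MidLoss = 4.8,
                             steepness = 1.5, exprNoiseSd = 0.1,
                             rnaDepth = 2, rnaAmplitude = 20,
                             tssSd = 1000,
                             geneLengthRange = c(2000, 50000),
                             gapRange = c(2000, 20000),
                             baselineFpkmRange = c(2, 50)) {
  cfg <- as.list(environment())
  stopifnot(cfg$depth > 0, cfg$binSize > 0, cfg$effectFold >= 1,
            all(diff(cfg$times) > 0))
  class(cfg) <- c("simConfig", "list")
  cfg
}

.sigmoid <- function(t, mid, k) 1 / (1 + exp(-k * (t - mid)))

#' Simulate a non-overlapping gene annotation
#'
#' Places genes with log-uniform lengths and uniform intergenic gaps
#' sequentially along the configured chromosomes, with random strands.
#' Deterministic for a fixed seed; errors if the genes do not fit.
#'
#' @param config A [simulationConfig()].
#' @return Named `GRanges` of gene models with `seqlengths` set.
#' @export
simulateAnnotation <- function(config) {
  set.seed(config$seed)
  n <- config$nBroadGain + config$nBroadLoss + config$nTssGain +
    config$nUnchanged
  lens <- round(exp(runif(n, log(config$geneLengthRange[1]),
                          log(config$geneLengthRange[2]))))
  gaps <- round(runif(n, config$gapRange[1], config$gapRange[2]))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  chroms <- names(config$chromLengths)
  df <- data.frame(gene_id = sprintf("gene_%03d", seq_len(n)),
                   chrom = NA_character_, start = NA_real_, end = NA_real_,
                   strand = strands)
  ci <- 1L; cursor <- gaps[1]
  for (i in seq_len(n)) {
    while (cursor + lens[i] + config$gapRange[1] >
             config$chromLengths[[chroms[ci]]]) {
      ci <- ci + 1L
      if (ci > length(chroms))
        stop("genes do not fit on the configured chromosomes; ",
             "increase chromLengths")
      cursor <- gaps[i]
    }
    df$chrom[i] <- chroms[ci]
    df$start[i] <- cursor
    df$end[i] <- cursor + lens[i]
    cursor <- cursor + lens[i] + gaps[i]
  }
  readGeneModelsFromDf(df, config$chromLengths)
}

#' Assign ground-truth dynamics to simulated genes
#'
#' Randomly assigns each gene an archetype (broad gene-body gain or loss of
#' H3K27me3, TSS-focal gain, or unchanged) together with the archetype's
#' transition midpoints, expression direction (inverse to the H3K27me3
#' change) and baseline levels, and plants intergenic differential domains
#' in gene-free zones.
#'
#' @param genes Annotation from [simulateAnnotation()].
#' @param config A [simulationConfig()].
#' @return Data frame (one row per gene, then one per intergenic domain)
#'   with columns `id`, `archetype`, `chrom`, `start`, `end`, `strand`,
#'   `expr_direction`, `expr_midpoint`, `me3_midpoint`, `baseline_fpkm`,
#'   `baseline_me3`, `effect_fold`.
#' @export
simulateGeneTruth <- function(genes, config) {
  set.seed(config$seed + 1L)
  n <- length(genes)
  arch <- sample(rep(c("broad_body_gain", "broad_body_loss",
                       "tss_focal_gain", "unchanged"),
                     c(config$nBroadGain, config$nBroadLoss,
                       config$nTssGain, config$nUnchanged)))
  exprDir <- c(broad_body_gain = "down", broad_body_loss = "up",
               tss_focal_gain = "down", unchanged = "flat")[arch]
  exprMid <- ifelse(exprDir == "down", config$exprMidDown,
                    ifelse(exprDir == "up", config$exprMidUp, NA))
  me3Mid <- ifelse(arch %in% c("broad_body_gain", "tss_focal_gain"),
                   config$me3MidGain,
                   ifelse(arch == "broad_body_loss", config$me3MidLoss,
                          NA))
  baseFpkm <- exp(runif(n, log(config$baselineFpkmRange[1]),
                        log(config$baselineFpkmRange[2])))
  ## unchanged genes span all five expression classes, including FPKM = 0
  unch <- arch == "unchanged"
  baseFpkm[unch] <- ifelse(runif(sum(unch)) < 0.2, 0,
                           exp(runif(sum(unch), log(0.1), log(200))))
  truth <- data.frame(
    id = names(genes),
    archetype = arch,
    chrom = as.character(seqnames(genes)),
    start = .start0(genes), end = .end0(genes),
    strand = as.character(strand(genes)),
    expr_direction = unname(exprDir),
    expr_midpoint = unname(exprMid),
    me3_midpoint = unname(me3Mid),
    baseline_fpkm = baseFpkm,
    baseline_me3 = config$depth,
    effect_fold = config$effectFold)
  rbind(truth, .planIntergenicDomains(genes, config))
}

## Intergenic domains: bin-aligned runs of 3-6 bins placed inside intergenic
## gaps, at least one bin away from any gene. Half gain, half lose H3K27me3;
## the associated strand-specific transcription changes inversely and
## earlier (expression midpoints).
.planIntergenicDomains <- function(genes, config) {
  if (config$nIntergenic == 0) return(NULL)
  bs <- config$binSize
  mask <- intergenicMask(genes, config$chromLengths)
  widths <- sample(3:6, config$nIntergenic, replace = TRUE)
  ## candidate gaps able to hold the widest domain plus 1-bin margins
  ok <- (.end0(mask) - .start0(mask)) >= (max(widths) + 4) * bs
  gaps <- mask[ok]
  if (length(gaps) < config$nIntergenic)
    stop("not enough intergenic room for ", config$nIntergenic, " domains")
  pick <- sample(length(gaps), config$nIntergenic)
  dirs <- rep(c("gain", "loss"), length.out = config$nIntergenic)
  rows <- lapply(seq_len(config$nIntergenic), function(j) {
    g <- gaps[pick[j]]
    firstBin <- ceiling(.start0(g) / bs) + 1          # 1-bin margin
    lastBin <- floor(.end0(g) / bs) - 1 - widths[j]
    startBin <- if (lastBin > firstBin)
      sample(firstBin:lastBin, 1) else firstBin
    gain <- dirs[j] == "gain"
    data.frame(
      id = sprintf("igd_%02d", j),
      archetype = "intergenic_domain",
      chrom = as.character(seqnames(g)),
      start = startBin * bs, end = (startBin + widths[j]) * bs,
      strand = sample(c("+", "-"), 1),
      expr_direction = if (gain) "down" else "up",
      expr_midpoint = if (gain) config$exprMidDown else config$exprMidUp,
      me3_midpoint = if (gain) config$me3MidGain else config$me3MidLoss,
      baseline_fpkm = NA_real_,
      baseline_me3 = config$depth,
      effect_fold = config$effectFold)
  })
  do.call(rbind, rows)
}

#' Simulate FPKM time courses
#'
#' The noiseless mean of each regulated gene follows a logistic transition
#' between its baseline and `baseline * effect_fold` (up) or
#' `baseline / effect_fold` (down), with the gene's expression midpoint and
#' the configured steepness; unchanged genes stay at baseline.
#' Multiplicative lognormal noise is applied.
#'
#' @param truth Truth table from [simulateGeneTruth()].
#' @param config A [simulationConfig()].
#' @param noiseless If `TRUE`, return expected values without noise.
#' @return Numeric matrix genes x times of FPKM, rows named by gene,
#'   columns `day_<t>`.
#' @export
simulateExpression <- function(truth, config, noiseless = FALSE) {
  set.seed(config$seed + 2L)
  truth <- truth[truth$archetype != "intergenic_domain", , drop = FALSE]
  f <- config$effectFold
  mat <- t(vapply(seq_len(nrow(truth)), function(i) {
    base <- truth$baseline_fpkm[i]
    dir <- truth$expr_direction[i]
    if (dir == "flat") return(rep(base, length(config$times)))
    s <- .sigmoid(config$times, truth$expr_midpoint[i], config$steepness)
    if (dir == "down") base * (1 - (1 - 1 / f) * s)
    else base * (1 + (f - 1) * s)
  }, numeric(length(config$times))))
  if (!noiseless)
    mat <- mat * exp(matrix(rnorm(length(mat), 0, config$exprNoiseSd),
                            nrow = nrow(mat)))
  rownames(mat) <- truth$id
  colnames(mat) <- paste0("day_", config$times)
  mat
}

## Expected (noiseless) per-bin H3K27me3 counts for one chromosome and one
## time point.
.me3Expected <- function(chrom, t, truth, config) {
  bs <- config$binSize
  n <- ceiling(config$chromLengths[[chrom]] / bs)
  lambda <- rep(config$depth, n)
  f <- config$effectFold
  rows <- truth[truth$chrom == chrom &
                  truth$archetype != "unchanged", , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    arch <- rows$archetype[i]
    s <- .sigmoid(t, rows$me3_midpoint[i], config$steepness)
    amp <- config$depth * (f - 1) *
      if (arch %in% c("broad_body_gain", "tss_focal_gain")) s
      else if (arch == "broad_body_loss") (1 - s)
      else if (rows$expr_direction[i] == "down") s else (1 - s)
    if (arch == "tss_focal_gain") {
      tss <- if (rows$strand[i] == "+") rows$start[i] else rows$end[i]
      lo <- max(0, floor((tss - 3 * config$tssSd) / bs))
      hi <- min(n - 1, ceiling((tss + 3 * config$tssSd) / bs) - 1)
      idx <- lo:hi
      centers <- (idx + 0.5) * bs
      w <- exp(-(centers - tss)^2 / (2 * config$tssSd^2))
      lambda[idx + 1L] <- lambda[idx + 1L] + amp * w
    } else {
      ## broad body enrichment (and intergenic domains): uniform over the
      ## span, fractional at edge bins
      i0 <- floor(rows$start[i] / bs); i1 <- ceiling(rows$end[i] / bs) - 1
      idx <- i0:i1
      w <- (pmin(rows$end[i], (idx + 1) * bs) -
              pmax(rows$start[i], idx * bs)) / bs
      lambda[idx + 1L] <- lambda[idx + 1L] + amp * w
    }
  }
  lambda
}

#' Simulate H3K27me3 coverage tracks
#'
#' One [SignalTrack-class] per time point. Expected per-bin counts are the
#' background depth plus the archetype's spatial enrichment (uniform over
#' the gene body for broad archetypes, a Gaussian bump at the TSS for the
#' focal archetype, uniform over planted intergenic domains), scaled by the
#' gene's logistic temporal factor; observed counts are Poisson draws.
#'
#' @param truth Truth table from [simulateGeneTruth()].
#' @param config A [simulationConfig()].
#' @param noiseless If `TRUE`, skip the Poisson draw and return expected
#'   counts.
#' @return Named list of [SignalTrack-class] objects (`day0`, `day2`, ...).
#' @export
simulateMe3Tracks <- function(truth, config, noiseless = FALSE) {
  set.seed(config$seed + 3L)
  tracks <- lapply(config$times, function(t) {
    bins <- lapply(names(config$chromLengths), function(chrom) {
      lambda <- .me3Expected(chrom, t, truth, config)
      if (noiseless) lambda else as.numeric(rpois(length(lambda), lambda))
    })
    names(bins) <- names(config$chromLengths)
    SignalTrack(bins, config$binSize, config$chromLengths,
                sampleLabel = paste0("day", t))
  })
  names(tracks) <- paste0("day", config$times)
  tracks
}

#' Simulate strand-split RNA coverage tracks
#'
#' Strand-specific RNA coverage per time point: a low background on both
#' strands, annotated-gene transcription on each gene's strand proportional
#' to its (noiseless) FPKM course, and the planted intergenic domains'
#' unannotated transcription on their assigned strand — which changes with
#' the (earlier) expression midpoint, inversely to the domain's H3K27me3
#' change. Counts are Poisson draws.
#'
#' @param truth Truth table from [simulateGeneTruth()].
#' @param config A [simulationConfig()].
#' @param noiseless If `TRUE`, return expected counts.
#' @return Named list (per time point) of lists with [SignalTrack-class]
#'   elements `watson` and `crick`.
#' @export
simulateRnaTracks <- function(truth, config, noiseless = FALSE) {
  set.seed(config$seed + 4L)
  expr <- simulateExpression(truth, config, noiseless = TRUE)
  set.seed(config$seed + 4L)   # expression call above must not shift the
                               # stream used for the Poisson draws
  bs <- config$binSize
  f <- config$effectFold
  tracks <- lapply(seq_along(config$times), function(ti) {
    t <- config$times[ti]
    perStrand <- lapply(c("+", "-"), function(str) {
      bins <- lapply(names(config$chromLengths), function(chrom) {
        n <- ceiling(config$chromLengths[[chrom]] / bs)
        lambda <- rep(config$rnaDepth, n)
        rows <- truth[truth$chrom == chrom & truth$strand == str, ,
                      drop = FALSE]
        for (i in seq_len(nrow(rows))) {
          i0 <- floor(rows$start[i] / bs)
          i1 <- ceiling(rows$end[i] / bs) - 1
          idx <- i0:i1
          w <- (pmin(rows$end[i], (idx + 1) * bs) -
                  pmax(rows$start[i], idx * bs)) / bs
          amp <- if (rows$archetype[i] == "intergenic_domain") {
            s <- .sigmoid(t, rows$expr_midpoint[i], config$steepness)
            config$rnaAmplitude *
              (if (rows$expr_direction[i] == "down") (1 - s) else s)
          } else {
            expr[rows$id[i], ti]
          }
          lambda[idx + 1L] <- lambda[idx + 1L] + amp * w
        }
        if (noiseless) lambda else as.numeric(rpois(n, lambda))
      })
      names(bins) <- names(config$chromLengths)
      SignalTrack(bins, bs, config$chromLengths,
                  sampleLabel = sprintf("day%s_%s", t,
                                        if (str == "+") "watson"
                                        else "crick"))
    })
    list(watson = perStrand[[1]], crick = perStrand[[2]])
  })
  names(tracks) <- paste0("day", config$times)
  tracks
}

#' Temporal archetype cohort for clustering tests
#'
#' A small, direct simulation of three temporal archetypes — rising,
#' falling-early and falling-late — as per-gene time courses with
#' multiplicative lognormal noise, with the true archetype labels attached.
#'
#' @param nPerClass Genes per archetype (default 50).
#' @param seed Integer seed.
#' @param times Sampling times in days.
#' @param midpoints Transition midpoints (days) for the three archetypes.
#' @param fold Effect size (ratio, default 4).
#' @param steepness Logistic steepness (1/day).
#' @param noiseSd Lognormal noise sd.
#' @return List with `mat` (genes x times) and `labels` (integer archetype
#'   per gene).
#' @export
simulateTemporalArchetypes <- function(nPerClass = 50, seed = 1,
                                       times = c(0, 2, 4, 7, 12),
                                       midpoints = c(rising = 6.9,
                                                     fallingEarly = 2,
                                                     fallingLate = 9),
                                       fold = 4, steepness = 1.5,
                                       noiseSd = 0.1) {
  set.seed(seed)
  shapes <- rbind(
    1 + (fold - 1) * .sigmoid(times, midpoints[[1]], steepness),
    fold - (fold - 1) * .sigmoid(times, midpoints[[2]], steepness),
    fold - (fold - 1) * .sigmoid(times, midpoints[[3]], steepness))
  labels <- rep(1:3, each = nPerClass)
  mat <- shapes[labels, , drop = FALSE] *
    exp(matrix(rnorm(3 * nPerClass * length(times), 0, noiseSd),
               nrow = 3 * nPerClass))
  rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  colnames(mat) <- paste0("day_", times)
  list(mat = mat, labels = labels)
}

#' Simulate a complete fixture bundle in memory
#'
#' Runs annotation, truth, expression, H3K27me3 and RNA simulation with one
#' seed; every simulated object is reproducible end to end.
#'
#' @param config A [simulationConfig()].
#' @return List with `config`, `genes`, `seqlengths`, `truth`, `fpkm`,
#'   `me3Tracks`, `rnaTracks`.
#' @export
simulateBundle <- function(config = simulationConfig()) {
  genes <- simulateAnnotation(config)
  truth <- simulateGeneTruth(genes, config)
  list(config = config,
       genes = genes,
       seqlengths = config$chromLengths,
       truth = truth,
       fpkm = simulateExpression(truth, config),
       me3Tracks = simulateMe3Tracks(truth, config),
       rnaTracks = simulateRnaTracks(truth, config))
}

#' Write a fixture bundle to disk
#'
#' Writes the annotation (BED6), chromosome sizes, one bedGraph per
#' H3K27me3 time point, strand-split RNA bedGraphs, the FPKM table, the
#' truth table, and a flat key=value manifest recording the configuration
#' and seed. Regenerating with the same seed reproduces every file byte for
#' byte.
#'
#' @param bundle Bundle from [simulateBundle()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  writeGeneModelsBed(bundle$genes, file.path(dir, "genes.bed"))
  write.table(data.frame(names(bundle$seqlengths),
                         format(unname(bundle$seqlengths),
                                scientific = FALSE, trim = TRUE)),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  for (nm in names(bundle$me3Tracks))
    writeBedGraph(bundle$me3Tracks[[nm]],
                  file.path(dir, sprintf("me3_%s.bedgraph", nm)))
  for (nm in names(bundle$rnaTracks)) {
    writeBedGraph(bundle$rnaTracks[[nm]]$watson,
                  file.path(dir, sprintf("rna_watson_%s.bedgraph", nm)))
    writeBedGraph(bundle$rnaTracks[[nm]]$crick,
                  file.path(dir, sprintf("rna_crick_%s.bedgraph", nm)))
  }
  write.table(data.frame(gene_id = rownames(bundle$fpkm), bundle$fpkm),
              file.path(dir, "fpkm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  keys <- vapply(cfg, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste0(names(cfg), "=", keys), file.path(dir, "manifest.txt"))
  invisible(dir)
}
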