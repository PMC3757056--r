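test_that("simulated annotations are disjoint, stranded and reproducible", {
  cfg <- simulationConfig(seed = 5, nBroadGain = 5, nBroadLoss = 5,
                          nTssGain = 0, nUnchanged = 10, nIntergenic = 0,
                          chromLengths = c(chr1 = 1e6))
  g1 <- simulateAnnotation(cfg)
  g2 <- simulateAnnotation(cfg)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_length(g1, 20)
  ## exhaustive pairwise overlap check
  expect_equal(sum(countOverlaps(g1, g1)), length(g1))
  expect_true(all(c("+", "-") %in% as.character(strand(g1))))
  ## too-small chromosome errors
  expect_error(simulateAnnotation(
    simulationConfig(seed = 5, chromLengths = c(chr1 = 1e5))),
    "do not fit")
})

test_that("noiseless expression follows the logistic construction", {
  cfg <- simulationConfig(seed = 6, nBroadGain = 3, nBroadLoss = 3,
                          nTssGain = 0, nUnchanged = 2, nIntergenic = 0,
                          chromLengths = c(chr1 = 8e5),
                          times = seq(0, 12, by = 0.1))
  genes <- simulateAnnotation(cfg)
  truth <- simulateGeneTruth(genes, cfg)
  fpkm <- simulateExpression(truth, cfg, noiseless = TRUE)
  f <- cfg$effectFold
  for (i in seq_len(nrow(truth))) {
    v <- fpkm[truth$id[i], ]
    if (truth$expr_direction[i] == "flat") {
      expect_true(all(v == v[1]))
      next
    }
    ## at the midpoint day the logistic sits exactly halfway between its
    ## asymptotes
    base <- truth$baseline_fpkm[i]
    target <- if (truth$expr_direction[i] == "down")
      base * (1 - (1 - 1 / f) / 2) else base * (1 + (f - 1) / 2)
    crossing <- cfg$times[which.min(abs(v - target))]
    expect_lt(abs(crossing - truth$expr_midpoint[i]), 0.1)
  }
})

test_that("noiseless track expectations encode the archetypes", {
  cfg <- simulationConfig(seed = 7, nBroadGain = 2, nBroadLoss = 2,
                          nTssGain = 2, nUnchanged = 2, nIntergenic = 2,
                          chromLengths = c(chr1 = 8e5))
  genes <- simulateAnnotation(cfg)
  truth <- simulateGeneTruth(genes, cfg)
  tracks <- simulateMe3Tracks(truth, cfg, noiseless = TRUE)
  body <- geneBody(genes)
  m <- regionSignalMatrix(tracks, body)
  for (i in seq_along(genes)) {
    arch <- truth$archetype[match(names(genes)[i], truth$id)]
    ratio <- m[i, "day12"] / m[i, "day0"]
    if (arch == "broad_body_gain") {
      ## near the full effect by day 12; fractional edge bins attenuate
      ## the region mean slightly for short genes
      expect_gt(ratio, 0.75 * cfg$effectFold)
      expect_lt(ratio, 1.01 * cfg$effectFold)
    } else if (arch == "broad_body_loss") {
      expect_lt(ratio, 1 / (0.75 * cfg$effectFold))
      expect_gt(ratio, 1 / (1.01 * cfg$effectFold))
    } else if (arch == "unchanged") {
      expect_equal(ratio, 1, tolerance = 1e-6)
    }
  }
  ## background bins far from any feature stay at depth at all times
  far <- GRanges("chr1", IRanges(cfg$chromLengths[["chr1"]] - 2000,
                                 cfg$chromLengths[["chr1"]]))
  for (tr in tracks)
    expect_equal(meanRegionSignal(tr, far)$mean_signal, cfg$depth)
})

test_that("Poisson sampling matches expectations across replicates", {
  cfg <- simulationConfig(seed = 1, nBroadGain = 1, nBroadLoss = 0,
                          nTssGain = 0, nUnchanged = 1, nIntergenic = 0,
                          chromLengths = c(chr1 = 3e5))
  genes <- simulateAnnotation(cfg)
  truth <- simulateGeneTruth(genes, cfg)
  expected <- binValues(simulateMe3Tracks(truth, cfg,
                                          noiseless = TRUE)$day12)$chr1
  reps <- vapply(1:100, function(r) {
    cfgR <- cfg; cfgR$seed <- 1000 + r
    binValues(simulateMe3Tracks(truth, cfgR)$day12)$chr1
  }, numeric(length(expected)))
  emp <- rowMeans(reps)
  se <- sqrt(expected / 100)
  expect_true(mean(abs(emp - expected) <= 3 * se) > 0.98)
})

test_that("fixture bundles are byte-identical across regeneration and re-readable", {
  cfg <- simulationConfig(seed = 9, nBroadGain = 3, nBroadLoss = 2,
                          nTssGain = 1, nUnchanged = 4, nIntergenic = 2,
                          chromLengths = c(chr1 = 6e5))
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  writeFixtureBundle(simulateBundle(cfg), d1)
  writeFixtureBundle(simulateBundle(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)

  ## every artifact loads through the package's own readers
  sizes <- readChromSizes(file.path(d1, "chrom.sizes"))
  expect_equal(sizes, cfg$chromLengths)
  genes <- readGeneModels(file.path(d1, "genes.bed"), seqlengths = sizes)
  expect_length(genes, 10)
  tr <- readBedGraph(file.path(d1, "me3_day0.bedgraph"), cfg$binSize,
                     sizes)
  bundle <- simulateBundle(cfg)
  expect_equal(binValues(tr)$chr1, binValues(bundle$me3Tracks$day0)$chr1,
               tolerance = 1e-6)
  fpkm <- readFpkmTable(file.path(d1, "fpkm.tsv"))
  expect_equal(dim(fpkm), c(10, 5))
  truth <- read.table(file.path(d1, "truth.tsv"), sep = "\t",
                      header = TRUE)
  expect_equal(nrow(truth), 10 + 2)   # genes plus planted domains
})
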