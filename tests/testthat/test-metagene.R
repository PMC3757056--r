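test_that("bin positions are normalized strand-awarely onto the gene axis", {
  gp <- makeGene(1000, 2000, "+")
  r <- normalizeBinPositions(gp, data.frame(b_start = 1000, b_end = 1100))
  expect_equal(c(r$r_start, r$r_end), c(0, 0.1))
  expect_equal(r$segment, "body")

  r <- normalizeBinPositions(gp, data.frame(b_start = 1900, b_end = 2000))
  expect_equal(c(r$r_start, r$r_end), c(0.9, 1))

  ## minus strand: the same genomic bin at the gene end is at the TSS
  gm <- makeGene(1000, 2000, "-")
  r <- normalizeBinPositions(gm, data.frame(b_start = 1900, b_end = 2000))
  expect_equal(c(r$r_start, r$r_end), c(0, 0.1))

  r <- normalizeBinPositions(gm, data.frame(b_start = 2000, b_end = 2500))
  expect_equal(r$segment, "upstream")
})

test_that("metagene profile has the documented structure and values", {
  tr <- makeTrack(rep(3, 30))
  g <- makeGene(10000, 20000, "+")
  p <- buildMetageneProfile(tr, g)
  expect_length(profileValues(p), 600)
  expect_equal(pointsPerSegment(p), 200L)
  expect_equal(profileValues(p), rep(3, 600))
  expect_equal(p@mean, 3)
  expect_equal(p@sd, 0)

  ## signal confined to the body maps to indices 201..400
  vals <- rep(0, 30); vals[11:20] <- 5   # bins covering [10000, 20000)
  p <- buildMetageneProfile(makeTrack(vals), g)
  v <- profileValues(p)
  expect_true(all(v[201:400] == 5))
  expect_true(all(v[c(1:200, 401:600)] == 0))
})

test_that("metagene profile matches the per-base oracle, both strands", {
  set.seed(5)
  for (i in 1:10) {
    chromLen <- 60000
    binSize <- sample(c(250, 500, 1000), 1)
    vals <- runif(chromLen / binSize, 0, 20)
    tr <- makeTrack(vals, binSize = binSize, chromLen = chromLen)
    len <- sample(2000:10000, 1)
    s0 <- sample(15000:30000, 1)
    str <- sample(c("+", "-"), 1)
    g <- makeGene(s0, s0 + len, str)
    got <- profileValues(buildMetageneProfile(tr, g))
    want <- perBaseMetagene(vals, binSize, chromLen, s0, s0 + len, str)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("minus-strand genes mirror plus-strand genes on a mirrored track", {
  set.seed(6)
  chromLen <- 30000
  vals <- runif(30, 0, 10)
  g <- makeGene(12000, 18000, "+")
  p <- profileValues(buildMetageneProfile(makeTrack(vals), g))
  ## mirror the track and the gene around the chromosome midpoint
  gm <- makeGene(chromLen - 18000, chromLen - 12000, "-")
  pm <- profileValues(buildMetageneProfile(makeTrack(rev(vals)), gm))
  expect_equal(pm, p, tolerance = 1e-9)
})

test_that("off-chromosome flank positions are missing, not zero", {
  tr <- makeTrack(rep(2, 10))    # chromosome [0, 10000)
  g <- makeGene(2000, 8000, "+") # upstream flank would span [-4000, 2000)
  p <- buildMetageneProfile(tr, g)
  v <- profileValues(p)
  expect_true(anyNA(v[1:200]))    # upstream flank reaches below 0
  expect_true(anyNA(v[401:600]))  # downstream flank reaches past the end
  expect_false(anyNA(v[201:400])) # the body itself is fully on-chromosome
  expect_equal(p@mean, 2)         # missing positions excluded from stats
})

test_that("z-scoring normalizes, is idempotent, and excludes flat profiles", {
  vals <- rep(0, 600); vals[300] <- 10
  p <- MetageneProfile <- buildMetageneProfile(
    makeTrack(rep(0, 30)), makeGene(10000, 20000, "+"))
  ## construct directly from a track with one hot bin inside the body
  hot <- rep(0, 30); hot[16] <- 10
  p <- buildMetageneProfile(makeTrack(hot), makeGene(10000, 20000, "+"))
  z <- zscoreProfile(p)
  expect_equal(z@mean, 0, tolerance = 1e-9)
  expect_equal(z@sd, 1, tolerance = 1e-9)
  expect_equal(order(profileValues(z)), order(profileValues(p)))
  z2 <- zscoreProfile(z)
  expect_equal(profileValues(z2), profileValues(z), tolerance = 1e-9)

  flat <- buildMetageneProfile(makeTrack(rep(1, 30)),
                               makeGene(10000, 20000, "+"))
  expect_warning(zf <- zscoreProfile(flat), "flat")
  expect_null(zf)
})

test_that("gene sampling is uniform, reproducible and bounded", {
  genes <- readGeneModelsFromDf(data.frame(
    gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
    start = seq(0, 99000, by = 1000), end = seq(500, 99500, by = 1000),
    strand = "+"))
  expect_identical(names(sampleGenes(genes, 100, seed = 1)), names(genes))
  expect_identical(names(sampleGenes(genes, 10, seed = 9)),
                   names(sampleGenes(genes, 10, seed = 9)))
  expect_error(sampleGenes(genes, 101), "cannot sample")

  freq <- rowMeans(vapply(1:400, function(s)
    names(genes) %in% names(sampleGenes(genes, 10, seed = s)),
    logical(100)))
  expect_true(all(abs(freq - 0.1) < 0.05))
})

test_that("expression classes and class-mean aggregation behave", {
  cls <- expressionClass(c(0, 1, 10.5, 150, 0.2))
  expect_equal(as.integer(cls), c(1L, 2L, 4L, 5L, 2L))
  expect_error(expressionClass(-1), "negative")

  m <- rbind(a = rep(1, 6), b = rep(3, 6), c = 1:6, d = -(1:6))
  fpkm <- c(a = 0, b = 0, c = 5, d = 5)
  agg <- aggregateByExpressionClass(m, fpkm)
  expect_equal(unname(agg$classMeans["FPKM=0", ]), rep(2, 6))
  expect_equal(unname(agg$classMeans["1<FPKM<=10", ]), rep(0, 6))
  expect_true(all(is.na(agg$classMeans["FPKM>100", ])))
  expect_equal(as.integer(agg$counts), c(2L, 0L, 2L, 0L, 0L))

  ## single gene per class: the mean is that gene's profile
  agg1 <- aggregateByExpressionClass(m["c", , drop = FALSE], fpkm["c"])
  expect_equal(unname(agg1$classMeans["1<FPKM<=10", ]), 1:6)
})
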