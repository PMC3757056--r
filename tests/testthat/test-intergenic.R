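test_that("the intergenic mask is the complement of gene bodies", {
  g <- readGeneModelsFromDf(data.frame(gene_id = "g1", chrom = "chr1",
                                       start = 10, end = 20,
                                       strand = "+"))
  mask <- intergenicMask(g, c(chr1 = 100))
  expect_equal(start(mask) - 1, c(0, 20))
  expect_equal(end(mask), c(10, 100))

  ## genes tiling the chromosome leave nothing
  tiling <- readGeneModelsFromDf(data.frame(
    gene_id = c("a", "b"), chrom = "chr1", start = c(0, 50),
    end = c(50, 100), strand = "+"))
  expect_length(intergenicMask(tiling, c(chr1 = 100)), 0)

  ## overlapping genes: complement of the union
  ov <- readGeneModelsFromDf(data.frame(
    gene_id = c("a", "b"), chrom = "chr1", start = c(10, 20),
    end = c(30, 40), strand = c("+", "-")))
  mask <- intergenicMask(ov, c(chr1 = 100))
  expect_equal(start(mask) - 1, c(0, 40))
  expect_equal(end(mask), c(10, 100))
})

test_that("planted intergenic domains are recovered; nulls and genes are not", {
  bundle <- smallBundle()
  cfg <- bundle$config
  mask <- intergenicMask(bundle$genes, cfg$chromLengths)
  cand <- scanCandidates(bundle$me3Tracks$day0, bundle$me3Tracks$day12,
                         bundle$rnaTracks$day0, bundle$rnaTracks$day12,
                         mask)
  dom <- bundle$truth[bundle$truth$archetype == "intergenic_domain", ]
  domGr <- GRanges(dom$chrom, IRanges(dom$start + 1, dom$end))

  ## every planted domain recovered within one bin of truth
  hits <- findOverlaps(domGr, cand)
  expect_equal(length(unique(queryHits(hits))), nrow(dom))
  bErr <- c(abs(start(domGr)[queryHits(hits)] -
                  start(cand)[subjectHits(hits)]),
            abs(end(domGr)[queryHits(hits)] - end(cand)[subjectHits(hits)]))
  expect_true(all(bErr <= cfg$binSize))

  ## recovered strand matches the planted strand
  expect_equal(as.character(strand(cand))[subjectHits(hits)],
               dom$strand[queryHits(hits)])

  ## no candidate overlaps a gene body
  expect_equal(sum(countOverlaps(cand, geneBody(bundle$genes))), 0)

  ## identical conditions give no candidates
  none <- scanCandidates(bundle$me3Tracks$day0, bundle$me3Tracks$day0,
                         bundle$rnaTracks$day0, bundle$rnaTracks$day0,
                         mask)
  expect_length(none, 0)
})

test_that("differential signal inside a gene body is never reported", {
  ## a broad-gain gene changes strongly, but lies outside the mask
  cfg <- simulationConfig(seed = 8, nBroadGain = 5, nBroadLoss = 0,
                          nTssGain = 0, nUnchanged = 5, nIntergenic = 0,
                          chromLengths = c(chr1 = 6e5))
  b <- simulateBundle(cfg)
  mask <- intergenicMask(b$genes, cfg$chromLengths)
  cand <- scanCandidates(b$me3Tracks$day0, b$me3Tracks$day12,
                         b$rnaTracks$day0, b$rnaTracks$day12, mask)
  expect_equal(sum(countOverlaps(cand, geneBody(b$genes))), 0)
})

test_that("candidates swap direction, not identity, when conditions swap", {
  bundle <- smallBundle()
  cfg <- bundle$config
  mask <- intergenicMask(bundle$genes, cfg$chromLengths)
  fwd <- scanCandidates(bundle$me3Tracks$day0, bundle$me3Tracks$day12,
                        bundle$rnaTracks$day0, bundle$rnaTracks$day12,
                        mask)
  rev <- scanCandidates(bundle$me3Tracks$day12, bundle$me3Tracks$day0,
                        bundle$rnaTracks$day12, bundle$rnaTracks$day0,
                        mask)
  ov <- findOverlaps(fwd, rev)
  expect_gte(length(ov), length(fwd) * 0.9)
  lf <- log2(fwd$me3_fold[queryHits(ov)])
  lr <- log2(rev$me3_fold[subjectHits(ov)])
  expect_true(all(sign(lf) == -sign(lr)))
})

test_that("nearest-gene annotation matches an exhaustive scan", {
  genes <- readGeneModelsFromDf(data.frame(
    gene_id = c("gA", "gB", "gC"), chrom = "chr1",
    start = c(10000, 30000, 60000), end = c(15000, 40000, 70000),
    strand = c("+", "-", "+")))

  ## region 500 bp upstream of gA's TSS
  cand <- GRanges("chr1", IRanges(9001, 9500), strand = "+")
  ann <- annotateNearestGene(cand, genes)
  expect_equal(ann$nearest_gene, "gA")
  expect_equal(ann$distance, 500)

  ## equidistant tie broken toward the downstream gene for a + region
  tie <- GRanges("chr1", IRanges(22001, 23000), strand = "+")
  expect_equal(annotateNearestGene(tie, genes)$nearest_gene, "gB")
  tieM <- GRanges("chr1", IRanges(22001, 23000), strand = "-")
  expect_equal(annotateNearestGene(tieM, genes)$nearest_gene, "gA")

  ## brute-force oracle over random regions
  set.seed(12)
  for (i in 1:20) {
    s0 <- sample(0:80000, 1); e0 <- s0 + sample(200:2000, 1)
    cand <- GRanges("chr1", IRanges(s0 + 1, e0), strand = "+")
    got <- annotateNearestGene(cand, genes)
    d <- sapply(seq_along(genes), function(j) {
      gs <- start(genes)[j] - 1; ge <- end(genes)[j]
      max(0, gs - e0, s0 - ge)
    })
    expect_equal(got$distance, min(d))
  }
})
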