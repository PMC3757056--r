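test_that("binCounts follows the half-open convention and conserves reads", {
  pos <- data.frame(chrom = "chr1", pos = c(100, 500, 999))
  tr <- binCounts(pos, 1000, c(chr1 = 3000))
  expect_equal(binValues(tr)$chr1, c(3, 0, 0))

  ## position exactly at a bin boundary goes to the next bin
  tr <- binCounts(data.frame(chrom = "chr1", pos = 1000), 1000,
                  c(chr1 = 3000))
  expect_equal(binValues(tr)$chr1, c(0, 1, 0))

  ## conservation under random scatter, recounted brute force
  set.seed(7)
  p <- data.frame(chrom = "chr1", pos = sample(0:9999, 200, TRUE))
  tr <- binCounts(p, 1000, c(chr1 = 10000))
  expect_equal(sum(binValues(tr)$chr1), 200)
  expect_equal(librarySize(tr), 200)
  brute <- sapply(0:9, function(i) sum(p$pos >= i * 1000 &
                                         p$pos < (i + 1) * 1000))
  expect_equal(binValues(tr)$chr1, as.numeric(brute))

  ## out-of-bounds positions rejected with a warning
  expect_warning(
    tr <- binCounts(data.frame(chrom = "chr1", pos = c(5, -1, 10000)),
                    1000, c(chr1 = 10000)),
    "2 position")
  expect_equal(librarySize(tr), 1)
})

test_that("library normalization equalizes totals and preserves ratios", {
  a <- makeTrack(c(10, 30, 60))          # total 100
  b <- makeTrack(c(40, 60, 100))         # total 200
  nn <- normalizeLibrary(a, b)
  expect_equal(binValues(nn$a)$chr1, c(10, 30, 60))    # smaller unchanged
  expect_equal(binValues(nn$b)$chr1, c(20, 30, 50))    # scaled by 0.5
  expect_equal(librarySize(nn$a), librarySize(nn$b), tolerance = 1e-6)
  ## per-bin ratios within the scaled track unchanged
  expect_equal(binValues(nn$b)$chr1 / binValues(b)$chr1[1] * 40,
               binValues(b)$chr1 * 0.5 / 40 * 40)
  r0 <- binValues(b)$chr1 / binValues(b)$chr1[1]
  r1 <- binValues(nn$b)$chr1 / binValues(nn$b)$chr1[1]
  expect_equal(r0, r1)

  ## identity case
  nn <- normalizeLibrary(a, a)
  expect_equal(binValues(nn$b)$chr1, binValues(a)$chr1)
  expect_error(normalizeLibrary(a, makeTrack(c(0, 0, 0))), "positive")

  ## list version equalizes all totals
  tracks <- normalizeLibraries(list(a = a, b = b, c = makeTrack(1:3 * 50)))
  expect_equal(vapply(tracks, librarySize, numeric(1)),
               c(a = 100, b = 100, c = 100), tolerance = 1e-6)
})

test_that("lowess smoothing preserves constants and lines, attenuates spikes", {
  const <- makeTrack(rep(4, 50), binSize = 100)
  expect_equal(binValues(lowessSmooth(const, 0.3))$chr1, rep(4, 50))

  ramp <- makeTrack(seq(0, 9.8, by = 0.2), binSize = 100)
  expect_equal(binValues(lowessSmooth(ramp, 0.3))$chr1,
               seq(0, 9.8, by = 0.2), tolerance = 1e-6)

  spike <- rep(1, 51); spike[26] <- 100
  sm <- binValues(lowessSmooth(makeTrack(spike, binSize = 100), 0.2))$chr1
  expect_lt(sm[26], 100)
  expect_true(all(sm >= 0))

  expect_warning(lowessSmooth(makeTrack(c(1, 2), binSize = 100)),
                 "fewer than 3")
})

test_that("region means equal the per-base average, including partial bins", {
  ## constant field
  tr <- makeTrack(rep(7, 10))
  r <- GRanges("chr1", IRanges(1234, 8765))
  expect_equal(meanRegionSignal(tr, r)$mean_signal, 7)

  ## full bins: plain arithmetic mean
  tr <- makeTrack(c(2, 4))
  expect_equal(meanRegionSignal(tr, GRanges("chr1", IRanges(1, 2000)))$mean_signal, 3)

  ## half of a value-10 bin plus all of a value-0 bin
  tr <- makeTrack(c(10, 0))
  r <- GRanges("chr1", IRanges(501, 2000))   # 0-based [500, 2000)
  expect_equal(meanRegionSignal(tr, r)$mean_signal, 10 * 500 / 1500,
               tolerance = 1e-12)

  ## brute-force per-base oracle over random regions
  set.seed(13)
  vals <- runif(100, 0, 50)
  tr <- makeTrack(vals, binSize = 100, chromLen = 10000)
  for (i in 1:25) {
    s0 <- sample(0:9000, 1)
    e0 <- s0 + sample(1:999, 1)
    got <- meanRegionSignal(tr, GRanges("chr1", IRanges(s0 + 1, e0)))
    expect_equal(got$mean_signal,
                 perBaseRegionMean(vals, 100, 10000, s0, e0),
                 tolerance = 1e-9)
  }

  expect_error(meanRegionSignal(tr, GRanges("chr9", IRanges(1, 10))),
               "absent")
})

test_that("mapping filter summary reproduces the published percentages", {
  expect_equal(mappingFilterSummary(174644447, 870116495),
               c(pct_discarded = 16.72, pct_retained = 83.28))
  expect_equal(mappingFilterSummary(0, 100),
               c(pct_discarded = 0, pct_retained = 100))
  expect_equal(mappingFilterSummary(50, 50),
               c(pct_discarded = 50, pct_retained = 50))
  expect_error(mappingFilterSummary(0, 0), "positive")
})

test_that("bedGraph and WIG round-trips preserve values", {
  set.seed(21)
  vals <- round(runif(100, 0, 40), 3)
  tr <- makeTrack(vals, binSize = 1000, chromLen = 1e5)

  bg <- tempfile(fileext = ".bedgraph")
  writeBedGraph(tr, bg)
  back <- readBedGraph(bg, 1000, c(chr1 = 1e5))
  expect_equal(binValues(back)$chr1, vals, tolerance = 1e-6)

  wig <- tempfile(fileext = ".wig")
  writeWig(tr, wig)
  expect_equal(binValues(readWig(wig, c(chr1 = 1e5)))$chr1, vals,
               tolerance = 1e-6)

  ## independent reader agrees with what we wrote
  skip_if_not_installed("rtracklayer")
  gr <- rtracklayer::import(wig, format = "wig")
  expect_equal(gr$score, vals, tolerance = 1e-6)
  expect_equal(start(gr), seq(1, 99001, by = 1000))

  ## an interval spanning two bins contributes its value to both
  writeLines("chr1\t500\t2500\t6", bg)
  tr2 <- readBedGraph(bg, 1000, c(chr1 = 3000))
  expect_equal(binValues(tr2)$chr1, c(6, 6, 6))

  ## overlapping intervals are rejected
  writeLines(c("chr1\t0\t1000\t1", "chr1\t500\t1500\t2"), bg)
  expect_error(readBedGraph(bg, 1000, c(chr1 = 3000)), "overlapping")
})
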