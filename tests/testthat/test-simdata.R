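test_that("parent panel is deterministic under a fixed seed and errors on empty chromosomes", {
  cfg <- smallConfig()
  p1 <- buildParentPanel(cfg)
  p2 <- buildParentPanel(cfg)
  expect_identical(start(snpPanel(p1)), start(snpPanel(p2)))
  expect_identical(teInsertions(p1), teInsertions(p2))
  expect_identical(geneticMap(p1), geneticMap(p2))

  expect_error(buildParentPanel(SimConfig(nChromosomes = 1,
                                          chromLengthBp = 5e6,
                                          snpDensity = 1e-9, seed = 1)),
               "Chr1")
})

test_that("SNP counts follow the Poisson process and positions are strictly increasing", {
  cfg <- SimConfig(nChromosomes = 12, chromLengthBp = 30e6, snpDensity = 2,
                   seed = 1)
  panel <- buildParentPanel(cfg)
  total <- length(snpPanel(panel))
  mean_expected <- 12 * 30e6 / 1000 * 2
  expect_lt(abs(total - mean_expected), 3 * sqrt(mean_expected))
  pos <- start(snpPanel(panel))
  chrom <- as.character(seqnames(snpPanel(panel)))
  expect_true(all(tapply(pos, chrom, function(p) all(diff(p) > 0))))
})

test_that("genetic map is monotone with a centrally suppressed rate", {
  panel <- buildParentPanel(smallConfig())
  gm <- geneticMap(panel)
  for (ch in unique(gm$chrom)) {
    cm <- gm$cM[gm$chrom == ch]
    expect_true(all(diff(cm) >= 0))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(SimConfig(errorRate = 0.3), "errorRate")
  expect_error(SimConfig(chromLengthBp = 1e6), "chromLengthBp")
  expect_error(SimConfig(pChromGain = 1.5), "probabilities")
  expect_error(SimConfig(nChromosomes = 2, chromLengthBp = 6e6,
                         heIntensity = list(rep(1, 6))),
               "heIntensity")
})

test_that("zero HE intensity yields a single balanced segment; a point mass confines breakpoints", {
  cfg <- smallConfig(meanHePerChrom = 0)
  panel <- buildParentPanel(cfg)
  tr <- drawMosaic(cfg, panel)
  segs <- truthSegments(tr)
  expect_length(segs, 2L)  # one segment per chromosome
  expect_true(all(mcols(segs)$dosage == 2L))
  expect_true(isEuploid(tr))

  intensity <- rep(0, 6)
  intensity[4] <- 1  # all mass in window [3,4) Mb
  cfg2 <- smallConfig(meanHePerChrom = 5,
                      heIntensity = list(intensity, intensity))
  set.seed(7)
  tr2 <- drawMosaic(cfg2, panel)
  bps <- start(truthSegments(tr2))
  bps <- bps[bps != 1]  # breakpoints are segment starts after the first
  expect_true(all(bps >= 3e6 & bps <= 4e6))
})

test_that("breakpoint counts are Poisson with the configured mean", {
  cfg <- SimConfig(nChromosomes = 1, chromLengthBp = 6e6, meanHePerChrom = 3,
                   pChromGain = 0, pChromLoss = 0, pSegmental = 0, seed = 7)
  panel <- buildParentPanel(cfg)
  set.seed(7)
  nbp <- replicate(1000, length(truthSegments(drawMosaic(cfg, panel))) - 1L)
  se <- sqrt(3 / 1000)
  expect_lt(abs(mean(nbp) - 3), 3 * se)
})

test_that("dosage walk stays in [0,4] and adjacent segments differ by one step", {
  cfg <- smallConfig(meanHePerChrom = 8, seed = 5)
  panel <- buildParentPanel(cfg)
  set.seed(5)
  for (rep in 1:20) {
    tr <- drawMosaic(cfg, panel)
    segs <- truthSegments(tr)
    for (ch in unique(as.character(seqnames(segs)))) {
      d <- mcols(segs[seqnames(segs) == ch])$dosage
      expect_true(all(d >= 0L & d <= 4L))
      if (length(d) > 1L) expect_true(all(abs(diff(d)) == 1L))
    }
  }
})

test_that("emitted counts follow the dosage model", {
  # pure 9311 with no error: every read attributed to 9311
  cfg <- SimConfig(nChromosomes = 1, chromLengthBp = 30e6, snpDensity = 2,
                   errorRate = 0, perSiteDepth = 20, seed = 3,
                   meanHePerChrom = 0)
  panel <- buildParentPanel(cfg)
  tr <- truthWithBreakpoints(cfg, list(NA), dosLeft = 4L)
  set.seed(3)
  cc <- emitCounts(tr, panel, cfg)
  expect_true(all(countNip(cc) == 0L))

  # balanced 2:2: pooled 9311 fraction within 3 binomial SE of 0.5
  tr2 <- truthWithBreakpoints(cfg, list(NA), dosLeft = 2L)
  set.seed(4)
  cc2 <- emitCounts(tr2, panel, cfg)
  a <- sum(count9311(cc2))
  n <- sum(siteDepth(cc2))
  expect_lt(abs(a / n - 0.5), 3 * sqrt(0.25 / n))

  # +1 on the 9311 homoeolog: relative depth 5/4, 9311 fraction 3/5
  tr3 <- truthWithBreakpoints(cfg, list(NA), dosLeft = 2L)
  tr3@chromOffsets$offset <- 1L
  tr3@chromOffsets$homoeolog <- "A"
  set.seed(5)
  cc3 <- emitCounts(tr3, panel, cfg)
  nsites <- nrow(cc3)
  meanDepth <- mean(siteDepth(cc3))
  expect_lt(abs(meanDepth - 25), 3 * sqrt(25 / nsites))
  expect_lt(abs(sum(count9311(cc3)) / sum(siteDepth(cc3)) - 0.6),
            3 * sqrt(0.24 / sum(siteDepth(cc3))))
})

test_that("population simulation is reproducible and exports aligned truth", {
  cfg <- smallConfig()
  s1 <- simulatePopulation(cfg)
  s2 <- simulatePopulation(cfg)
  expect_identical(count9311(s1$counts), count9311(s2$counts))
  expect_identical(countNip(s1$controls), countNip(s2$controls))
  expect_identical(names(s1$truth), colnames(count9311(s1$counts)))
  expect_identical(colnames(count9311(s1$controls)),
                   c("N9-F1", "9N-F1", "MIX"))
})

test_that("noise-free expectation counts genotype back to the exact truth", {
  # infinite-depth limit: replace sampled counts by their expectations
  cfg <- SimConfig(nChromosomes = 1, chromLengthBp = 10e6, snpDensity = 1,
                   errorRate = 0, perSiteDepth = 40, meanHePerChrom = 0,
                   seed = 9)
  panel <- buildParentPanel(cfg)
  bp <- 5e6
  tr <- truthWithBreakpoints(cfg, list(bp), dosLeft = 2L, dosRight = 3L)
  sites <- snpPanel(panel)
  d <- ifelse(start(sites) < bp, 2L, 3L)
  a <- as.integer(round(40 * d / 4))
  b <- as.integer(40 - a)
  cc <- AllelicCounts(matrix(a, ncol = 1), matrix(b, ncol = 1), sites, "i1")
  bins <- binSites(sites, NULL, 10L)
  gb <- genotypeBins(cc, bins)
  frags <- segmentFragments(gb)
  expect_identical(frags$genotype, c("2:2", "3:1"))
  he <- callHE(frags)
  expect_equal(nrow(he), 1L)
  # transition localised to within ~one 10-site bin of the true breakpoint
  expect_lt(abs((he$start + he$end) / 2 - bp), 25e3)
})
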