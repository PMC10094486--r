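test_that("bins hold ten kept sites with the stated remainder rule", {
  expect_equal(nrow(binSites(evenSites(100))), 10L)

  b104 <- binSites(evenSites(104))
  expect_equal(nrow(b104), 10L)
  expect_equal(b104$nSites[10], 14L)   # remainder 4 < 5 merges backwards

  b107 <- binSites(evenSites(107))
  expect_equal(nrow(b107), 11L)
  expect_equal(b107$nSites[11], 7L)    # remainder 5..9 stands alone

  expect_warning(binSites(evenSites(8)), "skipped")

  # masked sites are not binned
  sites <- evenSites(110)
  m <- S4Vectors::DataFrame(keep = c(rep(TRUE, 100), rep(FALSE, 10)),
                            reason = "ok")
  expect_equal(nrow(binSites(sites, m)), 10L)
})

test_that("the G statistic matches its closed form and is zero only at the expectation", {
  expect_equal(gStat(10, 10, "2:2"), 0)
  expect_equal(gStat(20, 20, "3:1"),
               2 * (20 * log(20 / 30) + 20 * log(20 / 10)),
               tolerance = 1e-12)
  expect_equal(gStat(0, 40, "0:4", 0.005),
               2 * 40 * log(40 / (40 * 0.995)),
               tolerance = 1e-12)
  expect_equal(gStat(30, 10, "3:1"), 0)
  expect_true(is.na(gStat(0, 0, "2:2")))
  expect_error(gStat(-1, 5, "2:2"), "nonnegative")
  expect_error(gStat(5, 5, "5:0"), "hypothesis")

  set.seed(14)
  a <- rpois(200, 30)
  b <- rpois(200, 30)
  d <- sample(0:4, 200, replace = TRUE)
  G <- gStat(a, b, d, 0.005)
  expect_true(all(G >= 0, na.rm = TRUE))
})

test_that("bin genotyping equals the binomial maximum-likelihood oracle", {
  expect_identical(as.character(genotypeBin(20, 20)$genotype), "2:2")
  expect_identical(as.character(genotypeBin(33, 7)$genotype), "3:1")
  expect_identical(as.character(genotypeBin(1, 39)$genotype), "0:4")
  # no-call on an empty bin
  expect_true(is.na(genotypeBin(0, 0)$genotype))

  set.seed(15)
  a <- rpois(300, 20)
  b <- rpois(300, 20)
  got <- as.character(genotypeBin(a, b, 0.005)$genotype)
  want <- mapply(oracleGenotype, a, b, MoreArgs = list(epsilon = 0.005))
  ok <- a + b > 0
  expect_identical(got[ok], unname(want[ok]))
})

test_that("p-values are the chi-square upper tail of G", {
  g <- genotypeBin(c(20, 25), c(20, 15))
  expect_equal(g$p, pchisq(g$G, 1, lower.tail = FALSE))
})

test_that("fragment segmentation removes short islands and re-merges flanks", {
  one <- segmentFragments(binsFromGenotypes(rep("2:2", 10)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$nBins, 10L)
  expect_equal(nrow(callHE(one)), 0L)

  # island removed, equal flanks re-merge absorbing its bins
  merged <- segmentFragments(binsFromGenotypes(
    rep(c("2:2", "3:1", "2:2"), c(8, 3, 9))))
  expect_equal(nrow(merged), 1L)
  expect_identical(merged$genotype, "2:2")
  expect_equal(merged$nBins, 20L)

  # island removed between different flanks: the gap becomes the HE region
  gap <- segmentFragments(binsFromGenotypes(
    rep(c("2:2", "1:3", "3:1"), c(6, 2, 6))))
  expect_identical(gap$genotype, c("2:2", "3:1"))
  he <- callHE(gap)
  expect_equal(nrow(he), 1L)
  expect_equal(he$start, 6000)        # last SNP of the left fragment
  expect_equal(he$end, 8001)          # first SNP of the right fragment
  expect_identical(he$leftGenotype, "2:2")
  expect_identical(he$rightGenotype, "3:1")
})

test_that("segmentation conserves bins across fragments and removed gaps", {
  set.seed(16)
  for (rep in 1:20) {
    g <- sample(DOSAGES, 60, replace = TRUE,
                prob = c(0.05, 0.2, 0.5, 0.2, 0.05))
    frags <- suppressWarnings(segmentFragments(binsFromGenotypes(g)))
    if (!nrow(frags)) next
    # fragments are disjoint, ordered, genotype-alternating
    expect_true(all(diff(frags$firstBin) > 0))
    expect_true(all(frags$firstBin[-1] > frags$lastBin[-nrow(frags)]))
    if (nrow(frags) > 1)
      expect_true(all(frags$genotype[-1] != frags$genotype[-nrow(frags)]))
    covered <- unlist(mapply(seq, frags$firstBin, frags$lastBin,
                             SIMPLIFY = FALSE))
    gaps <- setdiff(seq(min(frags$firstBin), max(frags$lastBin)), covered)
    # every interior bin is in exactly one fragment or one inter-fragment gap
    expect_equal(length(covered) + length(gaps),
                 max(frags$lastBin) - min(frags$firstBin) + 1L)
  }
})

test_that("three fragments give two ordered HE regions", {
  frags <- segmentFragments(binsFromGenotypes(
    rep(c("2:2", "3:1", "2:2"), c(6, 6, 6))))
  he <- callHE(frags)
  expect_equal(nrow(he), 2L)
  expect_true(all(he$start < he$end))
  expect_true(he$end[1] <= he$start[2])
  expect_equal(he$start[1], 6000)
  expect_equal(he$end[1], 6001 + 1000 - 1000)  # first SNP of bin 7
})

test_that("window HE frequency assigns events by interval midpoint", {
  lens <- c(Chr1 = 5e6)
  none <- windowHEFrequency(
    data.frame(individual = character(), chrom = character(),
               start = numeric(), end = numeric()), 2, lens)
  expect_true(all(none$count == 0))

  r <- data.frame(individual = c("a", "b"), chrom = "Chr1",
                  start = c(1.4e6, 1.45e6), end = c(1.6e6, 1.55e6))
  wf <- windowHEFrequency(r, 2, lens)
  expect_equal(wf$count[2], 2L)      # both midpoints at 1.5 Mb
  expect_equal(wf$frequency[2], 1.0)
  expect_equal(sum(wf$count), 2L)
})

test_that("population HE calling gates on euploidy", {
  cfg <- smallConfig(seed = 41, meanHePerChrom = 1)
  sim <- simulatePopulation(cfg)
  karyo <- callKaryotypes(sim$counts)
  # force one individual to look aneuploid
  karyo$calls$state[karyo$calls$individual == "S2-01" &
                      karyo$calls$chrom == "Chr1"] <- 1L
  he <- callHEPopulation(sim$counts, karyo = karyo)
  expect_false("S2-01" %in% he$individuals)
  expect_true(all(he$counts$individual != "S2-01"))
})
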