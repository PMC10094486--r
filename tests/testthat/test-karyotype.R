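test_that("window depths average kept sites and normalise by the global mean", {
  # 12 chromosomes, equal site counts; one chromosome at depth 25, rest 20
  sites <- suppressWarnings(do.call(c, lapply(sprintf("Chr%d", 1:12),
    function(ch) evenSites(100, ch, by = 10000))))
  depth <- rep(20L, length(sites))
  depth[as.character(seqnames(sites)) == "Chr4"] <- 25L
  cc <- AllelicCounts(matrix(depth, ncol = 1), matrix(0L, length(sites), 1),
                      sites, "i1")
  wd <- windowDepths(cc, globalStat = "mean")
  g <- 245 / 12  # global mean per-site depth
  expect_equal(unique(wd$relDepth[wd$chrom == "Chr4"]), 25 / g,
               tolerance = 1e-12)
  expect_equal(unique(wd$relDepth[wd$chrom == "Chr1"]), 20 / g,
               tolerance = 1e-12)
  # the robust default normalises by the median, which ignores the one
  # aberrant chromosome entirely
  wdm <- windowDepths(cc)
  expect_equal(unique(wdm$relDepth[wdm$chrom == "Chr4"]), 1.25)
  expect_equal(unique(wdm$relDepth[wdm$chrom == "Chr1"]), 1)

  # all sites depth 20: every window mean 20, rel 1
  cc2 <- constantCounts(evenSites(50, by = 10000), 10L, 10L)
  wd2 <- windowDepths(cc2)
  expect_true(all(wd2$meanDepth == 20))
  expect_true(all(wd2$relDepth == 1))
})

test_that("windows under five kept sites are excluded, and the count is exact", {
  sites <- c(evenSites(4, by = 1000),                       # 4 in window 1
             GRanges("Chr1", IRanges(1e6 + (1:7) * 1000, width = 1)))
  cc <- constantCounts(sites, 10L, 10L)
  wd <- windowDepths(cc)
  expect_identical(wd$excluded, c(TRUE, FALSE))
  expect_equal(sum(wd$excluded), sum(wd$nSites < 5))
  st <- classifyWindows(wd)$state
  expect_true(is.na(st[1]) && st[2] == 0L)
  # masking everything is an error
  m <- S4Vectors::DataFrame(keep = rep(FALSE, length(sites)),
                            reason = "biased_control")
  expect_error(windowDepths(cc, m), "no kept sites")
})

test_that("relative depth maps onto the copy-number rungs", {
  wd <- data.frame(relDepth = c(1, 1.25, 0.5, 1.5, 0.75, 1.19, 1.21, 0.56),
                   excluded = FALSE)
  expect_identical(classifyWindows(wd)$state,
                   c(0L, 1L, -2L, 2L, -1L, 0L, 1L, -1L))
})

test_that("karyotype summary applies the modal rule and reports segmental runs", {
  mkwd <- function(states) data.frame(
    individual = "i1", chrom = "Chr1",
    start = (seq_along(states) - 1) * 1e6 + 1, end = seq_along(states) * 1e6,
    nSites = 10, meanDepth = 20, relDepth = 1, excluded = FALSE,
    state = states)

  allGain <- summarizeKaryotype(mkwd(rep(1L, 30)))
  expect_identical(allGain$calls$state, 1L)
  expect_equal(nrow(allGain$events), 0L)

  seg <- summarizeKaryotype(mkwd(c(rep(0L, 10), rep(-1L, 5), rep(0L, 15))))
  expect_identical(seg$calls$state, 0L)
  expect_equal(nrow(seg$events), 1L)
  expect_identical(seg$events$offset, -1L)
  expect_equal(seg$events$start, 10e6 + 1)
  expect_equal(seg$events$end, 15e6)

  alt <- summarizeKaryotype(mkwd(rep(c(0L, 1L), 15)))
  expect_identical(alt$calls$state, 0L)
  expect_equal(alt$calls$confidence, 0.5)
  expect_equal(nrow(alt$events), 0L)  # no run of 3 aberrant windows

  unknown <- summarizeKaryotype(mkwd(rep(NA_integer_, 10)))
  expect_true(is.na(unknown$calls$state))
})

test_that("karyotype calls are invariant to a common depth scale factor", {
  cfg <- smallConfig(seed = 31)
  sim <- simulatePopulation(cfg)
  k1 <- callKaryotypes(sim$counts)
  scaled <- AllelicCounts(count9311(sim$counts) * 3L,
                          countNip(sim$counts) * 3L,
                          snpSites(sim$counts),
                          colnames(count9311(sim$counts)))
  k2 <- callKaryotypes(scaled)
  expect_identical(k1$calls, k2$calls)
  expect_identical(k1$events, k2$events)
})

test_that("euploid individuals are those with all-zero confident calls and no events", {
  calls <- data.frame(
    individual = rep(c("a", "b", "c", "d"), each = 2),
    chrom = rep(c("Chr1", "Chr2"), 4),
    state = c(0L, 0L, 1L, 0L, 0L, NA, 0L, 0L),
    confidence = 1)
  events <- data.frame(individual = "d", chrom = "Chr2", start = 1,
                       end = 3e6, offset = 1L, nWindows = 3L)
  expect_identical(euploidIndividuals(list(calls = calls, events = events)),
                   "a")
})
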