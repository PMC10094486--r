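test_that("pearson correlation matches the closed form and flags degenerate input", {
  x <- c(1, 2, 3)
  y <- c(1, 3, 2)
  res <- pearsonCor(x, y)
  closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, closed, tolerance = 1e-12)
  expect_equal(res$r, 0.5, tolerance = 1e-12)

  set.seed(30)
  u <- rnorm(50)
  v <- rnorm(50)
  closed2 <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(pearsonCor(u, v)$r, closed2, tolerance = 1e-12)
  expect_equal(pearsonCor(u, v)$r, pearsonCor(v, u)$r)  # symmetry

  expect_equal(pearsonCor(1:10, 2 * (1:10))$r, 1)
  expect_error(pearsonCor(1:10, rep(2, 10)), "constant")
  expect_error(pearsonCor(1:2, 1:2), "3 complete pairs")
})

test_that("proportion test reproduces the gain-event comparison and its oracle", {
  expect_equal(twoPropTest(9, 20, 8, 20), 1)
  expect_equal(twoPropTest(5, 10, 10, 20), 1)  # identical proportions
  p <- twoPropTest(10, 20, 3, 20)
  expect_equal(p, 0.0428, tolerance = 1e-2)
  expect_error(twoPropTest(1, 0, 1, 10), "positive")
  expect_error(twoPropTest(11, 10, 1, 10), "lie in")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_equal(fisher2x2(matrix(c(3, 7, 6, 4), 2, byrow = TRUE)), 0.3698,
               tolerance = 1e-3)
  expect_equal(fisher2x2(matrix(c(8, 2, 5, 5), 2, byrow = TRUE)), 0.3498,
               tolerance = 1e-3)
  tab <- matrix(c(8, 2, 5, 5), 2, byrow = TRUE)
  expect_equal(fisher2x2(tab), fisher2x2(tab[2:1, ]))    # row swap
  expect_equal(fisher2x2(tab), fisher2x2(tab[, 2:1]))    # column swap
  expect_error(fisher2x2(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("chi-square and exact tests agree on large-margin tables", {
  set.seed(31)
  for (rep in 1:10) {
    n1 <- sample(4000:8000, 1)
    n2 <- sample(4000:8000, 1)
    x1 <- rbinom(1, n1, 0.4)
    x2 <- rbinom(1, n2, 0.42)
    pChi <- twoPropTest(x1, n1, x2, n2)
    pF <- fisher2x2(matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE))
    expect_lt(abs(pChi - pF), 0.02)
  }
})

test_that("profile smoothing reproduces linear signals and denoises a sine", {
  pos <- seq_len(200)
  expect_equal(smoothProfile(pos, rep(2, 200)), rep(2, 200),
               tolerance = 1e-6)
  lin <- 0.5 + 0.01 * pos
  expect_equal(smoothProfile(pos, lin), lin, tolerance = 1e-6)

  set.seed(32)
  truth <- sin(pos / 15)
  noisy <- truth + rnorm(200, 0, 0.1)
  sm <- smoothProfile(pos, noisy)
  expect_lt(sqrt(mean((sm - truth)^2)), 0.1)
  expect_error(smoothProfile(1:5, 1:5), "at least 10")
})

test_that("reports carry Table-1-ordered correlations with two-tier stars", {
  set.seed(33)
  n <- 60
  wt <- data.frame(chrom = "Chr1", start = (seq_len(n) - 1) * 1e6 + 1,
                   end = seq_len(n) * 1e6,
                   heFrequency = NA_real_, snps = rpois(n, 50),
                   smallIndels = rpois(n, 20), largeIndels = rpois(n, 5),
                   tips = rpois(n, 10), tips_retrotransposon = rpois(n, 4),
                   tips_DNA_transposon = rpois(n, 3),
                   tips_MITE = rpois(n, 3), sharedTEs = rpois(n, 20),
                   shared_retrotransposon = rpois(n, 10),
                   shared_DNA_transposon = rpois(n, 5),
                   shared_MITE = rpois(n, 5))
  wt$heFrequency <- wt$snps * 0.01  # exact linear dependence
  rep1 <- buildReports(NULL, wt)
  expect_identical(rep1$table1$feature[1:11],
                   c("SNPs", "smallIndels", "largeIndels", "TIPs",
                     "retrotransposonTIPs", "DNAtransposonTIPs", "MITE_TIPs",
                     "sharedTEs", "sharedRetrotransposons",
                     "sharedDNAtransposons", "sharedMITEs"))
  expect_equal(rep1$table1$r[1], 1)
  expect_identical(rep1$table1$stars[1], "**")

  # an all-missing feature yields an NA row without stars
  wt$tips <- NA_real_
  rep2 <- buildReports(NULL, wt)
  row <- rep2$table1[rep2$table1$feature == "TIPs", ]
  expect_true(is.na(row$r))
  expect_identical(row$stars, "")
})

test_that("window tables join HE frequency, HR rate and densities on one tiling", {
  he <- data.frame(chrom = "Chr1", start = c(1, 1e6 + 1), end = c(1e6, 2e6),
                   count = c(2L, 0L), frequency = c(0.5, 0))
  hr <- data.frame(chrom = "Chr1", start = c(1, 1e6 + 1), end = c(1e6, 2e6),
                   rate = c(1.5, 2.5), fittedCM = c(1, 3))
  wv <- data.frame(chrom = "Chr1", start = c(1, 1e6 + 1), end = c(1e6, 2e6),
                   snps = c(10L, 20L))
  wt <- buildWindowTable(he, hr, wv)
  expect_equal(wt$heFrequency, c(0.5, 0))
  expect_equal(wt$hrRate, c(1.5, 2.5))
  expect_equal(wt$snps, c(10L, 20L))
})
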