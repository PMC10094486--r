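#' Pearson correlation with t-based p-value
#'
#' Thin wrapper over [stats::cor.test()] restricted to pairwise-complete
#' observations, returning the sample correlation and the two-sided p-value
#' from the t transform with n - 2 df. Fewer than 3 complete pairs or a
#' constant input is an error.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with elements `r`, `p` and `n` (complete pairs used).
#' @examples
#' pearsonCor(c(1, 2, 3), c(1, 3, 2))$r  # 0.5
#' @export
pearsonCor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sample test of equal proportions
#'
#' Compares two event proportions with the 2x2 chi-square test with Yates
#' continuity correction (two-sided), as used to compare per-generation
#' aneuploidy event counts on a fixed number of plants.
#'
#' @param x1,x2 event counts.
#' @param n1,n2 totals (positive).
#' @return the p-value.
#' @examples
#' twoPropTest(9, 20, 8, 20)  # 1: the correction absorbs the difference
#' @export
twoPropTest <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("totals must be positive")
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop("event counts must lie in [0, n]")
  suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE))$p.value
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value summing hypergeometric probabilities no larger
#' than that of the observed table; used for the reciprocal-cross
#' comparisons.
#'
#' @param tab a nonnegative integer 2x2 matrix (or something coercible).
#' @return the p-value.
#' @examples
#' fisher2x2(matrix(c(8, 2, 5, 5), 2, byrow = TRUE))  # about 0.3498
#' @export
fisher2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("cells must be nonnegative")
  stats::fisher.test(tab)$p.value
}

#' Loess-smooth a positional profile
#'
#' Fits [stats::loess()] (default span 0.2, degree 2) of a window statistic
#' on position and evaluates the fit at the input positions, for overlaying
#' smoothed HE-frequency and HR-rate profiles along a chromosome.
#'
#' @param positions,values numeric vectors (at least 10 points).
#' @param span,degree loess parameters.
#' @return fitted values at `positions` (NA where the value was NA).
#' @export
smoothProfile <- function(positions, values, span = 0.2, degree = 2L) {
  ok <- stats::complete.cases(positions, values)
  if (sum(ok) < 10L) stop("need at least 10 complete points to smooth")
  fit <- stats::loess(values[ok] ~ positions[ok], span = span,
                      degree = degree,
                      control = stats::loess.control(surface = "direct"))
  out <- rep(NA_real_, length(positions))
  out[ok] <- stats::predict(fit, positions[ok])
  out
}

#' Assemble the per-window association table
#'
#' Joins the window HE-frequency track, HR rates, variant/TE-insertion
#' densities and feature base fractions on their shared 1 Mb tiling.
#'
#' @param heFreq data.frame from [windowHEFrequency()].
#' @param hrRate optional data.frame from [localRate()].
#' @param variants optional data.frame from [windowVariantDensity()].
#' @param fractions optional data.frame from [windowFeatureFractions()].
#' @return one data.frame keyed by (chrom, start, end) with columns
#'   heFrequency, hrRate and every density/fraction column supplied.
#' @export
buildWindowTable <- function(heFreq, hrRate = NULL, variants = NULL,
                             fractions = NULL) {
  key <- function(d) paste(d$chrom, d$start)
  out <- heFreq[, c("chrom", "start", "end")]
  out$heFrequency <- heFreq$frequency
  if (!is.null(hrRate))
    out$hrRate <- hrRate$rate[match(key(out), key(hrRate))]
  addCols <- function(out, d) {
    idx <- match(key(out), key(d))
    for (cl in setdiff(names(d), c("chrom", "start", "end")))
      out[[cl]] <- d[[cl]][idx]
    out
  }
  if (!is.null(variants)) out <- addCols(out, variants)
  if (!is.null(fractions)) out <- addCols(out, fractions)
  out
}

#' Assemble the per-chromosome association table
#'
#' Combines chromosome features with the mean HE count per euploid
#' individual.
#'
#' @param chromFeatures data.frame from [chromFeatureTable()].
#' @param heCounts data.frame from [heCountMatrix()] restricted to the
#'   euploid individuals.
#' @return `chromFeatures` with a `meanHE` column.
#' @export
buildChromTable <- function(chromFeatures, heCounts) {
  mean_by <- tapply(heCounts$n, heCounts$chrom, mean)
  chromFeatures$meanHE <- as.numeric(mean_by[chromFeatures$chrom])
  chromFeatures
}

.stars <- function(p) ifelse(is.na(p), "",
                             ifelse(p < 0.01, "**",
                                    ifelse(p < 0.05, "*", "")))

.corRow <- function(feature, x, y) {
  res <- tryCatch(pearsonCor(x, y), error = function(e) NULL)
  if (is.null(res))
    return(data.frame(feature = feature, r = NA_real_, p = NA_real_,
                      n = sum(stats::complete.cases(x, y)), stars = ""))
  data.frame(feature = feature, r = res$r, p = res$p, n = res$n,
             stars = .stars(res$p))
}

#' Chromosome- and window-scale association reports
#'
#' Builds the three standard outputs of the association analysis:
#' `fig2` — correlations between per-chromosome mean HE count and each
#' chromosome feature (physical length, genetic length, gene/TE base
#' percentages by class); `table1` — correlations between window HE
#' frequency and window variant/TE-insertion densities, in the fixed row
#' order SNPs, small indels, large indels, TIPs, the three TIP classes,
#' shared TEs, the three shared classes, followed by the window base-percent
#' features; `profiles` — per-chromosome window positions with HE frequency,
#' HR rate and their loess-smoothed curves, plus a per-chromosome
#' correlation table. Significance stars: `*` p < 0.05, `**` p < 0.01.
#'
#' @param chromTable data.frame from [buildChromTable()] (or NULL to skip).
#' @param windowTable data.frame from [buildWindowTable()].
#' @param span,degree smoothing parameters for the profiles.
#' @return list with data.frames `fig2`, `table1`, `profiles`,
#'   `profileCors`.
#' @export
buildReports <- function(chromTable, windowTable, span = 0.2, degree = 2L) {
  fig2 <- NULL
  if (!is.null(chromTable)) {
    feats <- c(physicalLength = "lengthBp", geneticLength = "geneticLengthCM",
               pctGene = "pctGene", pctTE = "pctTE",
               pctRetrotransposon = "pctRetrotransposon",
               pctDNAtransposon = "pctDNAtransposon", pctMITE = "pctMITE")
    fig2 <- do.call(rbind, lapply(names(feats), function(f)
      .corRow(f, chromTable[[feats[[f]]]], chromTable$meanHE)))
  }

  t1feats <- c(SNPs = "snps",
               smallIndels = "smallIndels",
               largeIndels = "largeIndels",
               TIPs = "tips",
               retrotransposonTIPs = "tips_retrotransposon",
               DNAtransposonTIPs = "tips_DNA_transposon",
               MITE_TIPs = "tips_MITE",
               sharedTEs = "sharedTEs",
               sharedRetrotransposons = "shared_retrotransposon",
               sharedDNAtransposons = "shared_DNA_transposon",
               sharedMITEs = "shared_MITE",
               geneBases = "gene",
               teBases = "te",
               retrotransposonBases = "retrotransposon",
               DNAtransposonBases = "DNA_transposon",
               MITEBases = "MITE")
  t1feats <- t1feats[t1feats %in% names(windowTable)]
  table1 <- do.call(rbind, lapply(names(t1feats), function(f)
    .corRow(f, windowTable[[t1feats[[f]]]], windowTable$heFrequency)))

  profiles <- NULL
  profileCors <- NULL
  if ("hrRate" %in% names(windowTable)) {
    profL <- list()
    corL <- list()
    for (ch in unique(windowTable$chrom)) {
      w <- windowTable[windowTable$chrom == ch, ]
      w <- w[order(w$start), ]
      mid <- (w$start + w$end) / 2
      sm <- function(v) tryCatch(smoothProfile(mid, v, span, degree),
                                 error = function(e) rep(NA_real_, length(v)))
      profL[[ch]] <- data.frame(
        chrom = ch, position = mid, heFrequency = w$heFrequency,
        hrRate = w$hrRate, heSmooth = sm(w$heFrequency),
        hrSmooth = sm(w$hrRate))
      corL[[ch]] <- .corRow(ch, w$heFrequency, w$hrRate)
    }
    profiles <- do.call(rbind, profL)
    rownames(profiles) <- NULL
    profileCors <- do.call(rbind, corL)
    names(profileCors)[1] <- "chrom"
  }
  list(fig2 = fig2, table1 = table1, profiles = profiles,
       profileCors = profileCors)
}
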