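#' Create a generator configuration
#'
#' Builds a validated [SimConfig-class]. Defaults describe a rice-like
#' segmental allotetraploid resequencing study: 12 chromosomes of 30 Mb, two
#' diagnostic SNPs per kbp, 20x mean site depth, a 0.5% homoeolog
#' misattribution rate, three expected HE breakpoints per chromosome, and
#' whole-chromosome gain/loss probabilities matching roughly nine gains and
#' ten losses per 20-plant cohort (9/240 and 10/240 per chromosome).
#'
#' @param nChromosomes number of chromosomes.
#' @param chromLengthBp chromosome length in bp (>= 5 Mb).
#' @param snpDensity expected diagnostic SNPs per kbp.
#' @param perSiteDepth mean total allelic reads per site at euploid dosage.
#' @param errorRate probability a read is attributed to the wrong parent.
#' @param heIntensity list of per-chromosome intensity vectors (one value per
#'   1 Mb window), or empty list for a uniform breakpoint landscape. See
#'   [heIntensityFromFeatures()] to derive one from annotation.
#' @param meanHePerChrom expected HE breakpoints per chromosome (Poisson).
#' @param pChromGain,pChromLoss per-chromosome aneuploidy probabilities.
#' @param pSegmental per-chromosome probability of a segmental gain/loss.
#' @param segLengthBp min/max length (bp) of segmental events.
#' @param nIndividuals population size.
#' @param generation cohort label, "S2" or "S4".
#' @param seed integer RNG seed.
#' @return a `SimConfig`.
#' @examples
#' cfg <- SimConfig(nChromosomes = 2, chromLengthBp = 6e6, seed = 1)
#' cfg
#' @export
SimConfig <- function(nChromosomes = 12L, chromLengthBp = 30e6,
                      snpDensity = 2, perSiteDepth = 20,
                      errorRate = 0.005, heIntensity = list(),
                      meanHePerChrom = 3, pChromGain = 9 / 240,
                      pChromLoss = 10 / 240, pSegmental = 0.01,
                      segLengthBp = c(3e6, 8e6), nIndividuals = 20L,
                      generation = c("S2", "S4"), seed = 1L) {
  new("SimConfig",
      nChromosomes = as.integer(nChromosomes),
      chromLengthBp = as.numeric(chromLengthBp),
      snpDensity = as.numeric(snpDensity),
      perSiteDepth = as.numeric(perSiteDepth),
      errorRate = as.numeric(errorRate),
      heIntensity = heIntensity,
      meanHePerChrom = as.numeric(meanHePerChrom),
      pChromGain = as.numeric(pChromGain),
      pChromLoss = as.numeric(pChromLoss),
      pSegmental = as.numeric(pSegmental),
      segLengthBp = as.numeric(segLengthBp),
      nIndividuals = as.integer(nIndividuals),
      generation = match.arg(generation),
      seed = as.integer(seed))
}

.chromNames <- function(n) sprintf("Chr%d", seq_len(n))

# centrality profile: ~1 at the chromosome midpoint (centromere analog),
# ~0 at the ends; drives the opposing gene/retrotransposon gradients
.centrality <- function(t) exp(-((t - 0.5) / 0.18)^2)

.placeIntervals <- function(chrom, len, windowMean, width) {
  nw <- length(windowMean)
  counts <- stats::rpois(nw, windowMean)
  if (sum(counts) == 0L)
    return(GRanges())
  win <- rep.int(seq_len(nw) - 1L, counts)
  starts <- pmin(floor(win * 1e6 + stats::runif(length(win)) * 1e6) + 1, len)
  w <- pmax(1, round(stats::rexp(length(win), 1 / width)))
  ends <- pmin(starts + w - 1, len)
  GRanges(chrom, IRanges(starts, ends))
}

#' Generate the parental panel, annotation tracks, TE table and genetic map
#'
#' Draws the fixed inputs of a simulated study from a [SimConfig-class]:
#' diagnostic SNP positions as a homogeneous Poisson process at `snpDensity`;
#' gene and TE intervals with opposing density gradients (retrotransposons
#' enriched around the chromosome midpoint, genes and MITEs towards the ends,
#' DNA transposons roughly uniform); a TE-insertion table with per-parent
#' frequencies (shared, parent-specific and a few intermediate-frequency
#' insertions); and a monotone genetic map whose recombination rate is
#' suppressed in the central (pericentromeric) region.
#'
#' The function seeds the RNG from `cfg@seed`, so the same configuration
#' always yields the same panel.
#'
#' @param cfg a [SimConfig-class].
#' @return a [ParentPanel-class].
#' @examples
#' panel <- buildParentPanel(SimConfig(nChromosomes = 2, chromLengthBp = 6e6))
#' panel
#' @export
buildParentPanel <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  chroms <- .chromNames(cfg@nChromosomes)
  len <- cfg@chromLengthBp
  lens <- stats::setNames(rep(len, cfg@nChromosomes), chroms)
  nw <- ceiling(len / 1e6)
  tmid <- (seq_len(nw) - 0.5) / nw
  m <- .centrality(tmid)

  snpL <- featL <- list()
  teL <- mapL <- list()
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    lambda <- len / 1000 * cfg@snpDensity
    nsnp <- stats::rpois(1, lambda)
    if (lambda == 0 || nsnp == 0L)
      stop("no diagnostic SNPs generated on ", ch,
           " (snpDensity too low for chromosome length)")
    pos <- sort(sample.int(len, nsnp))
    snpL[[ch]] <- GRanges(ch, IRanges(pos, width = 1), site = seq_len(nsnp))

    # expected covered fraction per window, converted to interval counts
    geneDens <- 0.30 * (1 - 0.75 * m)          # genes deplete centrally
    retroDens <- 0.28 * (0.15 + 0.85 * m)      # retrotransposons central
    dnaDens <- 0.08 * rep(1, nw)               # DNA transposons flat
    miteDens <- 0.06 * (1 - 0.8 * m)           # MITEs distal
    gr <- c(
      .addClass(.placeIntervals(ch, len, geneDens * 1e6 / 3000, 3000), "gene"),
      .addClass(.placeIntervals(ch, len, retroDens * 1e6 / 5000, 5000),
                "retrotransposon"),
      .addClass(.placeIntervals(ch, len, dnaDens * 1e6 / 2000, 2000),
                "DNA_transposon"),
      .addClass(.placeIntervals(ch, len, miteDens * 1e6 / 400, 400), "MITE"))
    featL[[ch]] <- gr

    teL[[ch]] <- .drawTeTable(ch, len, nw, m)
    mapL[[ch]] <- .drawGeneticMap(ch, len)
  }

  snps <- suppressWarnings(do.call(c, unname(snpL)))
  features <- suppressWarnings(do.call(c, unname(featL)))
  new("ParentPanel",
      snps = snps, features = features,
      teTable = do.call(rbind, teL),
      geneticMap = do.call(rbind, mapL),
      chromLengths = lens)
}

.addClass <- function(gr, cls) {
  if (length(gr)) mcols(gr)$class <- cls
  gr
}

.drawTeTable <- function(ch, len, nw, m) {
  per <- list(retrotransposon = 60 * (0.15 + 0.85 * m),
              DNA_transposon = 25 * rep(1, nw),
              MITE = 40 * (1 - 0.8 * m)) # insertions per Mb window by class
  out <- list()
  for (cls in names(per)) {
    counts <- stats::rpois(nw, per[[cls]])
    win <- rep.int(seq_len(nw) - 1L, counts)
    n <- length(win)
    if (!n) next
    pos <- pmin(floor(win * 1e6 + stats::runif(n) * 1e6) + 1, len)
    kind <- sample(c("shared", "tipA", "tipB", "mid"), n, replace = TRUE,
                   prob = c(0.5, 0.2, 0.2, 0.1))
    hi <- function(k) stats::runif(k, 0.96, 1)
    lo <- function(k) stats::runif(k, 0, 0.04)
    mid <- function(k) stats::runif(k, 0.2, 0.8)
    freqA <- ifelse(kind %in% c("shared", "tipA"), hi(n),
                    ifelse(kind == "tipB", lo(n), mid(n)))
    freqB <- ifelse(kind %in% c("shared", "tipB"), hi(n),
                    ifelse(kind == "tipA", lo(n), mid(n)))
    out[[cls]] <- data.frame(chrom = ch, pos = pos, class = cls,
                             freqA = freqA, freqB = freqB)
  }
  res <- do.call(rbind, out)
  res[order(res$pos), , drop = FALSE]
}

# marker grid every ~250 kb; cM is the exact integral of a positive rate
# profile suppressed around the midpoint, so the map is strictly monotone
.drawGeneticMap <- function(ch, len, rateArm = 6, suppression = 0.95) {
  pos <- sort(unique(pmin(len, pmax(
    1, round(seq(1, len, by = 250e3) + stats::rnorm(length(seq(1, len, by = 250e3)), 0, 3e4))))))
  grid <- seq(0, len, length.out = 4096)
  rate <- rateArm * (1 - suppression * .centrality(grid / len)) / 1e6 # cM/bp
  cmGrid <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * diff(grid)))
  cM <- stats::approx(grid, cmGrid, xout = pos)$y
  data.frame(marker = sprintf("%s_M%04d", ch, seq_along(pos)),
             chrom = ch, pos_bp = pos, cM = cM)
}

#' Derive an HE-intensity landscape from annotation
#'
#' Computes a per-1 Mb-window breakpoint intensity from a panel's feature
#' track as a weighted combination of covered base fractions:
#' `geneWeight * gene + retroWeight * retrotransposon + baseline`, truncated
#' at zero. With the default weights the landscape is proportional to gene
#' density and inversely related to retrotransposon density, the structure
#' the association analyses are designed to detect.
#'
#' @param panel a [ParentPanel-class].
#' @param geneWeight,retroWeight weights on the gene and retrotransposon base
#'   fractions.
#' @param baseline additive floor keeping the intensity positive.
#' @param windowBp window size in bp.
#' @return a list of per-chromosome intensity vectors suitable for
#'   `SimConfig(heIntensity = )`.
#' @export
heIntensityFromFeatures <- function(panel, geneWeight = 1, retroWeight = -0.5,
                                    baseline = 0.02, windowBp = 1e6) {
  fr <- windowFeatureFractions(panel, windowBp = windowBp)
  out <- lapply(split(fr, fr$chrom), function(d) {
    d <- d[order(d$start), ]
    pmax(0, geneWeight * d$gene + retroWeight * d$retrotransposon + baseline)
  })
  out[.chromNames(length(chromLengths(panel)))]
}

.sampleBreakpoints <- function(k, len, intensity) {
  if (k == 0L) return(numeric())
  if (is.null(intensity)) {
    pos <- stats::runif(k, 2, len - 1)
  } else {
    if (all(intensity == 0)) {
      warning("all-zero HE intensity; sampling breakpoints uniformly")
      intensity <- rep(1, length(intensity))
    }
    win <- sample.int(length(intensity), k, replace = TRUE, prob = intensity)
    lo <- (win - 1) * 1e6
    hi <- pmin(win * 1e6, len)
    pos <- stats::runif(k, lo, hi)
    pos <- pmin(pmax(pos, 2), len - 1)
  }
  sort(unique(round(pos)))
}

#' Draw one tetraploid dosage mosaic
#'
#' Samples the ground truth of a single individual: per chromosome, a Poisson
#' number (`meanHePerChrom`) of HE breakpoints at positions proportional to
#' the configured intensity landscape; a dosage random walk that starts at
#' the balanced 2:2 state and moves the 9311 copy number by +/-1 at each
#' breakpoint (single reciprocal crossovers), reflecting at 0 and 4; and
#' whole-chromosome / segmental copy-number events at the configured
#' probabilities, each applied to one homoeolog chosen uniformly. Segmental
#' events are only placed on chromosomes without a whole-chromosome change.
#'
#' Uses the current RNG state: seed it (or call via [simulatePopulation()],
#' which does) for reproducibility.
#'
#' @param cfg a [SimConfig-class].
#' @param panel a [ParentPanel-class] from [buildParentPanel()].
#' @param id individual identifier.
#' @return a [TruthIndividual-class].
#' @export
drawMosaic <- function(cfg, panel, id = "ind1") {
  chroms <- .chromNames(cfg@nChromosomes)
  len <- cfg@chromLengthBp
  segL <- list()
  offs <- data.frame(chrom = chroms, offset = 0L,
                     homoeolog = NA_character_)
  evL <- list()
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    k <- stats::rpois(1, cfg@meanHePerChrom)
    intensity <- if (length(cfg@heIntensity)) cfg@heIntensity[[i]] else NULL
    bp <- .sampleBreakpoints(k, len, intensity)
    d <- 2L
    dos <- integer(length(bp) + 1L)
    dos[1] <- d
    for (j in seq_along(bp)) {
      step <- if (d == 0L) 1L else if (d == 4L) -1L else
        sample(c(-1L, 1L), 1)
      d <- d + step
      dos[j + 1L] <- d
    }
    starts <- c(1, bp)
    ends <- c(bp - 1, len)
    segL[[ch]] <- GRanges(ch, IRanges(starts, ends), dosage = dos)

    u <- stats::runif(1)
    if (u < cfg@pChromGain) {
      offs$offset[i] <- sample(c(1L, 2L), 1, prob = c(0.85, 0.15))
      offs$homoeolog[i] <- sample(c("A", "B"), 1)
    } else if (u < cfg@pChromGain + cfg@pChromLoss) {
      offs$offset[i] <- -sample(c(1L, 2L), 1, prob = c(0.85, 0.15))
      offs$homoeolog[i] <- sample(c("A", "B"), 1)
    } else if (stats::runif(1) < cfg@pSegmental) {
      w <- stats::runif(1, cfg@segLengthBp[1], cfg@segLengthBp[2])
      s <- round(stats::runif(1, 1, max(1, len - w)))
      evL[[ch]] <- GRanges(ch, IRanges(s, min(len, round(s + w - 1))),
                           offset = sample(c(-1L, 1L), 1),
                           homoeolog = sample(c("A", "B"), 1))
    }
  }
  segs <- suppressWarnings(do.call(c, unname(segL)))
  evs <- if (length(evL)) suppressWarnings(do.call(c, unname(evL))) else GRanges()
  new("TruthIndividual", segments = segs, chromOffsets = offs,
      segEvents = evs, generation = cfg@generation, id = id)
}

#' Simulate allelic read counts for one individual
#'
#' Converts a ground-truth mosaic into per-site homoeolog-specific read
#' counts. At a site with `a` copies of the 9311 homoeolog and `b` copies of
#' Nipponbare (after whole-chromosome and segmental offsets), total depth is
#' Poisson with mean `perSiteDepth * (a + b) / 4` and the 9311-attributed
#' count is binomial with success probability
#' `(a / (a + b)) * (1 - errorRate) + (b / (a + b)) * errorRate`.
#'
#' Uses the current RNG state (see [drawMosaic()]).
#'
#' @param truth a [TruthIndividual-class].
#' @param panel the matching [ParentPanel-class].
#' @param cfg the [SimConfig-class] used to generate both.
#' @return a one-column [AllelicCounts-class].
#' @export
emitCounts <- function(truth, panel, cfg) {
  sites <- snpPanel(panel)
  chrom <- as.character(seqnames(sites))
  pos <- start(sites)
  n <- length(sites)
  copiesA <- integer(n)
  copiesB <- integer(n)
  segs <- truthSegments(truth)
  segChrom <- as.character(seqnames(segs))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- segs[segChrom == ch]
    o <- order(start(s))
    idx <- findInterval(pos[sel], start(s)[o])
    d <- mcols(s)$dosage[o][idx]
    copiesA[sel] <- d
    copiesB[sel] <- 4L - d
  }
  offs <- chromOffsets(truth)
  for (i in which(offs$offset != 0L)) {
    sel <- chrom == offs$chrom[i]
    if (identical(offs$homoeolog[i], "B"))
      copiesB[sel] <- pmax(0L, copiesB[sel] + offs$offset[i])
    else
      copiesA[sel] <- pmax(0L, copiesA[sel] + offs$offset[i])
  }
  evs <- segmentalEvents(truth)
  for (i in seq_along(evs)) {
    sel <- chrom == as.character(seqnames(evs))[i] &
      pos >= start(evs)[i] & pos <= end(evs)[i]
    if (identical(mcols(evs)$homoeolog[i], "B"))
      copiesB[sel] <- pmax(0L, copiesB[sel] + mcols(evs)$offset[i])
    else
      copiesA[sel] <- pmax(0L, copiesA[sel] + mcols(evs)$offset[i])
  }
  ctot <- copiesA + copiesB
  depth <- stats::rpois(n, cfg@perSiteDepth * ctot / 4)
  fracA <- ifelse(ctot > 0, copiesA / ctot, 0.5)
  p <- fracA * (1 - cfg@errorRate) + (1 - fracA) * cfg@errorRate
  a <- stats::rbinom(n, depth, p)
  AllelicCounts(matrix(a, ncol = 1), matrix(depth - a, ncol = 1),
                sites, individuals = truth@id)
}

#' Simulate a whole study population with ground truth and controls
#'
#' Seeds the RNG from `cfg@seed`, builds the parental panel, draws
#' `nIndividuals` tetraploid mosaics with their allelic counts, and adds
#' three balanced control samples (two reciprocal F1 analogues and a parental
#' mix) that are uniformly 2:2 and euploid, for use by [controlBiasMask()].
#'
#' @param cfg a [SimConfig-class].
#' @return a list with elements `panel` ([ParentPanel-class]), `truth` (list
#'   of [TruthIndividual-class]), `counts` (multi-column
#'   [AllelicCounts-class]) and `controls` (three-column `AllelicCounts`).
#' @examples
#' sim <- simulatePopulation(SimConfig(nChromosomes = 1, chromLengthBp = 5e6,
#'                                     nIndividuals = 2, seed = 42))
#' sim$counts
#' @export
simulatePopulation <- function(cfg) {
  panel <- buildParentPanel(cfg) # seeds the RNG with cfg@seed
  ids <- sprintf("%s-%02d", cfg@generation, seq_len(cfg@nIndividuals))
  truths <- vector("list", cfg@nIndividuals)
  a <- b <- matrix(0L, nrow = length(snpPanel(panel)), ncol = cfg@nIndividuals,
                   dimnames = list(NULL, ids))
  for (j in seq_len(cfg@nIndividuals)) {
    truths[[j]] <- drawMosaic(cfg, panel, id = ids[j])
    cc <- emitCounts(truths[[j]], panel, cfg)
    a[, j] <- count9311(cc)[, 1]
    b[, j] <- countNip(cc)[, 1]
  }
  names(truths) <- ids

  ctlIds <- c("N9-F1", "9N-F1", "MIX")
  balanced <- .balancedTruth(cfg)
  ca <- cb <- matrix(0L, nrow = length(snpPanel(panel)), ncol = 3,
                     dimnames = list(NULL, ctlIds))
  for (j in 1:3) {
    balanced@id <- ctlIds[j]
    cc <- emitCounts(balanced, panel, cfg)
    ca[, j] <- count9311(cc)[, 1]
    cb[, j] <- countNip(cc)[, 1]
  }
  list(panel = panel,
       truth = truths,
       counts = AllelicCounts(a, b, snpPanel(panel), ids),
       controls = AllelicCounts(ca, cb, snpPanel(panel), ctlIds))
}

.balancedTruth <- function(cfg) {
  chroms <- .chromNames(cfg@nChromosomes)
  segs <- GRanges(chroms, IRanges(1, cfg@chromLengthBp), dosage = 2L)
  new("TruthIndividual", segments = segs,
      chromOffsets = data.frame(chrom = chroms, offset = 0L,
                                homoeolog = NA_character_),
      segEvents = GRanges(), generation = cfg@generation, id = "control")
}
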