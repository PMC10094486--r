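#' Group kept SNP sites into fixed-size bins
#'
#' Slices the kept sites of each chromosome into consecutive bins of
#' `binSnps` sites, the unit at which dosage is genotyped: pooling sites
#' damps the sampling noise of per-site depth. A trailing partial bin with
#' at least `ceiling(binSnps / 2)` sites stands alone; a smaller remainder is
#' merged into the previous bin. Chromosomes with fewer than `binSnps` kept
#' sites are skipped with a warning.
#'
#' @param panel a [ParentPanel-class] or a `GRanges` of SNP sites.
#' @param mask optional `DataFrame` with a logical `keep` column aligned to
#'   the sites; NULL keeps everything.
#' @param binSnps sites per bin.
#' @return a data.frame with one row per bin: chrom, bin (index within
#'   chromosome), firstSite, lastSite (row indices into the full site set),
#'   startBp, endBp (positions of the first and last SNP), nSites.
#' @examples
#' sites <- GenomicRanges::GRanges("Chr1",
#'   IRanges::IRanges(seq(1000, 104000, by = 1000), width = 1))
#' nrow(binSites(sites))  # 104 sites -> 10 bins, the last holds 14
#' @export
binSites <- function(panel, mask = NULL, binSnps = 10L) {
  sites <- if (is(panel, "ParentPanel")) snpPanel(panel) else panel
  keep <- if (is.null(mask)) rep(TRUE, length(sites)) else mask$keep
  idx <- which(keep)
  chrom <- as.character(seqnames(sites))[idx]
  pos <- start(sites)[idx]
  out <- list()
  for (ch in unique(chrom)) {
    sel <- idx[chrom == ch]
    n <- length(sel)
    if (n < binSnps) {
      warning("chromosome ", ch, " has ", n, " kept sites (< ", binSnps,
              "); skipped")
      next
    }
    nb <- n %/% binSnps
    rem <- n - nb * binSnps
    sizes <- rep(binSnps, nb)
    if (rem >= ceiling(binSnps / 2)) sizes <- c(sizes, rem)
    else sizes[nb] <- sizes[nb] + rem
    last <- cumsum(sizes)
    first <- last - sizes + 1L
    out[[ch]] <- data.frame(
      chrom = ch, bin = seq_along(sizes),
      firstSite = sel[first], lastSite = sel[last],
      startBp = start(sites)[sel[first]], endBp = start(sites)[sel[last]],
      nSites = sizes)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.DOSAGE_D <- 0:4  # copies of the 9311 homoeolog under each hypothesis

# expected 9311 fraction per hypothesis; epsilon replaces the zero
# expectation of the two homozygous ratios only
.hypothesisFraction <- function(d, epsilon) {
  p <- d / 4
  ifelse(d == 0L, epsilon, ifelse(d == 4L, 1 - epsilon, p))
}

#' G-test statistic of a homoeolog read ratio against a dosage hypothesis
#'
#' Computes the likelihood-ratio goodness-of-fit statistic
#' `G = 2 * (a * log(a / E_a) + b * log(b / E_b))` for `a` reads attributed
#' to 9311 and `b` to Nipponbare, where the expected counts follow the
#' hypothesised homoeolog ratio (9311:Nipponbare = 0:4, 1:3, 2:2, 3:1 or
#' 4:0). Because the 0:4 and 4:0 hypotheses would set an expectation to
#' exactly zero, the misattribution rate `epsilon` replaces 0, giving
#' expected 9311 fractions `epsilon, 1/4, 1/2, 3/4, 1 - epsilon`. Terms with
#' a zero observed count contribute zero. Under the null, G is chi-square
#' with 1 df; vectorised over `a`, `b` and `hypothesis`.
#'
#' @param a,b nonnegative read counts for 9311 and Nipponbare.
#' @param hypothesis dosage hypothesis: one of `"0:4","1:3","2:2","3:1","4:0"`
#'   or the 9311 copy number 0-4.
#' @param epsilon homoeolog misattribution rate standing in for the zero
#'   expectation of the homozygous hypotheses.
#' @return the G statistic (NA where `a + b == 0`).
#' @examples
#' gStat(20, 20, "3:1")  # about 11.51
#' gStat(10, 10, "2:2")  # 0: observed equals expected
#' @export
gStat <- function(a, b, hypothesis, epsilon = 0.005) {
  d <- if (is.character(hypothesis) || is.factor(hypothesis))
    match(as.character(hypothesis), .DOSAGE_LEVELS) - 1L
  else as.integer(hypothesis)
  if (any(is.na(d)) || any(d < 0L | d > 4L))
    stop("hypothesis must be one of ", paste(.DOSAGE_LEVELS, collapse = ", "))
  if (any(a < 0 | b < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  n <- a + b
  p <- .hypothesisFraction(d, epsilon)
  termA <- ifelse(a > 0, a * log(a / (n * p)), 0)
  termB <- ifelse(b > 0, b * log(b / (n * (1 - p))), 0)
  ifelse(n > 0, 2 * (termA + termB), NA_real_)
}

#' Genotype a bin by minimum-G (maximum-likelihood) dosage assignment
#'
#' Evaluates [gStat()] under all five homoeologous-ratio hypotheses and
#' assigns the one with the lowest G (equivalently the highest binomial
#' likelihood and highest 1-df chi-square p-value). Exact ties are broken
#' deterministically: towards the balanced 2:2 state, then towards the
#' smaller departure from balance, then towards the lower 9311 copy number.
#'
#' @param a,b read counts (vectors of equal length).
#' @param epsilon misattribution rate, see [gStat()].
#' @return a data.frame with columns `genotype` (factor with the five ratio
#'   levels), `G`, and `p` (chi-square upper tail, 1 df); rows with
#'   `a + b == 0` are NA throughout (no-call).
#' @examples
#' genotypeBin(c(20, 33, 1), c(20, 7, 39))$genotype  # 2:2, 3:1, 0:4
#' @export
genotypeBin <- function(a, b, epsilon = 0.005) {
  n <- length(a)
  stopifnot(length(b) == n)
  G <- vapply(0:4, function(d) gStat(a, b, d, epsilon), numeric(n))
  G <- matrix(G, nrow = n)
  rowMin <- pmin(G[, 1], G[, 2], G[, 3], G[, 4], G[, 5])
  # tie-break order: 2:2 first, then 1:3/3:1, then 0:4/4:0 (lower d first);
  # assigning in reverse preference lets the preferred hypothesis overwrite
  best <- rep(NA_integer_, n)
  for (j in rev(c(3L, 2L, 4L, 1L, 5L))) {
    sel <- !is.na(G[, j]) & G[, j] == rowMin
    best[sel] <- j
  }
  gBest <- ifelse(is.na(best), NA_real_, G[cbind(seq_len(n), ifelse(is.na(best), 1L, best))])
  data.frame(
    genotype = factor(.DOSAGE_LEVELS[best], levels = .DOSAGE_LEVELS),
    G = gBest,
    p = stats::pchisq(gBest, df = 1, lower.tail = FALSE))
}

#' Genotype all bins of a count table
#'
#' Pools the kept-site reads of each bin from [binSites()] and genotypes the
#' pooled counts with [genotypeBin()], per individual.
#'
#' @param counts an [AllelicCounts-class].
#' @param bins data.frame from [binSites()].
#' @param mask optional site mask (`DataFrame` with `keep`); NULL uses the
#'   mask attached to `counts`, else keeps all sites.
#' @param epsilon misattribution rate.
#' @return a data.frame with one row per individual x bin: individual,
#'   chrom, bin, startBp, endBp, a, b, genotype, G, p.
#' @export
genotypeBins <- function(counts, bins, mask = NULL, epsilon = 0.005) {
  if (is.null(mask)) mask <- siteMask(counts)
  keep <- if (is.null(mask)) rep(TRUE, nrow(counts)) else mask$keep
  aM <- count9311(counts)
  bM <- countNip(counts)
  aM[!keep, ] <- 0L
  bM[!keep, ] <- 0L
  # cumulative sums make pooled bin counts O(1) per bin
  out <- list()
  for (id in colnames(aM)) {
    ca <- cumsum(aM[, id])
    cb <- cumsum(bM[, id])
    a <- ca[bins$lastSite] - c(0, ca)[bins$firstSite]
    b <- cb[bins$lastSite] - c(0, cb)[bins$firstSite]
    g <- genotypeBin(a, b, epsilon)
    out[[id]] <- data.frame(
      individual = id, chrom = bins$chrom, bin = bins$bin,
      startBp = bins$startBp, endBp = bins$endBp,
      a = as.integer(a), b = as.integer(b), g,
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge genotyped bins into dosage fragments
#'
#' Segments one individual's genotyped bins into fragments: maximal runs of
#' equal genotype are merged, fragments spanning fewer than `minFrag` bins
#' are removed, and when a removal leaves two flanking fragments with the
#' same genotype they are re-merged (absorbing the removed bins into the
#' fragment span); removal and re-merging repeat until a fixpoint. Removed
#' bins left between two surviving fragments of different genotype become
#' part of the HE region interval reported by [callHE()].
#'
#' @param bins data.frame of one chromosome's (or several chromosomes', one
#'   individual's) genotyped bins from [genotypeBins()], ordered by bin.
#' @param minFrag minimum bins per surviving fragment.
#' @return a data.frame of fragments: individual, chrom, firstBin, lastBin,
#'   genotype, nBins (bin-index span), startBp, endBp.
#' @examples
#' b <- data.frame(individual = "i1", chrom = "Chr1", bin = 1:20,
#'                 startBp = (1:20) * 1000 - 999, endBp = (1:20) * 1000,
#'                 genotype = rep(c("2:2", "3:1", "2:2"), c(8, 3, 9)))
#' segmentFragments(b)  # 3-bin island removed, flanks re-merge: one fragment
#' @export
segmentFragments <- function(bins, minFrag = 5L) {
  out <- list()
  for (id in unique(bins$individual)) {
    for (ch in unique(bins$chrom[bins$individual == id])) {
      b <- bins[bins$individual == id & bins$chrom == ch, ]
      b <- b[order(b$bin), ]
      b <- b[!is.na(b$genotype), ]
      if (!nrow(b)) next
      r <- rle(as.character(b$genotype))
      endI <- cumsum(r$lengths)
      frags <- data.frame(firstBin = b$bin[endI - r$lengths + 1L],
                          lastBin = b$bin[endI], genotype = r$values)
      repeat {
        frags$nBins <- frags$lastBin - frags$firstBin + 1L
        keep <- frags$nBins >= minFrag
        changed <- any(!keep)
        frags <- frags[keep, , drop = FALSE]
        if (nrow(frags) > 1L) {
          # re-merge adjacent survivors sharing a genotype, absorbing the gap
          merged <- list()
          cur <- frags[1L, ]
          for (k in 2:nrow(frags)) {
            if (frags$genotype[k] == cur$genotype) {
              cur$lastBin <- frags$lastBin[k]
              changed <- TRUE
            } else {
              merged[[length(merged) + 1L]] <- cur
              cur <- frags[k, ]
            }
          }
          merged[[length(merged) + 1L]] <- cur
          frags <- do.call(rbind, merged)
        }
        frags$nBins <- frags$lastBin - frags$firstBin + 1L
        if (!changed || !nrow(frags)) break
      }
      if (!nrow(frags)) {
        warning("all fragments removed on ", ch, " for ", id)
        next
      }
      frags$individual <- id
      frags$chrom <- ch
      frags$startBp <- b$startBp[match(frags$firstBin, b$bin)]
      frags$endBp <- b$endBp[match(frags$lastBin, b$bin)]
      out[[paste(id, ch)]] <- frags[, c("individual", "chrom", "firstBin",
                                        "lastBin", "genotype", "nBins",
                                        "startBp", "endBp")]
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(individual = character(), chrom = character(),
                      firstBin = integer(), lastBin = integer(),
                      genotype = character(), nBins = integer(),
                      startBp = numeric(), endBp = numeric())
  rownames(res) <- NULL
  res
}

#' Call homoeologous-exchange regions between adjacent fragments
#'
#' Each pair of adjacent surviving fragments with different dosage genotypes
#' delimits one HE region: the interval from the last SNP of the left
#' fragment to the first SNP of the right fragment (reported half-open in
#' bp). The true exchange point lies somewhere inside this uncertainty
#' interval.
#'
#' @param fragments data.frame from [segmentFragments()].
#' @return a data.frame of HE regions: individual, chrom, start, end
#'   (half-open), leftGenotype, rightGenotype.
#' @export
callHE <- function(fragments) {
  out <- list()
  for (id in unique(fragments$individual)) {
    for (ch in unique(fragments$chrom[fragments$individual == id])) {
      f <- fragments[fragments$individual == id & fragments$chrom == ch, ]
      f <- f[order(f$firstBin), ]
      if (nrow(f) < 2L) next
      k <- seq_len(nrow(f) - 1L)
      out[[paste(id, ch)]] <- data.frame(
        individual = id, chrom = ch,
        start = f$endBp[k], end = f$startBp[k + 1L],
        leftGenotype = f$genotype[k], rightGenotype = f$genotype[k + 1L])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(individual = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      leftGenotype = character(), rightGenotype = character())
  rownames(res) <- NULL
  res
}

#' Count HE events per individual and chromosome
#'
#' @param regions data.frame from [callHE()].
#' @param individuals,chroms optional vectors fixing the full table layout
#'   (so individuals or chromosomes with zero events appear as 0).
#' @return a data.frame individual x chrom with an `n` column of HE counts.
#' @export
heCountMatrix <- function(regions, individuals = NULL, chroms = NULL) {
  if (is.null(individuals)) individuals <- unique(regions$individual)
  if (is.null(chroms)) chroms <- unique(regions$chrom)
  grid <- expand.grid(individual = individuals, chrom = chroms,
                      stringsAsFactors = FALSE)
  key <- paste(regions$individual, regions$chrom)
  tab <- table(key)
  grid$n <- as.integer(tab[paste(grid$individual, grid$chrom)])
  grid$n[is.na(grid$n)] <- 0L
  grid
}

#' Per-window HE frequency across individuals
#'
#' Each HE region contributes one event to the 1 Mb window containing the
#' midpoint of its uncertainty interval; the window frequency is the event
#' count divided by the number of individuals analysed.
#'
#' @param regions data.frame from [callHE()].
#' @param nIndividuals number of individuals the regions were called from.
#' @param chromLens named vector of chromosome lengths (bp).
#' @param windowBp window size.
#' @return a data.frame: chrom, start, end, count, frequency, covering every
#'   window of every chromosome in `chromLens`.
#' @export
windowHEFrequency <- function(regions, nIndividuals, chromLens,
                              windowBp = 1e6) {
  out <- list()
  for (ch in names(chromLens)) {
    nw <- ceiling(chromLens[[ch]] / windowBp)
    counts <- integer(nw)
    r <- regions[regions$chrom == ch, ]
    if (nrow(r)) {
      mid <- (r$start + r$end) / 2
      w <- pmin(floor(mid / windowBp) + 1L, nw)
      tab <- table(w)
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
    out[[ch]] <- data.frame(
      chrom = ch, start = (seq_len(nw) - 1) * windowBp + 1,
      end = pmin(seq_len(nw) * windowBp, chromLens[[ch]]),
      count = counts, frequency = counts / nIndividuals)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full HE calling for a population
#'
#' Runs the HE pipeline over a count table: bins kept sites, genotypes bins,
#' segments fragments and calls HE regions, restricted to euploid
#' individuals when a karyotype result is supplied (aneuploid depth shifts
#' masquerade as dosage changes, so aneuploid individuals are dropped).
#'
#' @param counts an [AllelicCounts-class].
#' @param mask optional site mask.
#' @param karyo optional result of [callKaryotypes()]; when given, only
#'   euploid individuals are analysed.
#' @param binSnps,epsilon,minFrag tuning parameters, see [binSites()],
#'   [gStat()] and [segmentFragments()].
#' @return a list: `bins`, `fragments`, `regions`, `counts` (per-chromosome
#'   HE count matrix), `individuals` (ids analysed).
#' @export
callHEPopulation <- function(counts, mask = NULL, karyo = NULL,
                             binSnps = 10L, epsilon = 0.005, minFrag = 5L) {
  ids <- colnames(count9311(counts))
  if (!is.null(karyo)) ids <- intersect(ids, euploidIndividuals(karyo))
  if (!length(ids)) stop("no euploid individuals to analyse")
  counts <- counts[, ids]
  if (is.null(mask)) mask <- siteMask(counts)
  bins <- binSites(snpSites(counts), mask, binSnps)
  gb <- genotypeBins(counts, bins, mask, epsilon)
  frags <- segmentFragments(gb, minFrag)
  regions <- callHE(frags)
  list(bins = bins, fragments = frags, regions = regions,
       counts = heCountMatrix(regions, individuals = ids,
                              chroms = unique(bins$chrom)),
       individuals = ids)
}
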