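# shared fixtures built in code
suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

DOSAGES <- c("0:4", "1:3", "2:2", "3:1", "4:0")

# independent oracle: exhaustive binomial log-likelihood argmax over the five
# dosage hypotheses, with the stated tie-break (2:2, then smaller |d-2|,
# then lower d); never calls the package genotyper
oracleGenotype <- function(a, b, epsilon) {
  p <- c(epsilon, 0.25, 0.5, 0.75, 1 - epsilon)
  ll <- vapply(p, function(ph) dbinom(a, a + b, ph, log = TRUE), numeric(1))
  pref <- c(3L, 2L, 4L, 1L, 5L)
  cand <- pref[which(ll[pref] == max(ll))]
  DOSAGES[cand[1]]
}

# direct textual G formula, independent of gStat's internals
directG <- function(a, b, pH) {
  n <- a + b
  ea <- n * pH
  eb <- n * (1 - pH)
  tA <- if (a > 0) a * log(a / ea) else 0
  tB <- if (b > 0) b * log(b / eb) else 0
  2 * (tA + tB)
}

smallConfig <- function(...) {
  args <- list(nChromosomes = 2, chromLengthBp = 6e6, nIndividuals = 2,
               snpDensity = 1, meanHePerChrom = 2, pChromGain = 0,
               pChromLoss = 0, pSegmental = 0, seed = 101)
  do.call(polyhex::SimConfig, utils::modifyList(args, list(...)))
}

# evenly spaced width-1 SNP sites
evenSites <- function(n, chrom = "Chr1", by = 1000) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(seq_len(n) * by, width = 1))
}

# AllelicCounts with constant per-site counts
constantCounts <- function(sites, a, b, ids = "i1") {
  n <- length(sites)
  polyhex::AllelicCounts(matrix(rep(a, n * length(ids)), ncol = length(ids)),
                         matrix(rep(b, n * length(ids)), ncol = length(ids)),
                         sites, ids)
}

# genotyped-bin table for segmentation tests: one bin per kbp
binsFromGenotypes <- function(genotypes, id = "i1", chrom = "Chr1") {
  n <- length(genotypes)
  data.frame(individual = id, chrom = chrom, bin = seq_len(n),
             startBp = (seq_len(n) - 1) * 1000 + 1, endBp = seq_len(n) * 1000,
             a = 20L, b = 20L, genotype = genotypes, G = 0, p = 1)
}

# ground truth with one dosage breakpoint per chromosome at given positions
truthWithBreakpoints <- function(cfg, bpList, dosLeft = 2L, dosRight = 3L) {
  chroms <- sprintf("Chr%d", seq_len(cfg@nChromosomes))
  segs <- list()
  for (i in seq_along(chroms)) {
    bp <- bpList[[i]]
    if (is.null(bp) || is.na(bp)) {
      segs[[i]] <- GenomicRanges::GRanges(
        chroms[i], IRanges::IRanges(1, cfg@chromLengthBp), dosage = dosLeft)
    } else {
      segs[[i]] <- GenomicRanges::GRanges(
        chroms[i], IRanges::IRanges(c(1, bp), c(bp - 1, cfg@chromLengthBp)),
        dosage = c(dosLeft, dosRight))
    }
  }
  methods::new("TruthIndividual",
               segments = suppressWarnings(do.call(c, segs)),
               chromOffsets = data.frame(chrom = chroms, offset = 0L,
                                         homoeolog = NA_character_),
               segEvents = GenomicRanges::GRanges(),
               generation = "S2", id = "t1")
}
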