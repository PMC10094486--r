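#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowData rowData<- colData
NULL

.DOSAGE_LEVELS <- c("0:4", "1:3", "2:2", "3:1", "4:0")
.TE_CLASSES <- c("retrotransposon", "DNA_transposon", "MITE")

#' Configuration of the synthetic tetraploid population generator
#'
#' A `SimConfig` bundles every parameter of the generative model: the genome
#' layout (chromosome number and length, diagnostic-SNP density), the
#' sequencing model (mean per-site depth, homoeolog misattribution rate
#' `errorRate`), the homoeologous-exchange (HE) process (expected breakpoints
#' per chromosome and an optional per-megabase intensity landscape), and the
#' chromosome-instability process (whole-chromosome gain/loss and segmental
#' event probabilities).
#'
#' @slot nChromosomes integer, number of chromosomes (12 for a rice-like
#'   genome).
#' @slot chromLengthBp numeric, chromosome length in bp (all chromosomes share
#'   one length; must be at least 5 Mb).
#' @slot snpDensity numeric, expected diagnostic SNPs per kbp.
#' @slot perSiteDepth numeric, mean total reads per SNP site at euploid
#'   (four-copy) dosage.
#' @slot errorRate numeric in `[0, 0.25)`, probability that a read is
#'   attributed to the wrong parent; also the expected discordant fraction
#'   under the 0:4 and 4:0 hypotheses.
#' @slot heIntensity list of per-chromosome numeric vectors, one nonnegative
#'   value per 1 Mb window, giving the relative breakpoint intensity; an empty
#'   list means a uniform landscape.
#' @slot meanHePerChrom numeric, expected HE breakpoints per chromosome per
#'   individual (Poisson mean).
#' @slot pChromGain,pChromLoss numeric, per-chromosome probabilities of a
#'   whole-chromosome gain or loss.
#' @slot pSegmental numeric, per-chromosome probability of one segmental
#'   gain/loss event.
#' @slot segLengthBp numeric length-2, min/max bp length of segmental events.
#' @slot nIndividuals integer, population size.
#' @slot generation character, cohort label ("S2" or "S4"); only a label that
#'   parameterises rates, no meiosis is simulated across generations.
#' @slot seed integer RNG seed; identical config + seed gives byte-identical
#'   output.
#'
#' @seealso [SimConfig()] for the user constructor with defaults,
#'   [buildParentPanel()], [simulatePopulation()].
#' @export
setClass("SimConfig", representation(
  nChromosomes = "integer",
  chromLengthBp = "numeric",
  snpDensity = "numeric",
  perSiteDepth = "numeric",
  errorRate = "numeric",
  heIntensity = "list",
  meanHePerChrom = "numeric",
  pChromGain = "numeric",
  pChromLoss = "numeric",
  pSegmental = "numeric",
  segLengthBp = "numeric",
  nIndividuals = "integer",
  generation = "character",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  probs <- c(gain = object@pChromGain, loss = object@pChromLoss,
             segmental = object@pSegmental)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "event probabilities must lie in [0, 1]")
  if (object@errorRate < 0 || object@errorRate >= 0.25)
    msg <- c(msg, "errorRate must lie in [0, 0.25) to keep 0:4 separable from 1:3")
  if (object@nChromosomes < 1L)
    msg <- c(msg, "need at least one chromosome")
  if (object@chromLengthBp < 5e6)
    msg <- c(msg, "chromLengthBp must be >= 5e6")
  if (object@snpDensity <= 0)
    msg <- c(msg, "snpDensity must be positive")
  if (object@perSiteDepth <= 0)
    msg <- c(msg, "perSiteDepth must be positive")
  if (object@meanHePerChrom < 0)
    msg <- c(msg, "meanHePerChrom must be nonnegative")
  if (length(object@segLengthBp) != 2L || any(object@segLengthBp <= 0) ||
      diff(object@segLengthBp) < 0)
    msg <- c(msg, "segLengthBp must be an increasing length-2 positive vector")
  if (object@nIndividuals < 1L)
    msg <- c(msg, "nIndividuals must be >= 1")
  if (length(object@heIntensity)) {
    nw <- ceiling(object@chromLengthBp / 1e6)
    if (length(object@heIntensity) != object@nChromosomes)
      msg <- c(msg, "heIntensity must have one vector per chromosome")
    else {
      ok <- vapply(object@heIntensity,
                   function(v) length(v) == nw && all(v >= 0), logical(1))
      if (!all(ok))
        msg <- c(msg, sprintf(
          "each heIntensity vector needs one nonnegative value per 1 Mb window (%d)", nw))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Parental reference panel and annotation bundle
#'
#' Holds everything the analysis treats as fixed, parent-derived input: the
#' ordered diagnostic SNP panel separating the two homoeologous subgenomes,
#' gene/TE feature intervals, the TE-insertion frequency table, and the
#' genetic map used for Marey-map recombination-rate estimation.
#'
#' @slot snps `GRanges` of width-1 diagnostic SNP sites, ordered by position
#'   within chromosome, with a per-chromosome `site` index in `mcols`.
#' @slot features `GRanges` of annotation intervals with an mcols column
#'   `class` in gene/retrotransposon/DNA_transposon/MITE.
#' @slot teTable data.frame of TE insertions: chrom, pos, class, freqA
#'   (frequency in parent A = 9311-like), freqB (parent B = Nipponbare-like).
#' @slot geneticMap data.frame of markers: marker, chrom, pos_bp, cM.
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @export
setClass("ParentPanel", representation(
  snps = "GRanges",
  features = "GRanges",
  teTable = "data.frame",
  geneticMap = "data.frame",
  chromLengths = "numeric"
))

setValidity("ParentPanel", function(object) {
  msg <- character()
  if (is.null(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be named")
  pos <- start(object@snps)
  chrom <- as.character(seqnames(object@snps))
  if (length(pos) && is.unsorted(order(chrom)) == FALSE) {
    bad <- tapply(pos, chrom, function(p) any(diff(p) <= 0))
    if (any(unlist(bad)))
      msg <- c(msg, "SNP positions must be strictly increasing within chromosomes")
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth dosage mosaic of one simulated tetraploid
#'
#' The simulated truth for a single individual: per chromosome, a tiling of
#' dosage segments (number of 9311 copies, 0-4, out of the euploid 4),
#' whole-chromosome copy-number offsets, and segmental gain/loss events.
#' Exported alongside simulated counts so callers can be scored against it.
#'
#' @slot segments `GRanges` tiling each chromosome, with mcols column
#'   `dosage` (integer 0-4 = copies of parent A / 9311).
#' @slot chromOffsets data.frame: chrom, offset (-2..+2), homoeolog ("A" or
#'   "B", which subgenome gained/lost).
#' @slot segEvents `GRanges` of segmental events with mcols `offset` and
#'   `homoeolog`.
#' @slot generation character cohort label.
#' @slot id character individual identifier.
#' @export
setClass("TruthIndividual", representation(
  segments = "GRanges",
  chromOffsets = "data.frame",
  segEvents = "GRanges",
  generation = "character",
  id = "character"
))

setValidity("TruthIndividual", function(object) {
  d <- mcols(object@segments)$dosage
  if (is.null(d) || any(d < 0L) || any(d > 4L))
    return("segment dosage must be an integer in 0..4")
  # segments must tile each chromosome without gaps or overlap
  segs <- object@segments
  for (ch in unique(as.character(seqnames(segs)))) {
    s <- segs[seqnames(segs) == ch]
    o <- order(start(s))
    if (any(start(s)[o][-1] != end(s)[o][-length(s)] + 1L))
      return(sprintf("segments do not tile chromosome %s", ch))
  }
  TRUE
})

#' Homoeolog-specific allelic read counts
#'
#' `AllelicCounts` extends `RangedSummarizedExperiment`: rows are diagnostic
#' SNP sites (the `rowRanges` are the SNP panel), columns are individuals, and
#' the two assays `count9311` / `countNip` carry the reads attributed to each
#' parental homoeolog. The site bias mask, when computed, lives in `rowData`
#' (columns `keep`, `reason`).
#'
#' @seealso [AllelicCounts()], [count9311()], [countNip()],
#'   [controlBiasMask()]
#' @export
setClass("AllelicCounts", contains = "RangedSummarizedExperiment")

setValidity("AllelicCounts", function(object) {
  an <- names(assays(object))
  if (!all(c("count9311", "countNip") %in% an))
    return("assays must include 'count9311' and 'countNip'")
  if (any(assay(object, "count9311") < 0) || any(assay(object, "countNip") < 0))
    return("counts must be nonnegative")
  TRUE
})

#' @describeIn AllelicCounts-class Construct from two count matrices and a
#'   SNP panel (`GRanges` of sites, rows) and individual names (columns).
#' @param count9311,countNip integer matrices (sites x individuals) of reads
#'   attributed to the 9311 and Nipponbare homoeolog.
#' @param sites `GRanges` of the SNP sites, one per row.
#' @param individuals character vector of column names.
#' @return an `AllelicCounts` object.
#' @export
AllelicCounts <- function(count9311, countNip, sites,
                          individuals = colnames(count9311)) {
  count9311 <- as.matrix(count9311)
  countNip <- as.matrix(countNip)
  if (is.null(individuals))
    individuals <- paste0("ind", seq_len(ncol(count9311)))
  colnames(count9311) <- colnames(countNip) <- individuals
  se <- SummarizedExperiment(
    assays = list(count9311 = count9311, countNip = countNip),
    rowRanges = sites,
    colData = DataFrame(individual = individuals, row.names = individuals))
  new("AllelicCounts", se)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChromosomes, "chromosomes x",
      format(object@chromLengthBp, big.mark = ","), "bp\n")
  cat("  SNP density:", object@snpDensity, "/kbp | depth:",
      object@perSiteDepth, "x | error rate:", object@errorRate, "\n")
  cat("  HE/chrom:", object@meanHePerChrom,
      "| P(gain/loss/segmental):", object@pChromGain, "/",
      object@pChromLoss, "/", object@pSegmental, "\n")
  cat("  individuals:", object@nIndividuals,
      "| generation:", object@generation, "| seed:", object@seed, "\n")
})

setMethod("show", "ParentPanel", function(object) {
  cat("ParentPanel:", length(object@chromLengths), "chromosomes,",
      length(object@snps), "diagnostic SNPs\n")
  cat("  features:", length(object@features), "intervals |",
      nrow(object@teTable), "TE insertions |",
      nrow(object@geneticMap), "map markers\n")
})

setMethod("show", "TruthIndividual", function(object) {
  nhe <- sum(tapply(mcols(object@segments)$dosage,
                    as.character(seqnames(object@segments)), length) - 1L)
  cat("TruthIndividual", object@id, "(", object@generation, "):",
      length(object@segments), "dosage segments,",
      nhe, "HE breakpoints\n")
  if (any(object@chromOffsets$offset != 0L))
    cat("  aneuploid chromosomes:",
        paste(object@chromOffsets$chrom[object@chromOffsets$offset != 0L],
              collapse = ", "), "\n")
  if (length(object@segEvents))
    cat("  segmental events:", length(object@segEvents), "\n")
})
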