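#' Fraction of bases covered by a feature class
#'
#' Computes the fraction of a region (a chromosome or window) covered by the
#' intervals of a track, merging overlaps of the same class first so no base
#' is counted twice. Intervals extending past the region are clipped with a
#' warning.
#'
#' @param track `GRanges` of feature intervals (one class; subset a combined
#'   track by its `class` column first, or see [windowFeatureFractions()]).
#' @param region a `GRanges` of length 1 delimiting the region.
#' @return a single fraction in `[0, 1]`.
#' @examples
#' track <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 51), c(100, 150)))
#' region <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 1000))
#' percentBases(track, region)  # merged coverage 150 / 1000 = 0.15
#' @export
percentBases <- function(track, region) {
  stopifnot(is(track, "GRanges"), is(region, "GRanges"), length(region) == 1L)
  if (!length(track)) return(0)
  track <- track[as.character(seqnames(track)) ==
                   as.character(seqnames(region))]
  if (!length(track)) return(0)
  if (any(start(track) < start(region)) || any(end(track) > end(region)))
    warning("intervals extend beyond the region; clipped")
  red <- GenomicRanges::reduce(track, ignore.strand = TRUE)
  ov <- GenomicRanges::intersect(red, region, ignore.strand = TRUE)
  sum(width(ov)) / width(region)
}

#' Classify a TE insertion as shared, parent-specific (TIP) or unclassified
#'
#' A TE is called present in a parent when its detected insertion frequency
#' exceeds `hi` and absent when below `lo`; intermediate frequencies are
#' indeterminate. Present/present is a shared TE; present/absent a TIP of
#' parent A; absent/present a TIP of parent B; anything involving an
#' indeterminate frequency is unclassified and excluded downstream.
#' Vectorised.
#'
#' @param freqA,freqB detected insertion frequency in each parent, in `[0,1]`.
#' @param hi,lo presence/absence thresholds (defaults 0.95 and 0.05).
#' @return factor with levels shared, TIP_A, TIP_B, unclassified.
#' @examples
#' classifyTE(c(1, 0.98, 0.98), c(1, 0.02, 0.5))
#' @export
classifyTE <- function(freqA, freqB, hi = 0.95, lo = 0.05) {
  stopifnot(all(freqA >= 0 & freqA <= 1), all(freqB >= 0 & freqB <= 1))
  stateA <- ifelse(freqA > hi, "P", ifelse(freqA < lo, "A", "I"))
  stateB <- ifelse(freqB > hi, "P", ifelse(freqB < lo, "A", "I"))
  status <- rep("unclassified", length(freqA))
  status[stateA == "P" & stateB == "P"] <- "shared"
  status[stateA == "P" & stateB == "A"] <- "TIP_A"
  status[stateA == "A" & stateB == "P"] <- "TIP_B"
  factor(status, levels = c("shared", "TIP_A", "TIP_B", "unclassified"))
}

.windowIndex <- function(pos, windowBp) floor((pos - 1) / windowBp) + 1L

.windowScaffold <- function(chromLens, windowBp) {
  out <- lapply(names(chromLens), function(ch) {
    nw <- ceiling(chromLens[[ch]] / windowBp)
    data.frame(chrom = ch, start = (seq_len(nw) - 1) * windowBp + 1,
               end = pmin(seq_len(nw) * windowBp, chromLens[[ch]]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.countPerWindow <- function(scaffold, chrom, pos, windowBp) {
  key <- paste(scaffold$chrom, .windowIndex(scaffold$start, windowBp))
  tab <- table(paste(chrom, .windowIndex(pos, windowBp)))
  n <- as.integer(tab[key])
  n[is.na(n)] <- 0L
  n
}

#' Per-window variant and TE-insertion densities
#'
#' Counts, in fixed windows: SNPs; small indels (length 1-99 bp); large
#' indels (length >= 100 bp — the two classes partition all lengths >= 1);
#' and TIP / shared-TE insertions overall and by TE class. A zero-length
#' indel is an error.
#'
#' @param snps data.frame with chrom, pos of SNPs (may be NULL).
#' @param indels data.frame with chrom, pos, length (may be NULL).
#' @param teTable data.frame with chrom, pos, class, freqA, freqB (may be
#'   NULL), classified via [classifyTE()].
#' @param chromLens named vector of chromosome lengths.
#' @param windowBp window size in bp.
#' @param hi,lo TE presence/absence thresholds passed to [classifyTE()].
#' @return a data.frame with one row per window: chrom, start, end, snps,
#'   smallIndels, largeIndels, tips, sharedTEs, and per-class columns
#'   `tips_<class>` / `shared_<class>`.
#' @export
windowVariantDensity <- function(snps = NULL, indels = NULL, teTable = NULL,
                                 chromLens, windowBp = 1e6,
                                 hi = 0.95, lo = 0.05) {
  sc <- .windowScaffold(chromLens, windowBp)
  zero <- integer(nrow(sc))
  sc$snps <- if (is.null(snps) || !nrow(snps)) zero else
    .countPerWindow(sc, snps$chrom, snps$pos, windowBp)
  if (!is.null(indels) && nrow(indels)) {
    if (any(indels$length == 0)) stop("indel of length 0")
    small <- indels[indels$length < 100, ]
    large <- indels[indels$length >= 100, ]
    sc$smallIndels <- .countPerWindow(sc, small$chrom, small$pos, windowBp)
    sc$largeIndels <- .countPerWindow(sc, large$chrom, large$pos, windowBp)
  } else sc$smallIndels <- sc$largeIndels <- zero
  teClasses <- .TE_CLASSES
  if (!is.null(teTable) && nrow(teTable)) {
    st <- classifyTE(teTable$freqA, teTable$freqB, hi, lo)
    isTip <- st %in% c("TIP_A", "TIP_B")
    isShared <- st == "shared"
    sc$tips <- .countPerWindow(sc, teTable$chrom[isTip], teTable$pos[isTip],
                               windowBp)
    sc$sharedTEs <- .countPerWindow(sc, teTable$chrom[isShared],
                                    teTable$pos[isShared], windowBp)
    for (cls in teClasses) {
      selT <- isTip & teTable$class == cls
      selS <- isShared & teTable$class == cls
      sc[[paste0("tips_", cls)]] <-
        .countPerWindow(sc, teTable$chrom[selT], teTable$pos[selT], windowBp)
      sc[[paste0("shared_", cls)]] <-
        .countPerWindow(sc, teTable$chrom[selS], teTable$pos[selS], windowBp)
    }
  } else {
    sc$tips <- sc$sharedTEs <- zero
    for (cls in teClasses) {
      sc[[paste0("tips_", cls)]] <- zero
      sc[[paste0("shared_", cls)]] <- zero
    }
  }
  sc
}

#' Per-window base fractions of gene and TE classes
#'
#' For every fixed window of every chromosome, the fraction of bases covered
#' by each feature class of a combined annotation track (overlaps within a
#' class merged first). Where MITE and DNA-transposon annotations nest, the
#' interval's own class label wins: classes are treated as mutually
#' exclusive labels of the input track.
#'
#' @param panel a [ParentPanel-class], or a `GRanges` track with a `class`
#'   mcols column (then `chromLens` is required).
#' @param chromLens named chromosome lengths; taken from the panel when
#'   omitted.
#' @param windowBp window size in bp.
#' @return a data.frame: chrom, start, end and one fraction column per class
#'   present (gene, retrotransposon, DNA_transposon, MITE), plus `te` = sum
#'   of the TE classes.
#' @export
windowFeatureFractions <- function(panel, chromLens = NULL, windowBp = 1e6) {
  if (is(panel, "ParentPanel")) {
    track <- featureTrack(panel)
    chromLens <- chromLengths(panel)
  } else track <- panel
  stopifnot(!is.null(chromLens))
  sc <- .windowScaffold(chromLens, windowBp)
  win <- GRanges(sc$chrom, IRanges(sc$start, sc$end))
  classes <- c("gene", .TE_CLASSES)
  for (cls in classes) {
    sub <- track[mcols(track)$class == cls]
    cov <- numeric(length(win))
    if (length(sub)) {
      red <- GenomicRanges::reduce(sub, ignore.strand = TRUE)
      hits <- GenomicRanges::findOverlaps(win, red, ignore.strand = TRUE)
      if (length(hits)) {
        pi <- GenomicRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                        red[S4Vectors::subjectHits(hits)])
        covered <- tapply(width(pi), S4Vectors::queryHits(hits), sum)
        cov[as.integer(names(covered))] <- covered
      }
    }
    sc[[cls]] <- cov / width(win)
  }
  sc$te <- sc$retrotransposon + sc$DNA_transposon + sc$MITE
  sc
}

#' Chromosome-scale feature summary
#'
#' Aggregates base fractions to whole chromosomes: percentage of gene bases,
#' total TE bases and each TE class, plus physical length and (when a
#' genetic map is given) genetic length in cM.
#'
#' @param panel a [ParentPanel-class].
#' @param map optional curated genetic map (data.frame with chrom, cM);
#'   defaults to the panel's.
#' @return a data.frame with one row per chromosome: chrom, lengthBp,
#'   geneticLengthCM, pctGene, pctTE, pctRetrotransposon, pctDNAtransposon,
#'   pctMITE (percent scale 0-100).
#' @export
chromFeatureTable <- function(panel, map = geneticMap(panel)) {
  lens <- chromLengths(panel)
  track <- featureTrack(panel)
  out <- lapply(names(lens), function(ch) {
    region <- GRanges(ch, IRanges(1, lens[[ch]]))
    sub <- function(cls) track[mcols(track)$class == cls &
                                 as.character(seqnames(track)) == ch]
    gl <- if (!is.null(map) && nrow(map)) {
      cm <- map$cM[map$chrom == ch]
      if (length(cm)) max(cm) - min(cm) else NA_real_
    } else NA_real_
    teCls <- vapply(.TE_CLASSES,
                    function(cl) percentBases(sub(cl), region), numeric(1))
    data.frame(chrom = ch, lengthBp = lens[[ch]], geneticLengthCM = gl,
               pctGene = 100 * percentBases(sub("gene"), region),
               pctTE = 100 * sum(teCls),
               pctRetrotransposon = 100 * teCls[["retrotransposon"]],
               pctDNAtransposon = 100 * teCls[["DNA_transposon"]],
               pctMITE = 100 * teCls[["MITE"]])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
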