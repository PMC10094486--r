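#' Per-window allelic depth painting
#'
#' Bins each chromosome into fixed `windowBp` tiles and computes, per
#' individual, the mean total allelic depth (9311 + Nipponbare reads) over
#' the kept SNP sites in each window, plus the depth relative to the
#' individual's genome-wide mean per-site depth. Windows with fewer than
#' `minSites` kept sites are flagged excluded and carry no state downstream.
#' The trailing partial window of a chromosome is kept when it reaches
#' `minSites`.
#'
#' The global per-individual depth used for normalisation is, by default,
#' the median over windows of the window mean depth: unlike the genome-wide
#' mean it is not inflated by the aneuploid chromosomes the painting is
#' meant to reveal (so an aberrant chromosome sits on its exact rung
#' `(4 + k) / 4`), and unlike a per-site median it is not quantised to
#' integer read counts. `globalStat = "mean"` gives the plain genome-wide
#' mean per-site depth instead.
#'
#' @param counts an [AllelicCounts-class].
#' @param mask optional `DataFrame` from [controlBiasMask()]; when NULL, the
#'   mask attached to `counts` is used, else all sites are kept.
#' @param windowBp window size in bp.
#' @param minSites minimum kept SNP sites for a window to be scored.
#' @param globalStat statistic of the genome-wide per-site depth used as the
#'   normaliser: `"median"` (robust, default) or `"mean"`.
#' @return a data.frame with columns individual, chrom, start, end (1-based
#'   inclusive), nSites, meanDepth, relDepth, excluded.
#' @export
windowDepths <- function(counts, mask = NULL, windowBp = 1e6, minSites = 5L,
                         globalStat = c("median", "mean")) {
  globalStat <- match.arg(globalStat)
  if (is.null(mask)) mask <- siteMask(counts)
  keep <- if (is.null(mask)) rep(TRUE, nrow(counts)) else mask$keep
  if (!any(keep))
    stop("no kept sites genome-wide; cannot compute window depths")
  sites <- snpSites(counts)[keep]
  depth <- siteDepth(counts)[keep, , drop = FALSE]
  chrom <- as.character(seqnames(sites))
  win <- (start(sites) - 1L) %/% windowBp
  grp <- factor(paste0(chrom, ":", win),
                levels = unique(paste0(chrom, ":", win)))
  nSites <- as.integer(table(grp)[levels(grp)])
  out <- list()
  for (id in colnames(depth)) {
    md <- tapply(depth[, id], grp, mean)[levels(grp)]
    globalDepth <- if (globalStat == "median")
      stats::median(md[nSites >= minSites]) else mean(depth[, id])
    out[[id]] <- data.frame(
      individual = id,
      chrom = sub(":.*", "", levels(grp)),
      start = as.integer(sub(".*:", "", levels(grp))) * windowBp + 1,
      end = (as.integer(sub(".*:", "", levels(grp))) + 1) * windowBp,
      nSites = nSites,
      meanDepth = as.numeric(md),
      relDepth = as.numeric(md) / globalDepth,
      excluded = nSites < minSites,
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify windows onto copy-number rungs
#'
#' Assigns each scored window a copy-number state from its relative depth.
#' In a euploid tetraploid the expected relative depth of a window with a
#' whole-chromosome offset of k is (4 + k)/4, giving the rungs 0.5, 0.75,
#' 1, 1.25 and 1.5. A window is called -2 when `relDepth <= 0.5 + delta`,
#' -1 when `<= 0.75 + delta`, +2 when `>= 1.5 - delta`, +1 when
#' `>= 1.25 - delta`, and 0 otherwise; `delta` is a half-band tolerance
#' absorbing sampling noise around each rung. Excluded windows get NA.
#'
#' @param wd data.frame from [windowDepths()].
#' @param cutoffs the four rungs (loss2, loss1, gain1, gain2) as multiples of
#'   global depth.
#' @param delta half-band tolerance around each rung.
#' @return `wd` with an integer `state` column.
#' @examples
#' wd <- data.frame(relDepth = c(1, 1.25, 0.5), excluded = FALSE)
#' classifyWindows(wd)$state  # 0, +1, -2
#' @export
classifyWindows <- function(wd, cutoffs = c(0.5, 0.75, 1.25, 1.5),
                            delta = 0.05) {
  r <- wd$relDepth
  state <- integer(length(r))
  state[r >= cutoffs[3] - delta] <- 1L
  state[r >= cutoffs[4] - delta] <- 2L
  state[r <= cutoffs[2] + delta] <- -1L
  state[r <= cutoffs[1] + delta] <- -2L
  state[wd$excluded] <- NA_integer_
  wd$state <- state
  wd
}

#' Summarise window states into karyotype calls
#'
#' Calls the whole-chromosome copy-number state per individual and
#' chromosome: when one non-zero state covers at least `modalFrac` of the
#' classified windows it becomes the chromosome state; otherwise the
#' chromosome is called 0 and maximal runs of at least `minRun` consecutive
#' windows sharing a non-zero state are reported as segmental gain/loss
#' events.
#' `confidence` is the fraction of classified windows agreeing with the
#' chromosome call. Chromosomes with no classified windows are called NA
#' ("unknown").
#'
#' @param wd data.frame from [classifyWindows()].
#' @param modalFrac fraction of windows the modal state must reach for a
#'   whole-chromosome call.
#' @param minRun minimum consecutive aberrant windows for a segmental event.
#' @return a list with `calls` (individual, chrom, state, confidence) and
#'   `events` (individual, chrom, start, end, offset, nWindows).
#' @export
summarizeKaryotype <- function(wd, modalFrac = 0.8, minRun = 3L) {
  calls <- list()
  events <- list()
  for (id in unique(wd$individual)) {
    for (ch in unique(wd$chrom[wd$individual == id])) {
      w <- wd[wd$individual == id & wd$chrom == ch, ]
      w <- w[order(w$start), ]
      st <- w$state[!is.na(w$state)]
      if (!length(st)) {
        calls[[length(calls) + 1L]] <- data.frame(
          individual = id, chrom = ch, state = NA_integer_, confidence = NA_real_)
        next
      }
      tab <- table(st)
      modal <- as.integer(names(tab)[which.max(tab)])
      frac <- max(tab) / length(st)
      if (modal != 0L && frac >= modalFrac) {
        calls[[length(calls) + 1L]] <- data.frame(
          individual = id, chrom = ch, state = modal, confidence = frac)
        next
      }
      calls[[length(calls) + 1L]] <- data.frame(
        individual = id, chrom = ch, state = 0L,
        confidence = sum(st == 0L) / length(st))
      # segmental events: runs of identical non-zero state over scored windows
      ws <- w[!is.na(w$state), ]
      r <- rle(ws$state)
      endIdx <- cumsum(r$lengths)
      startIdx <- endIdx - r$lengths + 1L
      for (k in which(r$values != 0L & r$lengths >= minRun)) {
        events[[length(events) + 1L]] <- data.frame(
          individual = id, chrom = ch,
          start = ws$start[startIdx[k]], end = ws$end[endIdx[k]],
          offset = r$values[k], nWindows = r$lengths[k])
      }
    }
  }
  list(calls = do.call(rbind, calls),
       events = if (length(events)) do.call(rbind, events) else
         data.frame(individual = character(), chrom = character(),
                    start = numeric(), end = numeric(),
                    offset = integer(), nWindows = integer()))
}

#' One-call karyotyping convenience wrapper
#'
#' Runs [windowDepths()], [classifyWindows()] and [summarizeKaryotype()].
#'
#' @inheritParams windowDepths
#' @inheritParams classifyWindows
#' @inheritParams summarizeKaryotype
#' @return as [summarizeKaryotype()], plus the classified window table as
#'   `windows`.
#' @export
callKaryotypes <- function(counts, mask = NULL, windowBp = 1e6,
                           minSites = 5L, cutoffs = c(0.5, 0.75, 1.25, 1.5),
                           delta = 0.05, modalFrac = 0.8, minRun = 3L,
                           globalStat = c("median", "mean")) {
  wd <- classifyWindows(
    windowDepths(counts, mask, windowBp, minSites, globalStat),
    cutoffs, delta)
  out <- summarizeKaryotype(wd, modalFrac, minRun)
  out$windows <- wd
  out
}

#' Identify euploid individuals from karyotype calls
#'
#' An individual is euploid when every chromosome is confidently called state
#' 0 and it has no segmental event; individuals with any unknown chromosome
#' are treated as non-euploid.
#'
#' @param karyo result of [summarizeKaryotype()] or [callKaryotypes()].
#' @return character vector of euploid individual ids.
#' @export
euploidIndividuals <- function(karyo) {
  calls <- karyo$calls
  ok <- tapply(calls$state, calls$individual,
               function(s) all(!is.na(s)) && all(s == 0L))
  ids <- names(ok)[ok]
  setdiff(ids, unique(karyo$events$individual))
}
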