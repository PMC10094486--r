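#' Mask sites with biased homoeolog depth in control samples
#'
#' Control samples (reciprocal F1 hybrids, a parental mix) carry a true 1:1
#' homoeolog ratio at every diagnostic site, so any strong imbalance there
#' marks a site whose reads cannot be attributed reliably. A site is masked
#' as `biased_control` when, in any control, the larger count is at least
#' twice the smaller (the two-fold rule, boundary inclusive) with the smaller
#' positive, or when one side is zero while the other reaches `zeroFloor`
#' (default 4) — the floor avoids masking on sampling noise at very low
#' depth. A site whose total depth in every informative sense is below
#' `minDepth` reads in any control is masked as `low_coverage`.
#'
#' Masking is monotone: adding a further control can only remove sites.
#'
#' @param controls an [AllelicCounts-class] whose columns are the control
#'   samples (at least one column).
#' @param zeroFloor minimum nonzero count that masks a site when the other
#'   homoeolog has zero reads.
#' @param minDepth minimum total allelic depth per control below which a site
#'   is masked as low coverage.
#' @return a `DataFrame` with one row per site: `keep` (logical) and `reason`
#'   (`"ok"`, `"biased_control"` or `"low_coverage"`).
#' @examples
#' sites <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(c(100, 200, 300), width = 1))
#' ctl <- AllelicCounts(matrix(c(30L, 15L, 20L)), matrix(c(10L, 10L, 10L)),
#'                      sites, "MIX")
#' controlBiasMask(ctl)$reason  # (30,10) and (20,10) are two-fold biased
#' @export
controlBiasMask <- function(controls, zeroFloor = 4L, minDepth = 2L) {
  if (!is(controls, "AllelicCounts") || ncol(controls) < 1L)
    stop("need an AllelicCounts object with at least one control column")
  a <- count9311(controls)
  b <- countNip(controls)
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  biased <- (lo > 0L & hi >= 2L * lo) | (lo == 0L & hi >= zeroFloor)
  lowcov <- (a + b) < minDepth
  anyBiased <- rowSums(biased) > 0L
  anyLow <- rowSums(lowcov & !biased) > 0L
  reason <- rep("ok", nrow(a))
  reason[anyLow] <- "low_coverage"
  reason[anyBiased] <- "biased_control"
  DataFrame(keep = reason == "ok", reason = reason)
}

#' Read and write allelic count tables
#'
#' The on-disk format is a long TSV with header columns `individual`,
#' `chrom`, `pos`, `count_9311`, `count_nip`; positions are 1-based. All
#' individuals must report the same ordered site set. `readAllelicCounts()`
#' validates the table (negative counts and disordered positions are errors
#' reported with their line number) and returns a matrix-shaped
#' [AllelicCounts-class]; the pair round-trips exactly.
#'
#' @param path file path of the TSV.
#' @param knownChroms optional character vector; rows on other chromosomes
#'   are an error.
#' @return `readAllelicCounts()`: an [AllelicCounts-class];
#'   `writeAllelicCounts()`: invisibly, the path written.
#' @export
readAllelicCounts <- function(path, knownChroms = NULL) {
  df <- utils::read.delim(path, colClasses = c(
    individual = "character", chrom = "character", pos = "integer",
    count_9311 = "integer", count_nip = "integer"))
  need <- c("individual", "chrom", "pos", "count_9311", "count_nip")
  if (!all(need %in% names(df)))
    stop("counts TSV must have columns: ", paste(need, collapse = ", "))
  if (!is.null(knownChroms) && any(!df$chrom %in% knownChroms)) {
    bad <- which(!df$chrom %in% knownChroms)[1]
    stop("unknown chromosome '", df$chrom[bad], "' at line ", bad + 1L)
  }
  bad <- which(df$count_9311 < 0 | df$count_nip < 0 | is.na(df$count_9311) |
                 is.na(df$count_nip) | is.na(df$pos))
  if (length(bad))
    stop("malformed counts row at line ", bad[1] + 1L)
  if (nrow(df) == 0L)
    return(AllelicCounts(matrix(integer(), 0, 0), matrix(integer(), 0, 0),
                         GRanges(), character()))
  ids <- unique(df$individual)
  key <- paste(df$chrom, df$pos)
  first <- df[df$individual == ids[1], ]
  sites <- GRanges(first$chrom, IRanges(first$pos, width = 1))
  siteKey <- paste(first$chrom, first$pos)
  for (ch in unique(first$chrom)) {
    p <- first$pos[first$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on ", ch)
  }
  a <- b <- matrix(NA_integer_, length(sites), length(ids),
                   dimnames = list(NULL, ids))
  for (id in ids) {
    sub <- df[df$individual == id, ]
    idx <- match(paste(sub$chrom, sub$pos), siteKey)
    if (any(is.na(idx)) || nrow(sub) != length(sites))
      stop("individual '", id, "' does not cover the shared site set")
    a[idx, id] <- sub$count_9311
    b[idx, id] <- sub$count_nip
  }
  AllelicCounts(a, b, sites, ids)
}

#' @rdname readAllelicCounts
#' @param x an [AllelicCounts-class] to serialise.
#' @export
writeAllelicCounts <- function(x, path) {
  sites <- snpSites(x)
  a <- count9311(x)
  b <- countNip(x)
  ids <- colnames(a)
  df <- data.frame(
    individual = rep(ids, each = nrow(a)),
    chrom = rep(as.character(seqnames(sites)), times = length(ids)),
    pos = rep(start(sites), times = length(ids)),
    count_9311 = as.vector(a),
    count_nip = as.vector(b))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read a site mask as TSV
#'
#' @param mask a `DataFrame` from [controlBiasMask()].
#' @param sites the matching SNP `GRanges`.
#' @param path file path.
#' @return `writeSiteMask()` the path, invisibly; `readSiteMask()` a
#'   `DataFrame` with `keep` and `reason`.
#' @export
writeSiteMask <- function(mask, sites, path) {
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   pos = start(sites),
                   keep = mask$keep, reason = mask$reason)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSiteMask
#' @export
readSiteMask <- function(path) {
  df <- utils::read.delim(path)
  DataFrame(keep = as.logical(df$keep), reason = df$reason)
}
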