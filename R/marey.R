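#' Curate genetic-map markers to a monotone Marey map
#'
#' A Marey map (genetic position against physical position) must be
#' non-decreasing; markers violating monotonicity are typically mapping or
#' lift-over artefacts. Per chromosome, markers at duplicate physical
#' positions are collapsed to their median cM, then the longest
#' non-decreasing subsequence of genetic positions (in physical order) is
#' retained — the minimal removal making the map monotone. Chromosomes left
#' with fewer than `minMarkers` markers are dropped with a warning.
#'
#' @param map data.frame with columns marker, chrom, pos_bp, cM.
#' @param minMarkers minimum markers a chromosome must keep.
#' @return the curated map, same columns, ordered by chrom and position.
#' @export
curateMarkers <- function(map, minMarkers = 5L) {
  out <- list()
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    m <- m[order(m$pos_bp), ]
    if (anyDuplicated(m$pos_bp)) {
      agg <- stats::aggregate(cM ~ pos_bp, m, stats::median)
      m <- m[!duplicated(m$pos_bp), ]
      m$cM <- agg$cM[match(m$pos_bp, agg$pos_bp)]
    }
    keep <- .lnds(m$cM)
    m <- m[keep, ]
    if (nrow(m) < minMarkers) {
      warning("chromosome ", ch, " has fewer than ", minMarkers,
              " markers after curation; excluded")
      next
    }
    out[[ch]] <- m
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# indices of the longest non-decreasing subsequence (first optimal one)
.lnds <- function(x) {
  n <- length(x)
  if (n <= 1L) return(seq_len(n))
  len <- integer(n)
  prev <- integer(n)
  for (i in seq_len(n)) {
    len[i] <- 1L
    prev[i] <- 0L
    for (j in seq_len(i - 1L)) {
      if (x[j] <= x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  idx <- integer(len[i])
  k <- len[i]
  while (i > 0L) {
    idx[k] <- i
    i <- prev[i]
    k <- k - 1L
  }
  idx
}

# tricube-weighted local polynomial fit at x0; returns c(value, slope).
# neighbourhood = ceiling(span * n) nearest markers; widened on singularity
.localPolyFit <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- max(degree + 2L, ceiling(span * n))
  repeat {
    d <- abs(x - x0)
    o <- order(d)[seq_len(min(q, n))]
    h <- max(d[o])
    if (h == 0) h <- 1
    w <- (1 - pmin(1, d[o] / h)^3)^3
    sel <- w > 0
    if (sum(sel) >= degree + 1L &&
        length(unique(x[o][sel])) >= degree + 1L) {
      xs <- (x[o][sel] - x0)
      X <- stats::poly(xs, degree = degree, raw = TRUE, simple = TRUE)
      X <- cbind(1, X)
      fit <- tryCatch(stats::lm.wfit(X, y[o][sel], w[sel]),
                      error = function(e) NULL)
      if (!is.null(fit) && !anyNA(fit$coefficients[1:2]))
        return(c(fit$coefficients[1], fit$coefficients[2]))
    }
    if (q >= n) return(c(NA_real_, NA_real_))
    q <- min(n, q * 2L)
    warning("singular local fit at ", x0, "; widening span")
  }
}

#' Local recombination rate from a Marey map
#'
#' Fits a locally weighted polynomial (tricube weights, default degree 2,
#' span 0.2) of genetic position on physical position per chromosome and
#' evaluates its analytic first derivative at window midpoints, giving the
#' local homologous recombination rate in cM/Mb. Negative fitted slopes are
#' clipped to 0 (a rate cannot be negative); windows whose midpoint falls
#' outside the marker span get NA.
#'
#' @param map curated map from [curateMarkers()].
#' @param chromLens named chromosome lengths (bp); when NULL, windows cover
#'   the marker span only.
#' @param windowBp window size in bp.
#' @param span fraction of markers in each local neighbourhood.
#' @param degree local polynomial degree.
#' @return a data.frame: chrom, start, end, rate (cM/Mb; NA outside the
#'   marker span) and fittedCM (the smoothed genetic position at the window
#'   midpoint).
#' @examples
#' map <- data.frame(marker = 1:31, chrom = "Chr1",
#'                   pos_bp = seq(0, 30e6, by = 1e6),
#'                   cM = seq(0, 30, by = 1))  # 1 cM/Mb everywhere
#' r <- localRate(map)
#' range(r$rate)  # 1 1
#' @export
localRate <- function(map, chromLens = NULL, windowBp = 1e6,
                      span = 0.2, degree = 2L) {
  out <- list()
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    m <- m[order(m$pos_bp), ]
    lo <- min(m$pos_bp)
    hi <- max(m$pos_bp)
    len <- if (is.null(chromLens)) hi else chromLens[[ch]]
    nw <- ceiling(len / windowBp)
    mid <- (seq_len(nw) - 0.5) * windowBp
    rate <- fitted <- rep(NA_real_, nw)
    inside <- mid >= lo & mid <= hi
    for (k in which(inside)) {
      vs <- .localPolyFit(m$pos_bp, m$cM, mid[k], span, degree)
      fitted[k] <- vs[1]
      rk <- max(0, vs[2]) * 1e6  # cM/bp -> cM/Mb
      rate[k] <- if (rk < 1e-9) 0 else rk  # zap numeric dust on flat maps
    }
    out[[ch]] <- data.frame(
      chrom = ch, start = (seq_len(nw) - 1) * windowBp + 1,
      end = pmin(seq_len(nw) * windowBp, len),
      rate = rate, fittedCM = fitted)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Curate a map and estimate window recombination rates in one call
#'
#' @inheritParams localRate
#' @inheritParams curateMarkers
#' @return as [localRate()].
#' @export
mareyRates <- function(map, chromLens = NULL, windowBp = 1e6, span = 0.2,
                       degree = 2L, minMarkers = 5L) {
  localRate(curateMarkers(map, minMarkers), chromLens, windowBp, span, degree)
}
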