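#' Accessors for homoeolog-specific counts
#'
#' `count9311()` and `countNip()` return the per-site read-count matrices for
#' the two parental homoeologs; `siteDepth()` returns their sum (total allelic
#' depth per site and individual); `snpSites()` returns the SNP panel as a
#' `GRanges`; `siteMask()` returns the bias mask stored in `rowData` (or NULL
#' when none has been attached).
#'
#' @param x an [AllelicCounts-class] object.
#' @return a matrix (counts, depth), `GRanges` (sites) or `DataFrame` (mask).
#' @name counts-accessors
NULL

#' @rdname counts-accessors
#' @export
setGeneric("count9311", function(x) standardGeneric("count9311"))

#' @rdname counts-accessors
#' @export
setGeneric("countNip", function(x) standardGeneric("countNip"))

#' @rdname counts-accessors
#' @export
setGeneric("siteDepth", function(x) standardGeneric("siteDepth"))

#' @rdname counts-accessors
#' @export
setGeneric("snpSites", function(x) standardGeneric("snpSites"))

#' @rdname counts-accessors
#' @export
setGeneric("siteMask", function(x) standardGeneric("siteMask"))

#' @rdname counts-accessors
#' @param value a `DataFrame` with columns `keep` and `reason`.
#' @export
setGeneric("siteMask<-", function(x, value) standardGeneric("siteMask<-"))

#' @rdname counts-accessors
setMethod("count9311", "AllelicCounts", function(x) assay(x, "count9311"))

#' @rdname counts-accessors
setMethod("countNip", "AllelicCounts", function(x) assay(x, "countNip"))

#' @rdname counts-accessors
setMethod("siteDepth", "AllelicCounts",
          function(x) assay(x, "count9311") + assay(x, "countNip"))

#' @rdname counts-accessors
setMethod("snpSites", "AllelicCounts", function(x) rowRanges(x))

#' @rdname counts-accessors
setMethod("siteMask", "AllelicCounts", function(x) {
  rd <- rowData(x)
  if (!"keep" %in% colnames(rd)) return(NULL)
  rd[, c("keep", "reason"), drop = FALSE]
})

#' @rdname counts-accessors
setMethod("siteMask<-", "AllelicCounts", function(x, value) {
  stopifnot(all(c("keep", "reason") %in% colnames(value)),
            nrow(value) == nrow(x))
  rowData(x)$keep <- value$keep
  rowData(x)$reason <- value$reason
  x
})

#' Accessors for the parental panel bundle
#'
#' @param x a [ParentPanel-class] object.
#' @return `snpPanel()` the diagnostic SNP `GRanges`; `featureTrack()` the
#'   annotation `GRanges`; `teInsertions()` the TE frequency table;
#'   `geneticMap()` the marker map; `chromLengths()` the named length vector.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("snpPanel", function(x) standardGeneric("snpPanel"))
#' @rdname panel-accessors
#' @export
setGeneric("featureTrack", function(x) standardGeneric("featureTrack"))
#' @rdname panel-accessors
#' @export
setGeneric("teInsertions", function(x) standardGeneric("teInsertions"))
#' @rdname panel-accessors
#' @export
setGeneric("geneticMap", function(x) standardGeneric("geneticMap"))
#' @rdname panel-accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname panel-accessors
setMethod("snpPanel", "ParentPanel", function(x) x@snps)
#' @rdname panel-accessors
setMethod("featureTrack", "ParentPanel", function(x) x@features)
#' @rdname panel-accessors
setMethod("teInsertions", "ParentPanel", function(x) x@teTable)
#' @rdname panel-accessors
setMethod("geneticMap", "ParentPanel", function(x) x@geneticMap)
#' @rdname panel-accessors
setMethod("chromLengths", "ParentPanel", function(x) x@chromLengths)

#' Accessors for simulated ground truth
#'
#' @param x a [TruthIndividual-class] object.
#' @return `truthSegments()` the dosage-segment `GRanges`; `chromOffsets()`
#'   the whole-chromosome copy-number offsets; `segmentalEvents()` the
#'   segmental gain/loss `GRanges`; `isEuploid()` TRUE when there is no
#'   whole-chromosome or segmental change.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
setGeneric("truthSegments", function(x) standardGeneric("truthSegments"))
#' @rdname truth-accessors
#' @export
setGeneric("chromOffsets", function(x) standardGeneric("chromOffsets"))
#' @rdname truth-accessors
#' @export
setGeneric("segmentalEvents", function(x) standardGeneric("segmentalEvents"))
#' @rdname truth-accessors
#' @export
setGeneric("isEuploid", function(x) standardGeneric("isEuploid"))

#' @rdname truth-accessors
setMethod("truthSegments", "TruthIndividual", function(x) x@segments)
#' @rdname truth-accessors
setMethod("chromOffsets", "TruthIndividual", function(x) x@chromOffsets)
#' @rdname truth-accessors
setMethod("segmentalEvents", "TruthIndividual", function(x) x@segEvents)
#' @rdname truth-accessors
setMethod("isEuploid", "TruthIndividual", function(x) {
  all(x@chromOffsets$offset == 0L) && length(x@segEvents) == 0L
})
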