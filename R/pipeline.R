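.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Write a GRanges (or interval data.frame) as BED
#'
#' BED is 0-based, half-open: `start - 1` / `end` of the 1-based inclusive
#' internal representation.
#'
#' @param x a `GRanges` (the `class` mcols column, when present, becomes the
#'   BED name field) or a data.frame with chrom, start, end and optionally
#'   name.
#' @param path output path.
#' @return invisibly, the number of records written.
#' @export
writeBed <- function(x, path) {
  if (is(x, "GRanges")) {
    df <- data.frame(chrom = as.character(seqnames(x)),
                     start = start(x) - 1L, end = end(x),
                     name = if ("class" %in% names(mcols(x)))
                       mcols(x)$class else ".")
  } else {
    df <- data.frame(chrom = x$chrom, start = x$start - 1, end = x$end,
                     name = if ("name" %in% names(x)) x$name else ".")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}

.truthToList <- function(truth) {
  segs <- truthSegments(truth)
  evs <- segmentalEvents(truth)
  list(
    id = truth@id,
    generation = truth@generation,
    euploid = isEuploid(truth),
    segments = data.frame(chrom = as.character(seqnames(segs)),
                          start = start(segs), end = end(segs),
                          dosage = mcols(segs)$dosage),
    chromOffsets = chromOffsets(truth),
    segEvents = if (length(evs))
      data.frame(chrom = as.character(seqnames(evs)), start = start(evs),
                 end = end(evs), offset = mcols(evs)$offset,
                 homoeolog = mcols(evs)$homoeolog)
    else data.frame())
}

#' Serialise simulated ground truth as JSON
#'
#' @param truths list of [TruthIndividual-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTruth <- function(truths, path) {
  jsonlite::write_json(lapply(truths, .truthToList), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default pipeline configuration
#'
#' One flat list carrying every tunable of the pipeline with its default:
#' the generator block (mirroring [SimConfig()]), the masking thresholds,
#' karyotyping rungs and tolerance, HE-calling bin size / epsilon / minimum
#' fragment, window size, loess span and degree, and TE presence thresholds.
#' Round-trips unchanged through YAML via [writeRunConfig()] /
#' [readRunConfig()].
#'
#' @return a named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    sim = list(nChromosomes = 12L, chromLengthBp = 30e6, snpDensity = 2,
               perSiteDepth = 20, errorRate = 0.005, meanHePerChrom = 3,
               pChromGain = 9 / 240, pChromLoss = 10 / 240,
               pSegmental = 0.01, segLengthBp = c(3e6, 8e6),
               nIndividuals = 20L, generation = "S2"),
    mask = list(zeroFloor = 4L, minDepth = 2L),
    karyotype = list(windowBp = 1e6, minSites = 5L,
                     cutoffs = c(0.5, 0.75, 1.25, 1.5), delta = 0.05,
                     modalFrac = 0.8, minRun = 3L),
    he = list(binSnps = 10L, epsilon = 0.005, minFrag = 5L),
    te = list(hi = 0.95, lo = 0.05),
    marey = list(span = 0.2, degree = 2L, minMarkers = 5L),
    assoc = list(span = 0.2, degree = 2L))
}

#' @rdname defaultRunConfig
#' @param config a configuration list.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' @rdname defaultRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- defaultRunConfig()
  for (blk in names(defaults)) {
    if (is.list(defaults[[blk]])) {
      for (k in names(defaults[[blk]]))
        if (is.null(cfg[[blk]][[k]])) cfg[[blk]][[k]] <- defaults[[blk]][[k]]
    } else if (is.null(cfg[[blk]])) cfg[[blk]] <- defaults[[blk]]
  }
  cfg
}

.simConfigFrom <- function(config) {
  s <- config$sim
  SimConfig(nChromosomes = s$nChromosomes, chromLengthBp = s$chromLengthBp,
            snpDensity = s$snpDensity, perSiteDepth = s$perSiteDepth,
            errorRate = s$errorRate,
            heIntensity = if (is.null(s$heIntensity)) list() else s$heIntensity,
            meanHePerChrom = s$meanHePerChrom, pChromGain = s$pChromGain,
            pChromLoss = s$pChromLoss, pSegmental = s$pSegmental,
            segLengthBp = unlist(s$segLengthBp),
            nIndividuals = s$nIndividuals, generation = s$generation,
            seed = config$seed)
}

#' Run the end-to-end pipeline
#'
#' Orchestrates simulate -> mask -> karyotype -> call-HE -> features ->
#' marey -> associate into a run directory of TSV/BED/JSON outputs plus a
#' manifest listing every file with its row count and a YAML snapshot of the
#' configuration. Rerunning with the same configuration and seed reproduces
#' the outputs byte for byte.
#'
#' In `analyze` mode the simulation stage is skipped and `counts.tsv`,
#' `controls.tsv` and `chrom_lengths.tsv` (plus optional `te_table.tsv` and
#' `genetic_map.tsv`) must already exist in `outDir`; a missing input is an
#' error naming the stage.
#'
#' @param config configuration list, see [defaultRunConfig()].
#' @param outDir run directory (created if needed).
#' @param mode `"full"` (simulate then analyse), `"simulate"`, or
#'   `"analyze"`.
#' @return invisibly, the manifest data.frame.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir,
                        mode = c("full", "simulate", "analyze")) {
  mode <- match.arg(mode)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(file, n) manifest[[file]] <<- data.frame(file = file, rows = n)
  pathOf <- function(f) file.path(outDir, f)

  panel <- NULL
  sim <- NULL
  if (mode %in% c("full", "simulate")) {
    sim <- simulatePopulation(.simConfigFrom(config))
    panel <- sim$panel
    sites <- snpPanel(panel)
    note("snp_panel.tsv", .writeTsv(
      data.frame(chrom = as.character(seqnames(sites)), pos = start(sites)),
      pathOf("snp_panel.tsv")))
    writeAllelicCounts(sim$counts, pathOf("counts.tsv"))
    note("counts.tsv", nrow(sim$counts) * ncol(sim$counts))
    writeAllelicCounts(sim$controls, pathOf("controls.tsv"))
    note("controls.tsv", nrow(sim$controls) * ncol(sim$controls))
    writeTruth(sim$truth, pathOf("truth.json"))
    note("truth.json", length(sim$truth))
    note("features.bed", writeBed(featureTrack(panel), pathOf("features.bed")))
    note("te_table.tsv", .writeTsv(teInsertions(panel), pathOf("te_table.tsv")))
    note("genetic_map.tsv", .writeTsv(geneticMap(panel),
                                      pathOf("genetic_map.tsv")))
    note("chrom_lengths.tsv", .writeTsv(
      data.frame(chrom = names(chromLengths(panel)),
                 length = as.numeric(chromLengths(panel))),
      pathOf("chrom_lengths.tsv")))
  }
  writeRunConfig(config, pathOf("config.yaml"))

  if (mode == "simulate") {
    mf <- do.call(rbind, manifest)
    .writeTsv(mf, pathOf("manifest.tsv"))
    return(invisible(mf))
  }

  # ---- analysis stages ----
  need <- function(f, stage) {
    p <- pathOf(f)
    if (!file.exists(p)) stop("stage '", stage, "': missing input ", f)
    p
  }
  if (mode == "analyze") {
    counts <- readAllelicCounts(need("counts.tsv", "mask"))
    controls <- readAllelicCounts(need("controls.tsv", "mask"))
    cl <- utils::read.delim(need("chrom_lengths.tsv", "karyotype"))
    chromLens <- stats::setNames(cl$length, cl$chrom)
    teTable <- if (file.exists(pathOf("te_table.tsv")))
      utils::read.delim(pathOf("te_table.tsv")) else NULL
    gmap <- if (file.exists(pathOf("genetic_map.tsv")))
      utils::read.delim(pathOf("genetic_map.tsv")) else NULL
  } else {
    counts <- sim$counts
    controls <- sim$controls
    chromLens <- chromLengths(panel)
    teTable <- teInsertions(panel)
    gmap <- geneticMap(panel)
  }

  mask <- controlBiasMask(controls, config$mask$zeroFloor,
                          config$mask$minDepth)
  note("site_mask.tsv", nrow(mask))
  writeSiteMask(mask, snpSites(counts), pathOf("site_mask.tsv"))

  ka <- config$karyotype
  karyo <- callKaryotypes(counts, mask, ka$windowBp, ka$minSites,
                          unlist(ka$cutoffs), ka$delta, ka$modalFrac,
                          ka$minRun)
  note("karyotype.tsv", .writeTsv(karyo$calls, pathOf("karyotype.tsv")))
  note("segmental_events.bed", writeBed(
    data.frame(chrom = karyo$events$chrom, start = karyo$events$start,
               end = karyo$events$end,
               name = sprintf("%s:%+d", karyo$events$individual,
                              karyo$events$offset)),
    pathOf("segmental_events.bed")))

  he <- callHEPopulation(counts, mask, karyo, config$he$binSnps,
                         config$he$epsilon, config$he$minFrag)
  note("fragments.tsv", .writeTsv(he$fragments, pathOf("fragments.tsv")))
  note("he_regions.bed", writeBed(
    data.frame(chrom = he$regions$chrom, start = he$regions$start + 1,
               end = he$regions$end,
               name = sprintf("%s:%s>%s", he$regions$individual,
                              he$regions$leftGenotype,
                              he$regions$rightGenotype)),
    pathOf("he_regions.bed")))
  note("he_counts.tsv", .writeTsv(he$counts, pathOf("he_counts.tsv")))
  heFreq <- windowHEFrequency(he$regions, length(he$individuals), chromLens,
                              ka$windowBp)
  note("he_window_frequency.tsv", .writeTsv(heFreq,
                                            pathOf("he_window_frequency.tsv")))

  variants <- windowVariantDensity(
    snps = data.frame(chrom = as.character(seqnames(snpSites(counts))),
                      pos = start(snpSites(counts))),
    indels = NULL, teTable = teTable, chromLens = chromLens,
    windowBp = ka$windowBp, hi = config$te$hi, lo = config$te$lo)

  fractions <- NULL
  chromTable <- NULL
  if (!is.null(panel)) {
    fractions <- windowFeatureFractions(panel, windowBp = ka$windowBp)
    note("window_features.tsv", .writeTsv(fractions,
                                          pathOf("window_features.tsv")))
    euHE <- he$counts[he$counts$individual %in% he$individuals, ]
    chromTable <- buildChromTable(chromFeatureTable(panel), euHE)
    note("chrom_features.tsv", .writeTsv(chromTable,
                                         pathOf("chrom_features.tsv")))
  }

  hr <- NULL
  if (!is.null(gmap) && nrow(gmap))
    hr <- mareyRates(gmap, chromLens, ka$windowBp, config$marey$span,
                     config$marey$degree, config$marey$minMarkers)
  if (!is.null(hr))
    note("hr_rates.tsv", .writeTsv(hr, pathOf("hr_rates.tsv")))

  wt <- buildWindowTable(heFreq, hr, variants, fractions)
  note("window_table.tsv", .writeTsv(wt, pathOf("window_table.tsv")))
  rep <- buildReports(chromTable, wt, config$assoc$span, config$assoc$degree)
  if (!is.null(rep$fig2))
    note("fig2_table.tsv", .writeTsv(rep$fig2, pathOf("fig2_table.tsv")))
  note("table1_correlations.tsv", .writeTsv(
    rep$table1, pathOf("table1_correlations.tsv")))
  if (!is.null(rep$profiles))
    note("fig3_profiles.tsv", .writeTsv(rep$profiles,
                                        pathOf("fig3_profiles.tsv")))

  mf <- do.call(rbind, manifest)
  rownames(mf) <- NULL
  .writeTsv(mf, pathOf("manifest.tsv"))
  invisible(mf)
}
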