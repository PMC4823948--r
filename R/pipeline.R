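#' Run configuration for a full plate analysis
#'
#' Assembles (and validates) the configuration of
#' \code{\link{runPlateAnalysis}}. A configuration can equally be read
#' from a JSON or YAML file with \code{\link{readRunConfig}}; every
#' element has the defaults below.
#'
#' @param assay biosensor assay (see \code{\link{fieldSpec}})
#' @param layout plate layout data.frame (see
#'   \code{\link{defaultPlateLayout}}) or path to a layout CSV
#' @param doseResponse logistic dose--response parameters of the
#'   simulated plate (list: \code{floor}, \code{ceiling}, \code{ec50},
#'   \code{hill})
#' @param fieldsPerWell view fields per well
#' @param nCells,imageShape field geometry overrides passed to
#'   \code{\link{fieldSpec}}
#' @param segmentation list: \code{minArea}, \code{maxArea},
#'   \code{minMeanIntensity}, \code{ringWidth}, \code{minDistance}
#' @param features list: \code{blockPx}, \code{minCoverage},
#'   \code{piThreshold}, \code{backgroundSubtract}
#' @param calibration list: \code{method}, \code{k}, \code{minLive}
#' @param outDir output directory (created); \code{NULL} to skip writing
#' @param seed master seed of the run
#' @return a \code{RunConfig} list
#' @export
runConfig <- function(assay = "CALR_GFP", layout = defaultPlateLayout(),
                      doseResponse = list(), fieldsPerWell = 6L,
                      nCells = 50L, imageShape = c(208L, 208L),
                      segmentation = list(), features = list(),
                      calibration = list(), outDir = NULL, seed = 1L) {
  .checkAssay(assay)
  if (is.character(layout)) layout <- readPlateLayout(layout)
  cfg <- list(
    assay = assay, layout = layout,
    doseResponse = modifyList(list(floor = 0.02, ceiling = 0.95,
                                   ec50 = 100, hill = 2), doseResponse),
    fieldsPerWell = as.integer(fieldsPerWell),
    nCells = as.integer(nCells), imageShape = as.integer(imageShape),
    segmentation = modifyList(list(minArea = 10, maxArea = 5000,
                                   minMeanIntensity = 0, ringWidth = 4,
                                   minDistance = 1), segmentation),
    features = modifyList(list(blockPx = 4, minCoverage = 0.5,
                               piThreshold = 500,
                               backgroundSubtract = TRUE), features),
    calibration = modifyList(list(method = "intersection", k = 3,
                                  minLive = 50), calibration),
    outDir = outDir, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from JSON or YAML
#'
#' @param file path to a \code{.json}, \code{.yaml} or \code{.yml} file
#'   whose top-level keys are \code{\link{runConfig}} arguments
#' @param ... overrides applied on top of the file contents
#' @return a \code{RunConfig}
#' @export
readRunConfig <- function(file, ...) {
  raw <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE))
    yaml::read_yaml(file)
  else jsonlite::read_json(file, simplifyVector = TRUE)
  raw <- modifyList(raw, list(...))
  if (!is.null(raw$layout) && is.character(raw$layout))
    raw$layout <- readPlateLayout(raw$layout)
  if (!is.null(raw$layout) && !is.data.frame(raw$layout))
    raw$layout <- as.data.frame(raw$layout)
  do.call(runConfig, raw)
}

# direction in which each assay's feature marks a positive (responding)
# cell: CALR aggregation and MX1 induction raise the readout, quinacrine
# vesicle depletion and nuclear HMGB1 exodus lower it
.assayDirection <- function(assay) {
  switch(assay,
         CALR_GFP = "above", QUINACRINE = "below",
         HMGB1_GFP = "below", MX1_GFP = "above")
}

#' Run the full simulate--segment--measure--calibrate--summarize pipeline
#'
#' Orchestrates one reproducible plate analysis: simulates the plate
#' (\code{\link{generatePlate}}), segments every field's nuclei and
#' cytoplasmic ROIs, measures per-cell records
#' (\code{\link{measureField}}), calibrates the assay threshold from the
#' control wells' Gaussians (falling back to \code{k_sigma} with a
#' warning when the layout has no positive controls), summarizes wells
#' and computes the dose--response statistics against the untreated
#' reference wells. When \code{outDir} is set, writes
#' \code{per_cell.csv}, \code{thresholds.json}, \code{wells.csv},
#' \code{stats.csv} and \code{manifest.json}; outputs are deterministic
#' given the configuration (the manifest records no timestamps).
#'
#' @param config a \code{\link{runConfig}} (or a path accepted by
#'   \code{\link{readRunConfig}})
#' @return (invisibly) list with \code{records}, \code{model},
#'   \code{wells}, \code{stats}, \code{layout}, \code{manifest}
#' @export
runPlateAnalysis <- function(config = runConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  sg <- config$segmentation; ft <- config$features; cal <- config$calibration
  spec <- fieldSpec(nCells = config$nCells, imageShape = config$imageShape,
                    ringWidth = sg$ringWidth, assay = config$assay)
  sim <- generatePlate(config$layout, assay = config$assay,
                       doseResponse = config$doseResponse,
                       fieldsPerWell = config$fieldsPerWell, spec = spec,
                       seed = config$seed)

  nSegmented <- 0L
  recs <- lapply(sim$fields, function(fi) {
    m <- segmentNuclei(getChannel(fi, "Hoechst"),
                       minDistance = sg$minDistance)
    m <- filterDebris(m, sg$minArea, sg$maxArea, sg$minMeanIntensity)
    nSegmented <<- nSegmented + nObjects(m)
    rois <- buildCytoplasmROIs(m, sg$ringWidth)
    measureField(fi, rois, config$assay, piThreshold = ft$piThreshold,
                 blockPx = ft$blockPx, minCoverage = ft$minCoverage,
                 backgroundSubtract = ft$backgroundSubtract)
  })
  records <- do.call(rbind, recs)

  direction <- .assayDirection(config$assay)
  negWells <- sim$layout$well[sim$layout$role == "neg"]
  posWells <- sim$layout$well[sim$layout$role == "pos"]
  usable <- records$live & records$qc_ok & is.finite(records$feature)
  negVals <- records$feature[usable & records$well %in% negWells]
  posVals <- if (length(posWells))
    records$feature[usable & records$well %in% posWells] else NULL
  model <- fitThreshold(negVals, posVals, direction = direction,
                        method = cal$method, k = cal$k,
                        assay = config$assay)

  wells <- do.call(rbind, lapply(split(records, records$well), function(r)
    summarizeWell(r, model, minLive = cal$minLive)))
  wells <- merge(sim$layout, wells, by = "well", sort = TRUE)

  ref <- wells[wells$role == "neg", , drop = FALSE]
  stats <- doseResponseTable(wells[wells$role != "neg", , drop = FALSE], ref)

  manifest <- list(
    package = "icdQuant",
    version = as.character(utils::packageVersion("icdQuant")),
    assay = config$assay, seed = config$seed,
    parameters = config[c("doseResponse", "fieldsPerWell", "nCells",
                          "imageShape", "segmentation", "features",
                          "calibration")],
    counts = list(fields = length(sim$fields),
                  cells_segmented = nSegmented,
                  cells_measured = nrow(records),
                  cells_qc_excluded = sum(!records$qc_ok),
                  wells = nrow(wells),
                  wells_flagged = sum(wells$excluded)))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(config$outDir, "per_cell.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(assay = model@assay, direction = model@direction,
           method = model@method, threshold = model@threshold,
           neg_mean = model@negMean, neg_sd = model@negSd,
           pos_mean = model@posMean, pos_sd = model@posSd, k = model@k),
      file.path(config$outDir, "thresholds.json"), auto_unbox = TRUE,
      digits = NA, na = "null")
    utils::write.csv(wells, file.path(config$outDir, "wells.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(config$outDir, "stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(records = records, model = model, wells = wells,
                 stats = stats, layout = sim$layout, truth = sim$truth,
                 manifest = manifest))
}
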