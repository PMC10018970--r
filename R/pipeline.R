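#' Run the full quantification pipeline
#'
#' For each input volume (TIFF path or [RasterVolume]) or pre-traced graph
#' ([VesselGraph]): segmentation (skipped for graph inputs), tracing,
#' distance analysis and per-sample statistics; artifacts (mask TIFF, SWC +
#' GraphML graph, segment CSV, distance histogram CSV, 8-bit heatmap TIFF)
#' and a run manifest are written to `outputDir`. Deterministic given the
#' config and inputs.
#'
#' Graph inputs are rasterized at the configured spacing to obtain the mask
#' used for rPVV and the distance field, so mask-derived and graph-derived
#' statistics stay on one footing.
#'
#' @param inputs list of TIFF paths, [RasterVolume]s or [VesselGraph]s.
#' @param config a [pipelineConfig()].
#' @param outputDir directory (created if absent), or `NULL` to skip
#'   artifact writing.
#' @param labels optional group labels, recycled over inputs.
#' @param domainSize physical extents (um) used when rasterizing graph
#'   inputs.
#' @return list with `features` (data.frame), `samples` (per-sample
#'   intermediate objects) and `manifest`.
#' @export
runPipeline <- function(inputs, config = pipelineConfig(), outputDir = NULL,
                        labels = "sample", domainSize = NULL) {
  if (length(inputs) < 1) stop("run_pipeline: at least one input required")
  labels <- rep_len(labels, length(inputs))
  if (!is.null(outputDir) && !dir.exists(outputDir)) {
    dir.create(outputDir, recursive = TRUE)
  }
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  warningsSeen <- character(0)
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warningsSeen <<- c(warningsSeen, paste0("[", name, "] ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - ts, 3)
    out
  }

  checksums <- vapply(inputs, function(x) {
    if (is.character(x)) unname(tools::md5sum(x)) else NA_character_
  }, character(1))

  samples <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    id <- if (is.character(inp)) basename(inp) else paste0("input", i)
    if (is.character(inp)) {
      inp <- stage(paste0(id, "/read"), readVolume(inp, config$spacing))
    }
    if (is(inp, "VesselGraph")) {
      ras <- stage(paste0(id, "/rasterize"),
                   rasterizeNetwork(inp, config$spacing, domainSize = domainSize))
      mask <- stage(paste0(id, "/segment"),
                    filterSmallFragments(ras$mask,
                                         config$segmentation$minFragmentVoxels,
                                         config$segmentation$connectivity))
      graph <- inp
      tab <- stage(paste0(id, "/measure"), measureSegments(graph))
    } else if (is(inp, "RasterVolume")) {
      mask <- stage(paste0(id, "/segment"), segmentVolume(inp, config$segmentation))
      tr <- stage(paste0(id, "/trace"),
                  traceMask(mask, config$pruneFactor, removeBoundary = FALSE))
      graph <- tr$graph
      tab <- tr$table
    } else {
      stop("[stage: ", id, "/input] unsupported input type: ", class(inp)[1])
    }
    d <- dim(mask@voxels)
    tab <- stage(paste0(id, "/rim-filter"),
                 removeBoundarySegments(tab, mask@origin,
                                        mask@origin + (d - 1) * mask@spacing,
                                        mask@spacing, config$rimMarginVoxels))
    dfield <- stage(paste0(id, "/distance"),
                    distanceTransform(mask, quantized = config$quantizedDistances))
    samples[[i]] <- list(id = id, label = labels[i], mask = mask,
                         graph = graph, table = tab, distance = dfield)
    if (!is.null(outputDir)) {
      stage(paste0(id, "/write"), {
        base <- file.path(outputDir, tools::file_path_sans_ext(id))
        writeVolume(mask, paste0(base, "_mask.tif"))
        writeSWC(graph, paste0(base, ".swc"))
        writeGraphML(graph, paste0(base, ".graphml"))
        writeSegmentTable(tab, paste0(base, "_segments.csv"))
        utils::write.csv(distanceHistogram(dfield, config$distanceBinWidth),
                         paste0(base, "_distances.csv"), row.names = FALSE)
        hm <- encode8bitHeatmap(dfield)
        writeVolume(hm$volume, paste0(base, "_heatmap.tif"), maxValue = 255)
      })
    }
  }

  features <- stage("features", assembleFeatureTable(samples))
  manifest <- list(
    package = "vascumorph",
    version = as.character(utils::packageVersion("vascumorph")),
    config = unclass(config),
    inputs = vapply(seq_along(inputs), function(i) {
      if (is.character(inputs[[i]])) inputs[[i]] else class(inputs[[i]])[1]
    }, character(1)),
    checksums = checksums,
    labels = labels,
    timings = timings,
    totalSeconds = round(proc.time()[["elapsed"]] - t0, 3),
    warnings = warningsSeen)
  if (!is.null(outputDir)) {
    utils::write.csv(features, file.path(outputDir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(features = features, samples = samples, manifest = manifest)
}
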