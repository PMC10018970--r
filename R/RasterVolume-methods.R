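#' Construct a RasterVolume
#'
#' @param voxels numeric 3D array.
#' @param spacing numeric(3), voxel pitch in um (x, y, z). Default 1 um
#'   isotropic.
#' @param origin numeric(3), physical position (um) of the centre of voxel
#'   `[1, 1, 1]`. Default the physical origin.
#' @return a [RasterVolume].
#' @export
rasterVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "double"
  new("RasterVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname accessors
#' @export
setMethod("voxelData", "RasterVolume", function(object) object@voxels)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "RasterVolume", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("voxelOrigin", "RasterVolume", function(object) object@origin)

#' @rdname accessors
#' @export
setMethod("nComponents", "VesselMask", function(object) object@nComponents)

#' @export
#' @describeIn computeRPVV foreground fraction of a binary volume.
setMethod("computeRPVV", "RasterVolume", function(object) {
  v <- object@voxels
  if (!all(v %in% c(0, 1))) stop("computeRPVV expects a binary volume")
  mean(v)
})

setMethod("show", "RasterVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
  if (is(object, "VesselMask")) {
    cat(sprintf("  rPVV %.4f, %d component(s), fragment filter >= %d vx\n",
                object@rPVV, object@nComponents, object@minFragmentVoxels))
  }
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("nodes", "VesselGraph", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("segments", "VesselGraph", function(object) object@segments)

#' @rdname accessors
#' @export
setMethod("polylines", "VesselGraph", function(object) object@polylines)

#' @rdname accessors
#' @export
setMethod("vesselGraph", "GroundTruth", function(object) object@graph)

#' @rdname accessors
#' @export
setMethod("distances", "DistanceField", function(object) object@distances)

setMethod("show", "VesselGraph", function(object) {
  cat(sprintf("VesselGraph: %d node(s), %d segment(s), %d filament(s)\n",
              nrow(object@nodes), nrow(object@segments),
              length(unique(object@segments$filament_id))))
  if (nrow(object@segments)) {
    len <- vapply(object@polylines, polylineLength, numeric(1))
    cat(sprintf("  total length %.1f um, mean segment length %.2f um\n",
                sum(len), mean(len)))
  }
  invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth for a %s-domain network (%.0f x %.0f x %.0f um)\n",
              paste(object@details$archetype, collapse = ""),
              object@domainSize[1], object@domainSize[2], object@domainSize[3]))
  cat(sprintf("  volume fraction %.4f | mean segment length %.2f um | mean diameter %.2f um\n",
              object@analyticVolumeFraction, object@analyticMeanSegmentLength,
              object@analyticMeanDiameter))
  if (!is.na(object@analyticMaxSurfaceDistance)) {
    cat(sprintf("  max surface distance %.2f um\n", object@analyticMaxSurfaceDistance))
  }
  invisible(NULL)
})

setMethod("show", "DistanceField", function(object) {
  cat(sprintf("DistanceField: %s voxels, %d extravascular\n",
              paste(dim(object@field), collapse = " x "),
              length(object@distances)))
  if (length(object@distances)) {
    q <- stats::quantile(object@distances, c(0.5, 0.9, 1))
    cat(sprintf("  median %.2f um, P90 %.2f um, max %.2f um\n", q[1], q[2], q[3]))
  }
  invisible(NULL)
})

# physical coordinates (um) of all voxel centres along each axis
axisCoords <- function(volume) {
  d <- dim(volume@voxels)
  lapply(1:3, function(a) volume@origin[a] + (seq_len(d[a]) - 1) * volume@spacing[a])
}
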