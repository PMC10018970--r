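#' @import methods
NULL

#' RasterVolume: a 3D scalar field on an anisotropic voxel grid
#'
#' Container for image volumes. Voxel `[i, j, k]` (1-based) has its centre at
#' `origin + (i-1, j-1, k-1) * spacing`; all physical quantities are in
#' micrometres. Binary masks are stored as 0/1 volumes.
#'
#' @slot voxels numeric 3D array of voxel values.
#' @slot spacing numeric(3), voxel pitch in um per axis (x, y, z).
#' @slot origin numeric(3), physical position in um of the centre of voxel
#'   `[1, 1, 1]`.
#'
#' @seealso [rasterVolume()], [rasterizeNetwork()]
#' @export
setClass("RasterVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("RasterVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3D array")
  if (any(d < 8L)) return("grid shape must be at least 8 x 8 x 8")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    return("spacing must be three positive finite numbers")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("origin must be three finite numbers")
  }
  TRUE
})

#' VesselMask: a binary vessel mask with component bookkeeping
#'
#' A [RasterVolume] whose voxels are 0/1, carrying the number of connected
#' components after fragment filtering and the relative perfused vessel
#' volume (rPVV, foreground voxels / total voxels).
#'
#' @slot nComponents integer, 26-connected foreground components.
#' @slot rPVV numeric in `[0, 1]`.
#' @slot minFragmentVoxels integer, fragment filter threshold applied (0 if
#'   none).
#' @export
setClass("VesselMask",
  contains = "RasterVolume",
  representation(nComponents = "integer", rPVV = "numeric",
                 minFragmentVoxels = "integer"),
  prototype(nComponents = 0L, rPVV = 0, minFragmentVoxels = 0L)
)

setValidity("VesselMask", function(object) {
  v <- object@voxels
  if (!all(v %in% c(0, 1))) return("mask voxels must be 0/1")
  if (object@rPVV < 0 || object@rPVV > 1) return("rPVV must lie in [0, 1]")
  if (abs(object@rPVV - mean(v)) > 1e-9) {
    return("rPVV must equal foreground voxels / total voxels")
  }
  TRUE
})

#' VesselGraph: a centerline network of vessel segments
#'
#' Nodes are bifurcations and endpoints; segments ("dendrites" in filament-
#' tracing terminology) are the centerline stretches between two nodes, each
#' carried as a polyline with a per-point radius. A "filament" is a connected
#' component of the network; `filament_id` is constant within one.
#'
#' @slot nodes data.frame with columns `id`, `x`, `y`, `z` (um), `degree`.
#' @slot segments data.frame with columns `segment_id`, `node_a`, `node_b`,
#'   `filament_id`.
#' @slot polylines list of numeric matrices (columns `x`, `y`, `z`, `radius`,
#'   um), parallel to the rows of `segments`; the first and last polyline
#'   points coincide with the positions of `node_a` and `node_b`.
#' @export
setClass("VesselGraph",
  representation(nodes = "data.frame", segments = "data.frame",
                 polylines = "list")
)

setValidity("VesselGraph", function(object) {
  ns <- nrow(object@segments)
  if (length(object@polylines) != ns) {
    return("one polyline per segment row required")
  }
  need <- c("segment_id", "node_a", "node_b", "filament_id")
  if (!all(need %in% names(object@segments))) {
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(object@segments$segment_id)) return("segment ids must be unique")
  if (anyDuplicated(object@nodes$id)) return("node ids must be unique")
  if (ns == 0L) return(TRUE)
  pos <- as.matrix(object@nodes[, c("x", "y", "z")])
  rownames(pos) <- as.character(object@nodes$id)
  for (i in seq_len(ns)) {
    pl <- object@polylines[[i]]
    if (!is.matrix(pl) || ncol(pl) < 4L || nrow(pl) < 2L) {
      return("each polyline must be a matrix with >= 2 rows and columns x, y, z, radius")
    }
    if (any(pl[, 4] <= 0)) return("all radii must be positive")
    a <- pos[as.character(object@segments$node_a[i]), ]
    b <- pos[as.character(object@segments$node_b[i]), ]
    if (max(abs(pl[1, 1:3] - a)) > 1e-6 || max(abs(pl[nrow(pl), 1:3] - b)) > 1e-6) {
      return("polyline endpoints must coincide with node positions")
    }
  }
  TRUE
})

#' GroundTruth: analytic reference values for a generated network
#'
#' Emitted by the synthetic vasculature generators together with the
#' [VesselGraph]; every analytic value is reproducible from the graph
#' geometry by an independent brute-force computation.
#'
#' @slot graph the generated [VesselGraph].
#' @slot domainSize numeric(3), domain extents in um.
#' @slot analyticVolumeFraction fraction of the domain occupied by the tube
#'   union (closed form where the construction permits, otherwise
#'   Monte-Carlo; the method used is recorded in `details`).
#' @slot analyticMeanSegmentLength um, exact mean of polyline arc lengths.
#' @slot analyticMeanDiameter um, exact mean of per-segment mean diameters.
#' @slot analyticMaxSurfaceDistance um, maximal distance from any point of
#'   the domain to the nearest tube surface, when computable for the
#'   construction (`NA` otherwise).
#' @slot details list of construction bookkeeping (calibration knobs, method
#'   tags, probe-grid estimates).
#' @export
setClass("GroundTruth",
  representation(graph = "VesselGraph", domainSize = "numeric",
                 analyticVolumeFraction = "numeric",
                 analyticMeanSegmentLength = "numeric",
                 analyticMeanDiameter = "numeric",
                 analyticMaxSurfaceDistance = "numeric",
                 details = "list")
)

#' DistanceField: extravascular Euclidean distances to the vessel surface
#'
#' Per-voxel Euclidean distance (um) from each extravascular voxel centre to
#' the nearest vessel voxel, honouring anisotropic spacing. Vessel-interior
#' voxels carry 0 in `field` and are excluded from `distances`, the empirical
#' distribution used for all statistics.
#'
#' @slot field numeric 3D array of distances (um), 0 at vessel voxels.
#' @slot distances numeric vector, distances of extravascular voxels only.
#' @slot spacing numeric(3) voxel pitch in um.
#' @slot includesVessel logical, whether vessel voxels were kept in
#'   `distances` (non-default; see [distanceTransform()]).
#' @export
setClass("DistanceField",
  representation(field = "array", distances = "numeric", spacing = "numeric",
                 includesVessel = "logical"),
  prototype(includesVessel = FALSE)
)

setValidity("DistanceField", function(object) {
  if (length(object@distances) && min(object@distances) < 0) {
    return("distances must be non-negative")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    return("spacing must be three positive numbers")
  }
  TRUE
})

#' NetworkSpec: parameters of a synthetic vascular network
#'
#' @slot archetype one of `"parallel_fiber"`, `"random_arc"`,
#'   `"planar_mesh"`, `"tumor"`.
#' @slot domainSize numeric(3), extents in um.
#' @slot targetVolumeFraction fraction in (0, 1) to calibrate to, or `NA` to
#'   leave the density at its structural default.
#' @slot meanSegmentLength um.
#' @slot meanRadius um.
#' @slot radiusCV coefficient of variation of per-segment radii.
#' @slot tortuosity path/chord ratio, >= 1.
#' @slot voids matrix with columns `x`, `y`, `z`, `r` (um): hard exclusion
#'   spheres (tumor archetype).
#' @slot seed integer seed; all randomness in a generator call flows from it.
#' @slot extra list of archetype-specific knobs (see [networkSpec()]).
#' @export
setClass("NetworkSpec",
  representation(archetype = "character", domainSize = "numeric",
                 targetVolumeFraction = "numeric", meanSegmentLength = "numeric",
                 meanRadius = "numeric", radiusCV = "numeric",
                 tortuosity = "numeric", voids = "matrix", seed = "integer",
                 extra = "list")
)

setValidity("NetworkSpec", function(object) {
  if (!object@archetype %in% c("parallel_fiber", "random_arc", "planar_mesh", "tumor")) {
    return("unknown archetype")
  }
  if (length(object@domainSize) != 3L || any(object@domainSize <= 0)) {
    return("all domain extents must be positive")
  }
  f <- object@targetVolumeFraction
  if (!is.na(f) && (f <= 0 || f >= 1)) {
    return("target_volume_fraction must lie in (0, 1)")
  }
  if (object@tortuosity < 1) return("tortuosity must be >= 1 (path/chord ratio)")
  if (object@meanRadius <= 0) return("mean radius must be positive")
  if (object@meanSegmentLength <= 0) return("mean segment length must be positive")
  if (object@radiusCV < 0) return("radius CV must be non-negative")
  if (ncol(object@voids) != 4L) return("voids must have columns x, y, z, r")
  TRUE
})
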