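#' @title Accessor generics
#' @description Accessors for the core classes; use these rather than slot
#'   access.
#' @param object an object of one of the package classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(object) standardGeneric("voxelOrigin"))

#' @rdname accessors
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))

#' @rdname accessors
#' @export
setGeneric("polylines", function(object) standardGeneric("polylines"))

#' @rdname accessors
#' @export
setGeneric("vesselGraph", function(object) standardGeneric("vesselGraph"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("distances", function(object) standardGeneric("distances"))

#' Relative perfused vessel volume
#'
#' rPVV is the fraction of the tissue volume occupied by perfused (labelled)
#' vessel voxels: foreground voxel count divided by total voxel count.
#'
#' @param object a [VesselMask] (or binary [RasterVolume]).
#' @return a fraction in `[0, 1]`.
#' @examples
#' m <- rasterVolume(array(c(rep(1, 47), rep(0, 953)), c(10, 10, 10)))
#' computeRPVV(m)  # 0.047
#' @export
setGeneric("computeRPVV", function(object) standardGeneric("computeRPVV"))
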