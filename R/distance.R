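#' Extravascular Euclidean distance transform
#'
#' Exact Euclidean distance (um) from each background voxel centre to the
#' nearest vessel (foreground) voxel centre, honouring anisotropic voxel
#' spacing. Vessel-interior voxels carry 0 and are by default excluded from
#' the empirical distance distribution, since the supply question concerns
#' tissue voxels; including them would deflate the upper percentiles.
#'
#' @param mask a [VesselMask] or binary [RasterVolume]; must contain at
#'   least one vessel voxel.
#' @param includeVessel keep vessel voxels (at distance 0) in the
#'   distribution.
#' @param quantized compute the distribution on the 8-bit (0-255) quantized
#'   distances instead of float values, replicating a workflow that exports
#'   the distance channel as an 8-bit image before reading its histogram.
#' @return a [DistanceField].
#' @export
distanceTransform <- function(mask, includeVessel = FALSE, quantized = FALSE) {
  stopifnot(is(mask, "RasterVolume"))
  v <- mask@voxels
  if (!all(v %in% c(0, 1))) stop("mask must be binary")
  if (sum(v) == 0) stop("empty mask: distances to the vessel surface are undefined")
  d <- dim(v)
  fld <- array(cpp_edt_3d(as.logical(v), d, mask@spacing), d)
  dist <- if (includeVessel) as.numeric(fld) else fld[v == 0]
  if (quantized) {
    mx <- max(fld)
    if (mx > 0) dist <- floor(dist / mx * 255 + 0.5) * (mx / 255)
  }
  new("DistanceField", field = fld, distances = dist, spacing = mask@spacing,
      includesVessel = includeVessel)
}

#' Distance frequency distribution
#'
#' Relative frequencies of extravascular distances over contiguous bins of
#' width `binWidth` starting at 0; frequencies sum to 1.
#'
#' @param field a [DistanceField].
#' @param binWidth um.
#' @return data.frame with `bin_center` (um) and `frequency`.
#' @export
distanceHistogram <- function(field, binWidth = 2) {
  stopifnot(is(field, "DistanceField"), binWidth > 0)
  d <- field@distances
  nb <- max(1L, ceiling((max(d) + 1e-12) / binWidth))
  idx <- pmin(pmax(ceiling(d / binWidth), 1L), nb) # distance 0 into bin 1
  counts <- tabulate(idx, nbins = nb)
  data.frame(bin_center = (seq_len(nb) - 0.5) * binWidth,
             frequency = counts / sum(counts))
}

#' RM10: range of the maximal 10 percent of vessel distances
#'
#' The distance between the 90th and 100th percentile of the extravascular
#' distance distribution — the range containing the maximal 10% of
#' observations. Low values indicate homogeneously spaced vessels; large
#' values flag poorly supplied regions. The 90th percentile uses linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param field a [DistanceField], or a numeric vector of distances.
#' @return list with `p90`, `p100`, `rm10` (all um).
#' @export
computeRM10 <- function(field) {
  d <- if (is(field, "DistanceField")) field@distances else as.numeric(field)
  if (length(d) < 10) {
    stop("RM10 needs at least 10 extravascular voxels (got ", length(d), ")")
  }
  p90 <- unname(stats::quantile(d, 0.9, type = 7))
  p100 <- max(d)
  list(p90 = p90, p100 = p100, rm10 = p100 - p90)
}

#' Encode a distance field as an 8-bit heatmap
#'
#' Linear map of `[0, max]` onto grey values 0-255 (rounding half up), as
#' used to visualise voxel-to-vessel distances in an 8-bit image channel.
#' The scale factor is returned so the encoding can be inverted with a
#' quantization error of at most `max / 510`.
#'
#' @param field a [DistanceField].
#' @return list with `volume` (8-bit [RasterVolume]) and `scale` (um per
#'   grey level; `maxDistance = scale * 255`).
#' @export
encode8bitHeatmap <- function(field) {
  stopifnot(is(field, "DistanceField"))
  mx <- max(field@field)
  grey <- if (mx > 0) floor(field@field / mx * 255 + 0.5) else
    array(0, dim(field@field))
  list(volume = rasterVolume(array(as.numeric(grey), dim(field@field)),
                             field@spacing),
       scale = if (mx > 0) mx / 255 else 0,
       maxDistance = mx)
}
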