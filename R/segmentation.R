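#' Volumetric median filter
#'
#' Replaces every voxel by the median of its cubic `(2r+1)^3` neighbourhood;
#' voxels near the border use the median of their in-bounds neighbours.
#' Radius 0 is the identity. The default radius 1 (3x3x3 window) is the
#' standard despeckling step before thresholding a fluorescence stack.
#'
#' @param volume a [RasterVolume].
#' @param radius neighbourhood radius in voxels, `>= 0`.
#' @return a filtered [RasterVolume].
#' @export
medianFilter3D <- function(volume, radius = 1L) {
  stopifnot(is(volume, "RasterVolume"), radius >= 0)
  d <- dim(volume@voxels)
  out <- cpp_median_filter_3d(as.numeric(volume@voxels), d, as.integer(radius))
  rasterVolume(array(out, d), volume@spacing, volume@origin)
}

#' Otsu threshold of an intensity sample
#'
#' Exhaustive search over a 256-bin histogram for the cut maximising the
#' between-class variance. Errors on (near-)constant input, where no two
#' classes are separable.
#'
#' @param values numeric vector of intensities.
#' @param nBins histogram resolution.
#' @return the threshold value: voxels `>= threshold` are foreground.
#' @export
otsuThreshold <- function(values, nBins = 256L) {
  rng <- range(values)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) {
    stop("cannot auto-threshold a constant volume: no separable classes")
  }
  br <- seq(rng[1], rng[2], length.out = nBins + 1L)
  h <- tabulate(pmin(findInterval(values, br, rightmost.closed = TRUE), nBins),
                nbins = nBins)
  p <- h / sum(h)
  centers <- (br[-1] + br[-(nBins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[nBins]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-nBins])
  br[k + 1L] # upper edge of the background class
}

#' Threshold a volume into a binary mask
#'
#' @param volume a [RasterVolume].
#' @param threshold numeric cut (foreground iff intensity `>= threshold`),
#'   or `"auto"` for Otsu's criterion on the full-volume histogram.
#' @return a binary [RasterVolume].
#' @export
thresholdVolume <- function(volume, threshold = "auto") {
  stopifnot(is(volume, "RasterVolume"))
  v <- volume@voxels
  if (any(!is.finite(v))) stop("volume must be finite-valued")
  if (identical(threshold, "auto")) threshold <- otsuThreshold(as.numeric(v))
  rasterVolume(array(as.numeric(v >= threshold), dim(v)),
               volume@spacing, volume@origin)
}

#' Remove small fragments from a binary mask
#'
#' Drops 26-connected components with fewer than `minVoxels` voxels
#' (components of exactly `minVoxels` are retained) and reports the
#' surviving component count and rPVV.
#'
#' @param mask binary [RasterVolume].
#' @param minVoxels fragment threshold in voxels; the study default is 2000.
#' @param connectivity 26 (default) or 6.
#' @return a [VesselMask].
#' @export
filterSmallFragments <- function(mask, minVoxels = 2000L, connectivity = 26L) {
  stopifnot(is(mask, "RasterVolume"))
  v <- mask@voxels
  if (!all(v %in% c(0, 1))) stop("mask must be binary")
  d <- dim(v)
  lab <- cpp_label_components_3d(as.logical(v), d, as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which(sizes >= minVoxels)
  out <- array(as.numeric(lab %in% keep), d)
  new("VesselMask", voxels = out, spacing = mask@spacing, origin = mask@origin,
      nComponents = length(keep), rPVV = mean(out),
      minFragmentVoxels = as.integer(minVoxels))
}

#' Segmentation parameter set
#'
#' @param medianRadius voxels (default 1).
#' @param threshold numeric or `"auto"`.
#' @param minFragmentVoxels fragment filter (default 2000 voxels).
#' @param connectivity component connectivity (default 26).
#' @return a named list of parameters.
#' @export
segmentationParams <- function(medianRadius = 1L, threshold = "auto",
                               minFragmentVoxels = 2000L, connectivity = 26L) {
  stopifnot(medianRadius >= 0, minFragmentVoxels >= 1)
  list(medianRadius = medianRadius, threshold = threshold,
       minFragmentVoxels = minFragmentVoxels, connectivity = connectivity)
}

#' Segment a fluorescence volume into a vessel mask
#'
#' The reconstruction pipeline: volumetric median filter, (auto-)threshold,
#' and small-fragment filtering.
#'
#' @param volume a [RasterVolume] intensity stack.
#' @param params a [segmentationParams()] list.
#' @return a [VesselMask].
#' @export
segmentVolume <- function(volume, params = segmentationParams()) {
  filtered <- medianFilter3D(volume, params$medianRadius)
  binary <- thresholdVolume(filtered, params$threshold)
  filterSmallFragments(binary, params$minFragmentVoxels, params$connectivity)
}
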