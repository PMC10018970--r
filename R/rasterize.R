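#' Rasterize a vessel network into an image volume
#'
#' Voxelizes the capsule tube union of a [VesselGraph]: a voxel is foreground
#' iff its centre lies within the union of the per-edge capsules (cylinders
#' with hemispherical caps). A binary ground-truth mask is always returned;
#' an intensity volume emulating fluorescence acquisition (Gaussian blur,
#' additive background, Poisson photon noise, and a surface "leakiness"
#' perturbation of tube radii) is added when a noise model is supplied.
#'
#' @param graph a [VesselGraph].
#' @param spacing numeric(3), voxel pitch in um (x, y, z); the study default
#'   is `c(0.5, 0.5, 1)`.
#' @param domainSize numeric(3), physical extents in um; the grid has
#'   `round(domainSize / spacing)` voxels per axis with voxel `[1,1,1]`
#'   centred at the origin. Alternatively give `dim` directly.
#' @param dim integer(3), explicit grid shape (overrides `domainSize`).
#' @param noise `NULL` for a clean binary rasterization (deterministic and
#'   seed-independent), or a list with any of: `blurSigma` (um),
#'   `background` (counts), `photonScale` (expected foreground counts;
#'   enables Poisson noise), `leakiness` (relative radius perturbation SD),
#'   `seed` (integer, default 1).
#' @return a list with `mask` (binary [RasterVolume], the ground truth) and
#'   `intensity` ([RasterVolume] or `NULL`).
#' @export
rasterizeNetwork <- function(graph, spacing = c(0.5, 0.5, 1),
                             domainSize = NULL, dim = NULL, noise = NULL) {
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  edges <- graphEdgeMatrix(graph)
  if (is.null(dim)) {
    if (is.null(domainSize)) {
      if (!nrow(edges)) stop("give domainSize or dim for an empty graph")
      domainSize <- apply(edges[, 4:6, drop = FALSE], 2, max) +
        max(edges[, 7]) + spacing
    }
    dim <- pmax(8L, as.integer(round(domainSize / spacing)))
  }
  dim <- as.integer(dim)
  if (prod(as.numeric(dim)) > 2^31 - 1) {
    stop("graph exceeds the addressable grid (", paste(dim, collapse = " x "),
         " voxels); coarsen the spacing")
  }
  origin <- c(0, 0, 0)
  if (nrow(edges)) {
    fg <- cpp_rasterize_capsules(edges, dim, spacing, origin)
  } else {
    fg <- logical(prod(dim))
  }
  mask <- rasterVolume(array(as.numeric(fg), dim), spacing, origin)

  intensity <- NULL
  if (!is.null(noise)) {
    seed <- if (is.null(noise$seed)) 1L else as.integer(noise$seed)
    rs <- .seededRNG(seed)
    edN <- edges
    if (!is.null(noise$leakiness) && noise$leakiness > 0 && nrow(edN)) {
      edN[, 7] <- pmax(edN[, 7] * (1 + noise$leakiness * rs$norm(nrow(edN))),
                       0.2 * edN[, 7])
    }
    fgN <- if (nrow(edN)) cpp_rasterize_capsules(edN, dim, spacing, origin)
           else logical(prod(dim))
    img <- as.numeric(fgN)
    if (!is.null(noise$blurSigma) && noise$blurSigma > 0) {
      img <- cpp_gaussian_blur_3d(img, dim, noise$blurSigma / spacing)
    }
    photons <- if (is.null(noise$photonScale)) 0 else noise$photonScale
    bg <- if (is.null(noise$background)) 0 else noise$background
    if (photons > 0) {
      img <- rs$pois(length(img), lambda = img * photons + bg)
    } else if (bg > 0) {
      img <- img + bg
    }
    intensity <- rasterVolume(array(as.numeric(img), dim), spacing, origin)
  }
  list(mask = mask, intensity = intensity)
}
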