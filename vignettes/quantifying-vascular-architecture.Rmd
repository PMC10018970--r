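---
title: "Quantifying 3D vascular architecture with vascumorph"
author: "vascumorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D vascular architecture with vascumorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascumorph)
```

## The measurement problem

A healthy organ builds its capillary bed as a regular, hierarchical network:
large vessels split into successively smaller ones, and the spacing between
capillaries is homogeneous enough that no tissue voxel lies farther from a
vessel than diffusion can supply. Tumors break both properties — vessel
density is spatially erratic, with hyperdense patches next to completely
avascular regions, and individual short segments are dilated while their
neighbours are constricted. `vascumorph` turns 3D fluorescence volumes of
labelled (perfused) vasculature into a small set of quantitative summaries
that capture exactly these two axes of organisation:

* **rPVV** — relative perfused vessel volume, the fraction of the imaged
  tissue occupied by vessel voxels;
* per-segment **morphometrics** — length, mean diameter, straightness
  (chord/arc) and XY-plane orientation of every inter-bifurcation segment of
  the traced centerline network;
* **RM10** — the range containing the maximal 10% of extravascular
  voxel-to-vessel distances (100th minus 90th percentile); small values mean
  homogeneously spaced vessels;
* **KDE areas** — the area of the highest-density region holding 50% (or
  90%) of the probability mass of the 2D kernel density estimate of segment
  diameter versus straightness, `KDE_50(D/S)`; hierarchical networks
  concentrate in a small region of that plane.

Per-sample summaries feed a z-scored PCA and two-group tests (Student's t
with an F-test screen that switches to the Welch variant under unequal
variances).

## Pipeline stages and their conventions

Throughout the package, voxel indices are 0-based in the kernels and 1-based
at the R surface, positions are **voxel centres**, and the physical position
of voxel `(i, j, k)` (1-based) is `origin + (i-1, j-1, k-1) * spacing`.
Everything outside the kernels is expressed in micrometres. The reference
acquisition geometry is an anisotropic 0.5 × 0.5 × 1 µm³ voxel grid.

**Segmentation.** A volumetric median filter (default radius 1, the 3×3×3
window — the standard reading of a "3D median over neighbouring pixels"; the
radius is an explicit parameter) despeckles the stack; thresholding is an
explicit intensity cut or Otsu's criterion computed on the full 3D histogram
(no per-slice thresholds); 26-connected components *smaller than* 2000
voxels are removed (a component of exactly 2000 voxels survives — the filter
is strict-below). Connectivity is configurable; 26 matches the visual
continuity of tubes.

**Tracing.** The mask is thinned to a one-voxel-wide curve skeleton by
sequential deletion of simple points (26/6 foreground/background
connectivity pairing) in six directional subiterations, with curve endpoints
protected. Deletion within a pass runs over eight parity subfields: purely
sequential deletion would otherwise "unzip" two-voxel-wide columns along the
scan order and erase whole branches. Skeleton voxels with other than two
neighbours become nodes; mutually adjacent node voxels are collapsed to
their centroid so one anatomical bifurcation yields one node; staircase
3-cliques in the 26-adjacency graph are reduced by dropping the long
diagonal of any edge bypassed by a strictly shorter two-step path. Per-point
radii are read from the interior Euclidean distance transform at the
centerline — fast and voxel-noise tolerant compared with cross-sectional
fitting. Terminal spurs shorter than twice their local radius (thinning
artifacts) are pruned before the graph is finalised.

Straightness is defined as chord length over arc length, bounded in (0, 1],
with the inverse tortuosity available by reciprocal; the orientation of a
segment is the axial angle of its chord's XY projection, mapped to
(-90°, 90°] — a single angle per segment, as plotted in orientation
histograms. Closed loops have zero chord; they are flagged and excluded from
straightness statistics.

**Rim filtering.** Imaging a small field of view necessarily cuts vessels at
its rim; those partial segments would bias every statistic downwards and
are removed. The default criterion is an endpoint within one voxel of a
volume face. Thinning, however, retracts the free end of a cut tube inwards
by roughly one tube radius, so phantom studies that compare traced values
against ground truth use a rim margin of the order of the vessel radius
(`marginVoxels` in `traceMask()`, `rimMarginVoxels` in `pipelineConfig()`).

**Distance analysis.** The Euclidean distance transform is exact on the
anisotropic grid (per-axis lower-envelope algorithm on squared distances).
Vessel-interior voxels carry distance 0 and are excluded from the empirical
distribution by default: the supply question concerns tissue voxels, and
including the zeros would deflate the upper percentiles that RM10 depends
on (`includeVessel = TRUE` restores them). Percentiles use linear
interpolation between order statistics (type 7), the common statistical
software default; the convention matters for RM10 and is therefore fixed
and documented. Statistics are computed on float distances; the 0–255
heatmap channel is an export format (rounding half-up, decode error at most
max/510). A `quantized = TRUE` mode reproduces a workflow that reads
percentiles off the 8-bit histogram instead, for strict replication of
image-viewer based analyses.

**KDE areas.** The 2D density is a product-Gaussian KDE evaluated on a
256×256 grid spanning the data range padded by three bandwidths. The
bandwidth follows Scott's rule for two dimensions — kernel standard
deviation `h_i = s_i * n^(-1/6)` per axis, stated explicitly because R's
common 2D KDE (`MASS::kde2d`) divides its bandwidth argument by four and
silently changes the meaning of any rule plugged into it. The mass
threshold is found by sorting grid densities and accumulating mass until
the target level is reached (discrete highest-density region, no contour
interpolation), which is deterministic and converges under grid refinement.
Kernel smoothing convolves the true density with the kernel and therefore
inflates the HDR area — by the factor `(1 + h²/s²)` per axis for a Gaussian
cloud, about +6% at n = 5000 under Scott's rule. The reported area removes
this first-order smoothing bias (`biasCorrect = TRUE` by default):
`area × prod_i sqrt(s_i²/(s_i²+h_i²))`. The correction is exact for
Gaussian data and is a data-driven constant factor for any fixed sample, so
between-group comparisons are unaffected; `biasCorrect = FALSE` gives the
raw discrete HDR area.

Areas are computed per sample and averaged within groups by default; the
feature table keeps per-sample values so a pooled-segments analysis remains
possible by concatenating segment tables before calling `kdeAreaDS()`.

## The synthetic vasculature generator

No raw imaging volumes are redistributable, so validation rests on
synthetic phantoms with exact ground truth. Four archetypes emulate the
qualitative organisation seen in cleared-tissue volumes:

* `parallel_fiber` (skeletal muscle): long straight fibers on a near-square
  lattice with perpendicular cross-links. Lattices with extreme aspect
  ratios are rejected during calibration — they produce fiber gaps narrower
  than the tubes themselves, which no tracing could resolve.
* `random_arc` (brain cortex): isotropically oriented circular-arc segments
  grown from an expanding attachment pool, so one dominant filament carries
  at least 90% of the total length, plus a small fraction (default 5%) of
  isolated segments. Growth uses best-candidate sampling (a handful of
  admissible directions, keeping the endpoint farthest from the existing
  network) so the filament fills the domain instead of balling up around
  its seed.
* `planar_mesh` (colonic mucosa): one high-calibre square mesh layer near
  the top of the domain, fed by thinner vessels perpendicular to it; a
  two-layer variant covers retina-like geometry, as a structural analogy
  without published parameters to anchor it.
* `tumor`: the arc machinery plus hard exclusion spheres ("voids",
  reject-and-resample so no centerline — including its tube radius — enters
  them), a configurable fraction of short segments dilated to at least
  twice the base radius, broader radius scatter, and higher tortuosity.

Tubes follow a capsule model: every polyline edge is a cylinder with
hemispherical caps, the network is the union of all capsules, and a voxel
is foreground iff its centre lies inside that union. Capsules make both the
analytic volume and the surface distance well defined. For the fiber
lattice the union volume is closed-form: fiber volumes are exact cylinders,
and a cross-link whose capsule tips sit on two fiber axes adds its capsule
volume minus half a perpendicular-cylinder crossing per end (the cap ball,
lying entirely inside the fiber, cancels exactly; the crossing volume is a
generalised Steinmetz solid evaluated by 1D quadrature). Where junction
geometry is not closed-form (arcs, meshes, curved fibers) the union volume
is measured by Monte-Carlo point sampling, seeded and recorded in the
ground-truth `details`. Maximal surface distances are closed-form for the
lattice constructions (`pitch/sqrt(2) - r` at a square-lattice cell centre)
and otherwise estimated on a probe grid (a lower bound, recorded as such).

Per-segment tortuosity is scattered around the set-point (hash-indexed for
the deterministic lattice builders, Gamma-distributed for the arc family):
real capillaries are not perfectly straight, and a degenerate
zero-variance straightness axis would make the D/S density undefined.

**Calibration.** `target_volume_fraction` is met by choosing the lattice
size (coarse) and the cross-link count (fine; one link changes the fraction
by well under 1%) for fibers, and by bisection on mesh pitch (coarse) plus
feeder count and feeder length (fine) for meshes; the arc family scales its
segment count against Monte-Carlo union measurements. The calibration
contract is 2% relative. `calibrateSegmentLength()` tunes one structural
knob (link spacing or mesh pitch, with a continuous rim-margin refinement
for fibers) against the generator's own rim-filtered graph bookkeeping —
the same statistic the tracing stage reports.

All randomness flows from the single `seed` slot of the `NetworkSpec`
through a private RNG stream; the global `.Random.seed` is never touched,
and an identical `NetworkSpec` yields a bit-identical graph.

**What the phantoms do not emulate.** Rasterization supports Gaussian blur,
additive background, Poisson photon noise and a "leakiness" perturbation of
tube radii, but there is no light-sheet PSF, shadowing, depth-dependent
attenuation, or staining heterogeneity; vessels are tubes with circular
cross-sections and the networks carry no flow or pressure information.
Passing recovery tests on these phantoms demonstrates that the measurement
chain is unbiased for resolvable tube networks under mild noise — not that
segmentation would succeed on heavily degraded real acquisitions.

## Validation conditions and problem sizes

The recovery studies use phantom sizes chosen to keep the full suite fast
while leaving every estimator in its operating regime: rPVV recovery on
200³-voxel volumes at the 0.5 × 0.5 × 1 µm³ acquisition spacing with blur,
background and Poisson noise applied before auto-thresholding;
segment-length recovery on a 9 × 9 fiber lattice at the 68.5 µm set-point
pitch (378 interior segments) traced at 1.5 µm, and on a 250³ µm mesh
phantom at 1 µm; diameter recovery at the acquisition spacing, where the
EDT radius estimator is accurate to well under half a voxel diagonal;
distance extremes on deterministic lattice and single-vessel constructions
with closed-form maxima (66 µm and 177 µm); and the tumor-versus-organised
contrasts on ten seeds at 1.5 µm with ground-truth masks, where RM10 and
`KDE_50(D/S)` separate the groups in every seed and PC1–PC2 scores of the
pooled feature table are linearly separable by archetype.

## Known limitations

* Thinning-based centerlines wobble by a fraction of a voxel; straightness
  of traced (as opposed to generated) segments is accordingly a few tenths
  of a percent below 1 for perfectly straight tubes, and traced arc lengths
  carry a small staircase inflation. No sub-voxel smoothing is applied
  beyond plain polyline arithmetic.
* The EDT radius at the centerline underestimates tube radii by a sub-voxel
  amount at coarse spacing; at the acquisition spacing the bias is below
  2%.
* Vessels denser than the resolvable limit (surface gaps narrower than a
  voxel) merge in the mask; no attempt is made to separate touching tubes.
* Group comparison implements per-comparison tests; no multiplicity
  correction is applied by default (Holm adjustment is available through
  `stats::p.adjust` on the returned p values).
* The tumor archetype models spatial heterogeneity, dilation and
  tortuosity, but not arteriovenous identity, branching-angle statistics or
  perfusion intermittency.

## A minimal end-to-end run

```{r example, eval = FALSE}
spec <- networkSpec("tumor", domainSize = c(150, 150, 150),
                    targetVolumeFraction = 0.035, meanRadius = 3,
                    radiusCV = 0.25, meanSegmentLength = 45, seed = 1,
                    voids = data.frame(x = 100, y = 100, z = 100, r = 40))
truth <- generateNetwork(spec)
ras <- rasterizeNetwork(vesselGraph(truth), spacing = c(0.5, 0.5, 1),
                        domainSize = c(150, 150, 150),
                        noise = list(blurSigma = 0.6, photonScale = 120,
                                     background = 6, seed = 1))
mask <- segmentVolume(ras$intensity)
tr <- traceMask(mask)
dfield <- distanceTransform(mask)
c(rPVV = mask@rPVV,
  RM10 = computeRM10(dfield)$rm10,
  kde50 = kdeAreaDS(tr$table)$area)
```
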