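# vascumorph

Quantitative analysis of 3D vascular architecture from cleared-tissue
fluorescence volumes.

Healthy organs build regular, hierarchical capillary networks; tumors build
chaotic ones, with hyperdense patches next to avascular voids and short
dilated segments spliced into narrow vessels. Whether a treatment
"normalizes" a tumor's vasculature is a quantitative question, and this
package implements the measurements needed to answer it from light-sheet
volumes of labelled, perfused vessels:

* **Segmentation** — volumetric median filter, global/Otsu thresholding,
  removal of 26-connected fragments smaller than 2000 voxels, and the
  **relative perfused vessel volume** (rPVV = vessel voxels / total voxels);
* **Tracing** — topology-preserving 3D thinning, centerline-graph
  extraction (nodes at bifurcations and endpoints, segments between them),
  and per-segment morphometrics: arc length L, mean diameter D (2× the
  interior distance transform at the centerline), straightness
  S = chord/arc ∈ (0, 1], and the axial XY orientation angle; segments cut
  at the field-of-view rim are removed before statistics;
* **Distance analysis** — exact anisotropic Euclidean distance transform of
  the extravascular space and the heterogeneity statistic
  **RM10 = P100 − P90** of the voxel-to-vessel distance distribution (low
  RM10 ⇔ homogeneously spaced vessels);
* **Density statistics** — the area of the highest-density region holding
  50% (or 90%) of the mass of the 2D kernel density of diameter versus
  straightness, **KDE₅₀(D/S)** (small areas ⇔ hierarchical, organised
  networks), per-sample feature tables, z-scored PCA, and two-group t tests
  with an F-test screen that switches to the Welch variant;
* **Synthetic vasculature** — generators for organ archetypes (parallel
  fibers with cross-links, isotropic random arcs, planar meshes with
  feeders) and tumor-like networks (avascular voids, dilated short
  segments, high tortuosity), with exact ground truth and a capsule-model
  rasterizer (optional blur/background/Poisson/leakiness noise), used
  throughout the test suite as the source of truth.

The Evans Blue permeability correction
`A620(corrected) = A620 − (1.426·A740 + 0.030)` ships as a small utility
(`milesCorrection()`).

## Worked example

Generate a tumor-archetype phantom with an avascular void, image it with
noise, and run the full measurement chain:

```r
library(vascumorph)

spec <- networkSpec("tumor", domainSize = c(150, 150, 150),
                    targetVolumeFraction = 0.035, meanRadius = 3,
                    radiusCV = 0.25, meanSegmentLength = 45, seed = 1,
                    voids = data.frame(x = 100, y = 100, z = 100, r = 40))
truth <- generateNetwork(spec)
truth
#> GroundTruth for a tumor-domain network (150 x 150 x 150 um)
#>   volume fraction 0.0305 | mean segment length 45.56 um | mean diameter 6.38 um
#>   max surface distance 93.33 um

ras <- rasterizeNetwork(vesselGraph(truth), spacing = c(0.5, 0.5, 1),
                        domainSize = c(150, 150, 150),
                        noise = list(blurSigma = 0.6, photonScale = 120,
                                     background = 6, seed = 1))
mask <- segmentVolume(ras$intensity)
mask
#> VesselMask: 300 x 300 x 150 voxels, spacing 0.5 x 0.5 x 1 um
#>   value range [0, 1]
#>   rPVV 0.0305, 2 component(s), fragment filter >= 2000 vx

tr <- traceMask(mask)
dfield <- distanceTransform(mask)
rm10 <- computeRM10(dfield)
sprintf("rPVV %.4f | P90 %.1f um | max %.1f um | RM10 %.1f um | KDE50(D/S) %.3f",
        mask@rPVV, rm10$p90, rm10$p100, rm10$rm10, kdeAreaDS(tr$table)$area)
#> "rPVV 0.0305 | P90 46.5 um | max 93.2 um | RM10 46.7 um | KDE50(D/S) 0.936"
```

Reading the output: the segmented perfused volume fraction (3.05%) matches
the generator's ground truth; the farthest tissue voxel sits 93 µm from a
vessel and the top decile of distances spans 47 µm — the avascular void
shows up directly in RM10; and the D/S density is spread over ≈0.94 µm of
diameter–straightness area, an order of magnitude above what an organised
fiber phantom yields under the same settings. (Traced segments are shorter
on average than the generated ones because touching tumor tubes merge in
the mask and create genuine extra junctions — one reason tumor statistics
are computed from the image, not from an idealised graph.) For organised
archetypes, group comparison and PCA, see the vignette
`vignettes/quantifying-vascular-architecture.Rmd` and `runPipeline()`,
which drives TIFF stacks end to end and writes masks, SWC/GraphML graphs,
segment tables, distance histograms, 8-bit heatmaps and a run manifest.

A thin command-line front end ships in `inst/cli/vascumorph.R`
(subcommands `simulate`, `segment`, `trace`, `distances`, `stats`, `run`).

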