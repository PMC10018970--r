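test_that("lattice geometry gives the closed-form maximal surface distance", {
  # spacing 100.4 um, radius 5 um -> cell-centre distance spacing/sqrt(2) - r
  expect_equal(latticeMaxSurfaceDistance(100.4, 5), 100.4 / sqrt(2) - 5,
               tolerance = 1e-12)
  a <- 100.4
  spec <- networkSpec("parallel_fiber", domainSize = c(a, a, 30), meanRadius = 5,
                      seed = 1, latticeSpacing = a, latticeOffset = "zero",
                      linkSpacing = Inf, fiberAxis = "z")
  gt <- generateNetwork(spec)
  expect_equal(gt@analyticMaxSurfaceDistance, a / sqrt(2) - 5, tolerance = 1e-9)
  # brute-force nearest-surface search over a fine probe grid, independent of
  # the package's distance kernels
  axes <- unique(nodes(vesselGraph(gt))[, c("x", "y")])
  px <- seq(0, a, by = 0.25)
  grid <- expand.grid(x = px, y = px)
  dmin <- rep(Inf, nrow(grid))
  for (r in seq_len(nrow(axes))) {
    dmin <- pmin(dmin, sqrt((grid$x - axes$x[r])^2 + (grid$y - axes$y[r])^2) - 5)
  }
  expect_equal(max(dmin), a / sqrt(2) - 5, tolerance = 0.3)
})

test_that("a single straight cylinder has volume fraction pi r^2 l / V", {
  dom <- c(80, 40, 40)
  spec <- networkSpec("parallel_fiber", domainSize = dom, meanRadius = 4,
                      seed = 1, latticeSpacing = 100, latticeOffset = "half",
                      linkSpacing = Inf)
  gt <- generateNetwork(spec)
  expect_equal(nrow(segments(vesselGraph(gt))), 1L)
  expect_equal(gt@analyticVolumeFraction, pi * 16 * 80 / prod(dom),
               tolerance = 1e-9)
})

test_that("volume-fraction calibration hits the muscle set-point within 2%", {
  spec <- networkSpec("parallel_fiber", domainSize = c(100, 100, 200),
                      targetVolumeFraction = 0.039, meanRadius = 4.1, seed = 1)
  gt <- generateNetwork(spec)
  expect_gte(gt@analyticVolumeFraction, 0.0382)
  expect_lte(gt@analyticVolumeFraction, 0.0398)
})

test_that("infeasible volume fractions and all-covering voids are rejected", {
  expect_error(generateNetwork(
    networkSpec("parallel_fiber", domainSize = c(20, 20, 20),
                targetVolumeFraction = 0.01, meanRadius = 5, seed = 1)),
    "infeasible")
  expect_error(generateNetwork(
    networkSpec("tumor", domainSize = c(50, 50, 50), meanRadius = 3, seed = 1,
                voids = data.frame(x = 25, y = 25, z = 25, r = 60))),
    "voids")
})

test_that("random arcs are isotropic in the XY plane and match length/straightness bookkeeping", {
  spec <- networkSpec("random_arc", domainSize = c(400, 400, 400),
                      meanSegmentLength = 40, meanRadius = 3, tortuosity = 1,
                      seed = 7, nSegments = 600L)
  gt <- generateNetwork(spec)
  tab <- measureSegments(vesselGraph(gt))
  expect_gte(nrow(tab), 600)

  # orientation histogram: no 15-degree bin beyond 4 sigma of uniform
  ang <- tab$orientation_xy[!is.na(tab$orientation_xy)]
  counts <- table(cut(ang, seq(-90, 90, by = 15)))
  n <- sum(counts); p <- 1 / length(counts)
  expect_true(all(abs(counts - n * p) <= 4 * sqrt(n * p * (1 - p))))

  # tortuosity 1 -> every segment is straight in polyline arithmetic
  expect_true(all(tab$straightness > 1 - 1e-9))

  # CLT check against the generator's own set-point
  expect_lt(abs(mean(tab$length) - 40), 3 * sd(tab$length) / sqrt(nrow(tab)))

  # one dominant filament carrying >= 90% of total length
  byFil <- tapply(tab$length, tab$filament_id, sum)
  expect_gte(max(byFil) / sum(byFil), 0.9)
})

test_that("planar mesh has a high-calibre mesh layer above thinner feeders", {
  spec <- networkSpec("planar_mesh", domainSize = c(150, 150, 100),
                      meanRadius = 6.6, meanSegmentLength = 35, seed = 2,
                      meshRadius = 6.6, feederRadius = 4)
  gt <- generateNetwork(spec)
  tab <- measureSegments(vesselGraph(gt))
  zTop <- max(tab$za)
  inLayer <- tab$za >= zTop - 1 & tab$zb >= zTop - 1
  expect_gt(mean(tab$mean_diameter[inLayer]), mean(tab$mean_diameter[!inLayer]))
  expect_gt(mean(tab$mean_diameter), 2 * 4) # overall mean above feeder calibre
  expect_equal(sort(unique(round(tab$mean_diameter, 6))), c(8, 13.2))
})

test_that("a feeder-less mesh in a thin domain is planar with lattice max distance", {
  spec <- networkSpec("planar_mesh", domainSize = c(120, 120, 13),
                      meanRadius = 6.5, meanSegmentLength = 40, seed = 3,
                      feederFraction = 0, layerZ = 6.5)
  gt <- generateNetwork(spec)
  g <- vesselGraph(gt)
  zs <- unlist(lapply(polylines(g), function(pl) pl[, 3]))
  expect_lt(diff(range(zs)), 1e-9) # single plane
  expect_equal(gt@analyticMaxSurfaceDistance,
               latticeMaxSurfaceDistance(gt@details$pitch, 6.5),
               tolerance = 1e-9)
})

test_that("tumor voids exclude centerlines and raise the maximal distance", {
  void <- data.frame(x = 200, y = 200, z = 100, r = 150)
  spec <- networkSpec("tumor", domainSize = c(400, 400, 200), meanRadius = 4,
                      meanSegmentLength = 50, seed = 5, nSegments = 600L,
                      voids = void)
  gt <- generateNetwork(spec)
  # no centerline point enters the void sphere
  for (pl in polylines(vesselGraph(gt))) {
    d2 <- (pl[, 1] - 200)^2 + (pl[, 2] - 200)^2 + (pl[, 3] - 100)^2
    expect_true(all(d2 >= 150^2))
  }
  expect_gte(gt@analyticMaxSurfaceDistance, 150)

  specNoVoid <- spec
  specNoVoid@voids <- matrix(numeric(0), 0, 4)
  gt0 <- generateNetwork(specNoVoid)
  expect_gt(gt@analyticMaxSurfaceDistance, gt0@analyticMaxSurfaceDistance)
})

test_that("tumor dilation bookkeeping matches brute-force recomputation", {
  spec <- networkSpec("tumor", domainSize = c(200, 200, 200), meanRadius = 3.5,
                      meanSegmentLength = 45, seed = 6, nSegments = 120L,
                      dilatedFraction = 0.1, dilationFactor = 3)
  gt <- generateNetwork(spec)
  tab <- measureSegments(vesselGraph(gt))
  # brute force over polylines, independent of measureSegments
  diams <- vapply(polylines(vesselGraph(gt)), function(pl) 2 * mean(pl[, 4]),
                  numeric(1))
  expect_equal(sd(tab$mean_diameter) / mean(tab$mean_diameter),
               sd(diams) / mean(diams), tolerance = 1e-12)
  expect_equal(gt@analyticMeanDiameter, mean(diams), tolerance = 1e-12)
  # dilated segments carry >= 2x the base radius
  expect_true(length(gt@details$dilated) >= 1)
  expect_true(all(diams[gt@details$dilated] >= 2 * 2 * 3.5 * 0.2))

  # parameter-off identity: dilatedFraction 0, tortuosity 1 reproduces the
  # plain random-arc diameter draw
  specOff <- networkSpec("tumor", domainSize = c(200, 200, 200), meanRadius = 3.5,
                         meanSegmentLength = 45, tortuosity = 1, seed = 6,
                         nSegments = 60L, dilatedFraction = 0, radiusCV = 0.2)
  specArc <- networkSpec("random_arc", domainSize = c(200, 200, 200),
                         meanRadius = 3.5, meanSegmentLength = 45,
                         tortuosity = 1, seed = 6, nSegments = 60L,
                         radiusCV = 0.2)
  dOff <- vapply(polylines(vesselGraph(generateNetwork(specOff))),
                 function(pl) mean(pl[, 4]), numeric(1))
  dArc <- vapply(polylines(vesselGraph(generateNetwork(specArc))),
                 function(pl) mean(pl[, 4]), numeric(1))
  expect_equal(dOff, dArc, tolerance = 1e-12)

  # diameter CV exceeds the organ archetype under identical settings
  expect_gt(sd(diams) / mean(diams), sd(dArc) / mean(dArc))
})

test_that("identical spec and seed give bit-identical graphs", {
  spec <- networkSpec("random_arc", domainSize = c(150, 150, 150),
                      meanSegmentLength = 40, meanRadius = 3, seed = 11,
                      nSegments = 50L)
  g1 <- vesselGraph(generateNetwork(spec))
  g2 <- vesselGraph(generateNetwork(spec))
  expect_identical(polylines(g1), polylines(g2))
  expect_identical(nodes(g1), nodes(g2))
})

test_that("ground-truth analytics are reproducible from the emitted graph", {
  spec <- networkSpec("parallel_fiber", domainSize = c(100, 100, 100),
                      targetVolumeFraction = 0.04, meanRadius = 4, seed = 1)
  gt <- generateNetwork(spec)
  g <- vesselGraph(gt)
  lens <- vapply(polylines(g), polylineLength, numeric(1))
  expect_equal(gt@analyticMeanSegmentLength, mean(lens), tolerance = 1e-9)
  diams <- vapply(polylines(g), function(pl) 2 * mean(pl[, 4]), numeric(1))
  expect_equal(gt@analyticMeanDiameter, mean(diams), tolerance = 1e-9)
  # closed-form union volume against an independent Monte-Carlo measurement
  expect_equal(mcVolumeFraction(g, c(100, 100, 100), 200000L, seed = 99L),
               gt@analyticVolumeFraction, tolerance = 0.02)
})

test_that("rasterized volume fraction converges to the analytic value", {
  spec <- networkSpec("parallel_fiber", domainSize = c(60, 60, 60),
                      meanRadius = 4, seed = 1, latticeSpacing = 30,
                      linkSpacing = Inf)
  gt <- generateNetwork(spec)
  g <- vesselGraph(gt)
  errs <- vapply(c(1, 0.5, 0.25), function(s) {
    ras <- rasterizeNetwork(g, rep(s, 3), domainSize = c(60, 60, 60))
    abs(computeRPVV(ras$mask) - gt@analyticVolumeFraction)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.002)
})

test_that("rasterization respects the capsule model and determinism contract", {
  # straight cylinder radius 4, length 100, isotropic 0.5 um: voxel volume
  # within 5% of pi r^2 l (caps clipped by the grid)
  dom <- c(100, 24, 24)
  spec <- networkSpec("parallel_fiber", domainSize = dom, meanRadius = 4,
                      seed = 1, latticeSpacing = 50, linkSpacing = Inf)
  g <- vesselGraph(generateNetwork(spec))
  ras <- rasterizeNetwork(g, c(0.5, 0.5, 0.5), domainSize = dom)
  volVox <- sum(voxelData(ras$mask)) * 0.5^3
  expect_equal(volVox, pi * 16 * 100, tolerance = 0.05)

  # noise off: idempotent and seed-independent
  ras2 <- rasterizeNetwork(g, c(0.5, 0.5, 0.5), domainSize = dom)
  expect_identical(voxelData(ras$mask), voxelData(ras2$mask))
  expect_null(ras$intensity)

  # empty graph -> all background
  g0 <- vascumorph:::makeVesselGraph(matrix(numeric(0), 0, 3),
                                     data.frame(node_a = integer(0),
                                                node_b = integer(0)),
                                     list())
  r0 <- rasterizeNetwork(g0, c(1, 1, 1), domainSize = c(20, 20, 20))
  expect_equal(sum(voxelData(r0$mask)), 0)

  # the noise model returns an intensity copy but never touches the mask
  rn <- rasterizeNetwork(g, c(1, 1, 1), domainSize = dom,
                         noise = list(blurSigma = 0.8, photonScale = 80,
                                      background = 5, leakiness = 0.1,
                                      seed = 3))
  expect_false(is.null(rn$intensity))
  expect_identical(voxelData(rn$mask), voxelData(
    rasterizeNetwork(g, c(1, 1, 1), domainSize = dom)$mask))
})
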