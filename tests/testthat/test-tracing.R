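test_that("skeletonization preserves topology for tubes, pairs and tori", {
  # solid straight tube -> a single centerline path
  g <- buildVesselGraph(skeletonizeMask(tubeMask()))
  expect_equal(nrow(segments(g)), 1L)
  expect_equal(sort(nodes(g)$degree), c(1L, 1L))

  # two disjoint tubes -> two skeleton components
  m2 <- tubeMask(c(40, 40, 20), radius = 3, centre = c(10, 10))
  v <- voxelData(m2) + voxelData(tubeMask(c(40, 40, 20), radius = 3,
                                          centre = c(30, 10)))
  g2 <- buildVesselGraph(skeletonizeMask(rasterVolume(pmin(v, 1))))
  expect_equal(length(unique(segments(g2)$filament_id)), 2L)

  # torus -> exactly one cycle (Euler: edges - vertices + components = 1)
  tr <- traceMask(torusMask(), removeBoundary = FALSE)
  s <- segments(tr$graph)
  ig <- igraph::graph_from_data_frame(data.frame(s$node_a, s$node_b),
                                      directed = FALSE)
  expect_equal(igraph::ecount(ig) - igraph::vcount(ig) +
                 igraph::count_components(ig), 1)

  # empty mask -> empty skeleton
  sk0 <- skeletonizeMask(rasterVolume(array(0, c(10, 10, 10))))
  expect_equal(sum(voxelData(sk0)), 0)
})

test_that("a rasterized Y yields one bifurcation, three endpoints, three segments", {
  ras <- rasterizeNetwork(yGraph(), c(1, 1, 1), domainSize = c(55, 50, 20))
  tr <- traceMask(ras$mask, removeBoundary = FALSE)
  expect_equal(nrow(segments(tr$graph)), 3L)
  expect_equal(sort(nodes(tr$graph)$degree), c(1L, 1L, 1L, 3L))
})

test_that("segment measures reproduce closed-form arc values", {
  # straight segment
  straight <- cbind(x = c(0, 10), y = c(0, 0), z = c(0, 0), radius = 2)
  m <- measureSegment(straight)
  expect_equal(m$straightness, 1)
  expect_equal(m$length, 10)
  expect_equal(m$mean_diameter, 4)
  expect_equal(m$orientation_xy, 0)

  # semicircle: chord 2r over arc pi r
  expect_equal(measureSegment(arcPoly(pi))$straightness, 2 / pi,
               tolerance = 1e-3)
  # quarter circle: chord r sqrt(2) over arc pi r / 2
  expect_equal(measureSegment(arcPoly(pi / 2))$straightness,
               2 * sqrt(2) / pi, tolerance = 1e-3)

  # closed loop: zero-length chord -> straightness 0, flagged
  loop <- arcPoly(2 * pi)
  loop[nrow(loop), 1:3] <- loop[1, 1:3]
  ml <- measureSegment(loop)
  expect_equal(ml$straightness, 0)
  expect_true(ml$loop)

  # orientation is axial in (-90, 90]
  diag <- cbind(x = c(0, -5), y = c(0, 5), z = c(0, 0), radius = 1)
  expect_equal(measureSegment(diag)$orientation_xy, -45)
  vert <- cbind(x = c(0, 0), y = c(0, 0), z = c(0, 9), radius = 1)
  expect_true(is.na(measureSegment(vert)$orientation_xy))
})

test_that("straightness equals 1 exactly iff the polyline is collinear", {
  collinear <- cbind(x = seq(0, 20, by = 0.5), y = 0, z = 0, radius = 1)
  expect_gte(measureSegment(collinear)$straightness, 1 - 1e-9)
  bent <- collinear
  bent[10, 2] <- 0.2
  expect_lt(measureSegment(bent)$straightness, 1 - 1e-9)
})

test_that("tube diameter is recovered from the interior EDT at the centerline", {
  # cylinder radius 4.1 um at the acquisition spacing: mean diameter within
  # half a voxel diagonal of 8.2 um
  dom <- c(80, 30, 30)
  spec <- networkSpec("parallel_fiber", domainSize = dom, meanRadius = 4.1,
                      seed = 3, latticeSpacing = 60, linkSpacing = Inf)
  ras <- rasterizeNetwork(vesselGraph(generateNetwork(spec)), c(0.5, 0.5, 1),
                          domainSize = dom)
  tr <- traceMask(ras$mask, removeBoundary = FALSE)
  halfDiag <- sqrt(sum(c(0.5, 0.5, 1)^2)) / 2
  expect_lt(abs(mean(tr$table$mean_diameter) - 8.2), halfDiag)
})

test_that("rim cut-off filtering drops face-touching segments only", {
  tab <- data.frame(segment_id = 1:3, filament_id = 1L,
                    length = c(10, 10, 10), mean_diameter = 4,
                    straightness = 1, orientation_xy = 0, loop = FALSE,
                    xa = c(0, 20, 30), ya = c(25, 25, 25), za = c(10, 10, 10),
                    xb = c(10, 30, 40), yb = c(25, 25, 25), zb = c(10, 10, 18))
  out <- removeBoundarySegments(tab, c(0, 0, 0), c(50, 50, 19), c(1, 1, 1))
  expect_equal(out$segment_id, 2L) # 1 touches x=0, 3 ends within 1 voxel of z face
})

test_that("rim filtering brings the traced mean length closer to ground truth", {
  dom <- c(150, 150, 150)
  spec <- networkSpec("parallel_fiber", domainSize = dom, meanRadius = 4,
                      meanSegmentLength = 45, seed = 4)
  gt <- generateNetwork(spec)
  gtTab <- removeBoundarySegments(measureSegments(vesselGraph(gt)),
                                  c(0, 0, 0), dom, rep(1, 3))
  ras <- rasterizeNetwork(vesselGraph(gt), c(1, 1, 1), domainSize = dom)
  trAll <- traceMask(ras$mask, removeBoundary = FALSE)$table
  trRim <- traceMask(ras$mask, marginVoxels = 6)$table
  truth <- mean(gtTab$length)
  expect_lt(abs(mean(trRim$length) - truth), abs(mean(trAll$length) - truth))
  # segment count within 10% of the generator's interior count
  expect_lt(abs(nrow(trRim) - nrow(gtTab)) / nrow(gtTab), 0.1)
})

test_that("morphometrics are recovered within 5% at the fine acquisition spacing", {
  dom <- c(80, 80, 80)
  spec <- networkSpec("parallel_fiber", domainSize = dom, meanRadius = 4,
                      meanSegmentLength = 40, seed = 4)
  gt <- generateNetwork(spec)
  gtTab <- removeBoundarySegments(measureSegments(vesselGraph(gt)),
                                  c(0, 0, 0), dom, rep(1, 3))
  ras <- rasterizeNetwork(vesselGraph(gt), c(0.5, 0.5, 0.5), domainSize = dom)
  tr <- traceMask(ras$mask, marginVoxels = 10)$table
  truth <- mean(gtTab$length)
  expect_lt(abs(mean(tr$length) - truth) / truth, 0.05)
  expect_lt(abs(mean(tr$mean_diameter) - 8) / 8, 0.05)
  expect_lt(abs(mean(tr$straightness) -
                  mean(gtTab$straightness)) / mean(gtTab$straightness), 0.05)
})

test_that("arc length of an axis-aligned rasterized tube matches within a voxel step", {
  m <- tubeMask(c(50, 16, 16), radius = 3.5)
  tr <- traceMask(m, removeBoundary = FALSE)
  # thinning retracts each free end by about the tube radius
  expect_equal(sum(tr$table$length), 49, tolerance = 9)
  expect_equal(nrow(tr$table), 1L)
  expect_gt(tr$table$straightness, 0.999)
})

test_that("orientation centering shifts the modal bin to zero", {
  expect_true(all(centerOrientationDistribution(rep(32, 10))$angles == 0))

  set.seed(8)
  u <- runif(4000, -90, 90)
  cu <- centerOrientationDistribution(u)
  h <- cu$histogram
  n <- 4000; p <- 1 / nrow(h)
  expect_true(all(abs(h$frequency * n - n * p) <= 4 * sqrt(n * p * (1 - p))))
  expect_true(all(cu$angles > -90 & cu$angles <= 90))

  # fibers have a much tighter axial spread than isotropic arcs
  fib <- networkSpec("parallel_fiber", domainSize = c(150, 150, 150),
                     targetVolumeFraction = 0.04, meanRadius = 4, seed = 5)
  arc <- networkSpec("random_arc", domainSize = c(150, 150, 150),
                     meanSegmentLength = 40, meanRadius = 3, seed = 5,
                     nSegments = 200L)
  angF <- measureSegments(vesselGraph(generateNetwork(fib)))$orientation_xy
  angA <- measureSegments(vesselGraph(generateNetwork(arc)))$orientation_xy
  sdF <- axialCircularSD(centerOrientationDistribution(angF)$angles)
  sdA <- axialCircularSD(centerOrientationDistribution(angA)$angles)
  expect_lt(sdF, sdA)
})

test_that("graph totals are independent of segment ordering", {
  spec <- networkSpec("random_arc", domainSize = c(120, 120, 120),
                      meanSegmentLength = 35, meanRadius = 3, seed = 9,
                      nSegments = 60L)
  g <- vesselGraph(generateNetwork(spec))
  tab <- measureSegments(g)
  perm <- sample(nrow(tab))
  expect_equal(sum(tab$length[perm]), sum(tab$length))
  expect_equal(sort(tab$segment_id), seq_len(nrow(tab)))
})
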