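test_that("distance transform is exact against the brute-force oracle", {
  # face-adjacent background voxel along x at 0.5 um spacing
  arr <- array(0, c(10, 10, 10))
  arr[5, 5, 5] <- 1
  f <- distanceTransform(rasterVolume(arr, c(0.5, 0.5, 1)))
  expect_equal(f@field[6, 5, 5], 0.5)
  expect_equal(f@field[5, 6, 5], 0.5)
  expect_equal(f@field[5, 5, 6], 1)
  expect_equal(f@field[5, 5, 5], 0)

  # random masks <= 25^3 with anisotropic spacing: exact agreement
  for (seed in 1:2) {
    set.seed(seed)
    d <- c(20, 18, 15)
    m <- array(as.numeric(runif(prod(d)) < 0.04), d)
    if (sum(m) == 0) m[3, 3, 3] <- 1
    sp <- c(0.5, 0.7, 1.1)
    f <- distanceTransform(rasterVolume(m, sp))
    expect_lt(max(abs(f@field - bruteForceEDT(m, sp))), 1e-9)
  }

  # single vessel plane at the first z slice: distance k um at z-index k
  arr <- array(0, c(9, 9, 12))
  arr[, , 1] <- 1
  f <- distanceTransform(rasterVolume(arr, c(0.5, 0.5, 1)))
  for (k in c(2, 5, 12)) expect_equal(f@field[4, 4, k], k - 1)

  expect_error(distanceTransform(rasterVolume(array(0, c(8, 8, 8)))), "empty")
})

test_that("vessel voxels are excluded from the distribution by default", {
  arr <- array(0, c(10, 10, 10))
  arr[1:5, , ] <- 1
  f <- distanceTransform(rasterVolume(arr))
  expect_equal(length(distances(f)), 500)
  expect_true(all(distances(f) > 0))
  fi <- distanceTransform(rasterVolume(arr), includeVessel = TRUE)
  expect_equal(length(distances(fi)), 1000)
})

test_that("distance histograms are normalised with bounded support", {
  arr <- array(0, c(12, 12, 12))
  arr[6, 6, 6] <- 1
  f <- distanceTransform(rasterVolume(arr))
  h <- distanceHistogram(f, 2)
  expect_equal(sum(h$frequency), 1)

  # all distances in one bin
  arr2 <- array(0, c(8, 8, 8))
  arr2[, , 1] <- 1
  f2 <- distanceTransform(rasterVolume(arr2, c(1, 1, 5)))
  h2 <- distanceHistogram(f2, 100)
  expect_equal(h2$frequency[1], 1)

  # lattice phantom support bounded by the analytic maximum
  a <- 40
  spec <- networkSpec("parallel_fiber", domainSize = c(a, a, 20), meanRadius = 4,
                      seed = 1, latticeSpacing = a, latticeOffset = "zero",
                      linkSpacing = Inf, fiberAxis = "z")
  gt <- generateNetwork(spec)
  ras <- rasterizeNetwork(vesselGraph(gt), c(0.5, 0.5, 1),
                          domainSize = c(a, a, 20))
  fl <- distanceTransform(ras$mask)
  h3 <- distanceHistogram(fl, 2)
  sup <- max(h3$bin_center[h3$frequency > 0]) - 1 # bin centre -> upper edge
  expect_lte(sup, gt@analyticMaxSurfaceDistance + sqrt(sum(c(0.5, 0.5, 1)^2)))
})

test_that("RM10 equals p100 - p90 with the sorted-array percentile convention", {
  r <- computeRM10(as.numeric(0:100))
  expect_equal(r$p90, 90)
  expect_equal(r$p100, 100)
  expect_equal(r$rm10, 10)

  expect_equal(computeRM10(rep(7.5, 50))$rm10, 0)
  expect_error(computeRM10(1:9), "at least 10")

  # oracle: sorted-array linear interpolation, independent implementation
  set.seed(5)
  x <- rexp(501, 0.1)
  s <- sort(x)
  hIdx <- (length(s) - 1) * 0.9 + 1
  p90 <- s[floor(hIdx)] + (hIdx - floor(hIdx)) * (s[floor(hIdx) + 1] - s[floor(hIdx)])
  r2 <- computeRM10(x)
  expect_equal(r2$p90, p90, tolerance = 1e-12)
  expect_equal(r2$rm10, max(x) - p90, tolerance = 1e-12)
})

test_that("injecting a void strictly increases RM10 at similar vessel volume", {
  dom <- c(120, 120, 120)
  base <- networkSpec("random_arc", domainSize = dom, meanSegmentLength = 40,
                      meanRadius = 3.5, seed = 3, nSegments = 80L)
  withVoid <- networkSpec("tumor", domainSize = dom, meanSegmentLength = 40,
                          meanRadius = 3.5, seed = 3, nSegments = 80L,
                          dilatedFraction = 0,
                          voids = data.frame(x = 60, y = 60, z = 60, r = 35))
  rmOf <- function(spec) {
    ras <- rasterizeNetwork(vesselGraph(generateNetwork(spec)), c(1.5, 1.5, 1.5),
                            domainSize = dom)
    computeRM10(distanceTransform(ras$mask))$rm10
  }
  expect_gt(rmOf(withVoid), rmOf(base))
})

test_that("8-bit heatmap encoding maps [0, max] onto 0-255 within the quantization bound", {
  arr <- array(0, c(10, 10, 10))
  arr[1, 1, 1] <- 1
  f <- distanceTransform(rasterVolume(arr))
  hm <- encode8bitHeatmap(f)
  g <- voxelData(hm$volume)
  expect_equal(g[1, 1, 1], 0)
  expect_equal(max(g), 255)
  expect_equal(g[which.max(f@field)], 255)
  # round-trip decode error <= max/510 everywhere
  decoded <- g * hm$scale
  expect_lte(max(abs(decoded - f@field)), hm$maxDistance / 510 + 1e-12)

  # constant nonzero field -> grey 255 (degenerate range convention)
  cf <- new("DistanceField", field = array(3, c(8, 8, 8)),
            distances = rep(3, 512), spacing = c(1, 1, 1),
            includesVessel = FALSE)
  expect_true(all(voxelData(encode8bitHeatmap(cf)$volume) == 255))
})

test_that("quantized mode reproduces the 8-bit histogram workflow", {
  arr <- array(0, c(15, 15, 15))
  arr[8, 8, 8] <- 1
  fq <- distanceTransform(rasterVolume(arr), quantized = TRUE)
  ff <- distanceTransform(rasterVolume(arr))
  mx <- max(ff@field)
  expect_true(all(abs(distances(fq) - distances(ff)) <= mx / 510 + 1e-12))
  # quantized values sit on the 256-level grid
  lv <- distances(fq) / (mx / 255)
  expect_true(all(abs(lv - round(lv)) < 1e-9))
})
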