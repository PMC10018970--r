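test_that("KDE highest-density areas recover the Gaussian closed form", {
  set.seed(2)
  x <- rnorm(5000, sd = 2)
  y <- rnorm(5000, sd = 2)
  a <- kdeArea(x, y, 0.5)
  expect_equal(a$area, 2 * pi * log(2) * 4, tolerance = 0.05)

  # nested mass levels on the same sample
  a9 <- kdeArea(x, y, 0.9)
  expect_lt(a$area, a9$area)

  # translation invariance
  at <- kdeArea(x + 100, y - 42, 0.5)
  expect_equal(at$area, a$area, tolerance = 1e-9)

  # axis scaling multiplies the area by a * b
  as_ <- kdeArea(3 * x, 0.5 * y, 0.5)
  expect_equal(as_$area, a$area * 1.5, tolerance = 1e-6)
})

test_that("degenerate point clouds are rejected with a diagnostic", {
  expect_error(kdeArea(rep(1, 30), rnorm(30)), "constant")
  z <- rnorm(30)
  expect_error(kdeArea(z, 2 * z + 1), "collinear")
  expect_error(kdeArea(rnorm(10), rnorm(10)), "at least 20")
})

test_that("feature assembly is consistent with the individually computed statistics", {
  dom <- c(100, 100, 100)
  mkSample <- function(seed, label) {
    spec <- networkSpec("random_arc", domainSize = dom, meanSegmentLength = 35,
                        meanRadius = 3, radiusCV = 0.15, tortuosity = 1.2,
                        seed = seed, nSegments = 60L)
    g <- vesselGraph(generateNetwork(spec))
    ras <- rasterizeNetwork(g, c(1.5, 1.5, 1.5), domainSize = dom)
    mask <- filterSmallFragments(ras$mask, 5)
    list(id = paste0("s", seed), label = label, mask = mask,
         table = measureSegments(g), distance = distanceTransform(mask))
  }
  samples <- list(mkSample(1, "a"), mkSample(2, "a"), mkSample(3, "b"),
                  mkSample(4, "b"))
  ft <- assembleFeatureTable(samples)
  expect_equal(nrow(ft), 4)
  expect_equal(ft$group, c("a", "a", "b", "b"))

  # row values equal the individually computed statistics
  s1 <- samples[[1]]
  expect_equal(ft$rPVV[1], s1$mask@rPVV)
  expect_equal(ft$RM10[1], computeRM10(s1$distance)$rm10)
  tab1 <- s1$table[!s1$table$loop, ]
  expect_equal(ft$mean_length[1], mean(tab1$length))
  expect_equal(ft$kde50_DS[1], kdeAreaDS(tab1, 0.5)$area)
  expect_equal(ft$filament_count[1], length(unique(tab1$filament_id)))

  # permuting sample order permutes rows only
  ftr <- assembleFeatureTable(rev(samples))
  expect_equal(ftr[rev(seq_len(4)), -1], ft[, -1], ignore_attr = TRUE)

  # samples with too few segments are dropped with a warning
  few <- mkSample(5, "a")
  few$table <- few$table[1:5, ]
  expect_warning(ft2 <- assembleFeatureTable(c(samples, list(few))),
                 "dropping")
  expect_equal(nrow(ft2), 4)

  # inconsistent voxel spacing across samples is an error
  bad <- mkSample(6, "b")
  bad$mask@spacing <- c(2, 2, 2)
  expect_error(assembleFeatureTable(c(samples, list(bad))), "spacing")
})

test_that("PCA ranks variables by PC1-PC2 loading norm and is scaling-invariant", {
  set.seed(10)
  n <- 12
  shared <- rnorm(n, sd = 3)
  tb <- data.frame(id = paste0("s", 1:n), group = rep(c("a", "b"), each = n / 2),
                   f1 = shared + rnorm(n, sd = 0.1),
                   f2 = -shared + rnorm(n, sd = 0.1),
                   f3 = rnorm(n), f4 = rnorm(n))
  p <- runPCA(tb)
  expect_gt(p$varianceRatio[1], max(p$varianceRatio[-1]))
  # ranking orders variables by their PC1-PC2 loading-vector norm
  norms <- sqrt(rowSums(p$loadings[, 1:2]^2))
  expect_equal(p$ranking, names(sort(norms, decreasing = TRUE)))

  # z-scoring makes scores invariant under feature scaling
  tb2 <- tb
  tb2$f1 <- tb$f1 * 1000
  p2 <- runPCA(tb2)
  expect_equal(abs(p2$scores), abs(p$scores), tolerance = 1e-9)

  expect_error(runPCA(tb[1:2, ]), "at least 3")
  tbc <- tb
  tbc$f3 <- 1
  expect_error(runPCA(tbc), "constant")
})

test_that("group comparison screens variances and reduces to the textbook t test", {
  # identical groups -> p = 1 (degenerate zero-variance convention)
  r0 <- groupCompare(c(rep(5, 4), rep(5, 4)), rep(c("a", "b"), each = 4))
  expect_equal(r0$p.value, 1)
  expect_equal(r0$variant, "degenerate")

  # pooled t statistic matches the hand formula when variances agree
  set.seed(21)
  a <- rnorm(10, 0, 1); b <- rnorm(10, 0.8, 1)
  r <- groupCompare(c(a, b), rep(c("a", "b"), each = 10))
  sp2 <- (9 * var(a) + 9 * var(b)) / 18
  tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 10 + 1 / 10))
  expect_equal(r$variant, "student")
  expect_equal(r$statistic, tHand, tolerance = 1e-12)
  expect_equal(r$p.value, 2 * pt(-abs(tHand), 18), tolerance = 1e-12)

  # constructed heteroscedasticity selects the Welch variant
  set.seed(22)
  a2 <- rnorm(12, 0, 0.2); b2 <- rnorm(12, 1, 4)
  r2 <- groupCompare(c(a2, b2), rep(c("a", "b"), each = 12))
  expect_equal(r2$variant, "welch")
  tt <- t.test(a2, b2)
  expect_equal(r2$p.value, tt$p.value, tolerance = 1e-12)

  expect_error(groupCompare(1:4, c("a", "b", "c", "a")), "two groups")
})

test_that("the Evans Blue hemoglobin correction follows the printed formula", {
  expect_equal(milesCorrection(1.0, 0.5), 0.257)
  expect_equal(milesCorrection(0.8, 0), 0.77)
  # monotone decreasing in the 740 nm reading
  a740 <- seq(0, 1, by = 0.1)
  out <- milesCorrection(1.2, a740)
  expect_true(all(diff(out) < 0))
  expect_error(milesCorrection(-0.1, 0.2))
})
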