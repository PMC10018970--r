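# fixtures built in code: small masks, graphs and polylines reused across tests

# solid axis-aligned tube mask (axis = x), radius in voxels of the yz plane
tubeMask <- function(dims = c(40, 20, 20), radius = 4, centre = NULL,
                     spacing = c(1, 1, 1)) {
  if (is.null(centre)) centre <- c(dims[2] / 2, dims[3] / 2)
  arr <- array(0, dims)
  for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (sqrt((j - centre[1])^2 + (k - centre[2])^2) <= radius) arr[, j, k] <- 1
  }
  rasterVolume(arr, spacing)
}

# torus mask around the z axis of the array centre
torusMask <- function(n = 40, height = 12, major = 12, minor = 3) {
  arr <- array(0, c(n, n, height))
  c0 <- n / 2
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(height)) {
    rr <- sqrt((i - c0)^2 + (j - c0)^2)
    if (sqrt((rr - major)^2 + (k - height / 2)^2) <= minor) arr[i, j, k] <- 1
  }
  rasterVolume(arr, c(1, 1, 1))
}

# tiny hand-built vessel graph: three straight segments in a Y
yGraph <- function(radius = 3) {
  np <- rbind(c(10, 25, 10), c(30, 25, 10), c(45, 10, 10), c(45, 40, 10))
  vascumorph:::makeVesselGraph(
    np,
    data.frame(node_a = c(1, 2, 2), node_b = c(2, 3, 4)),
    list(cbind(x = c(10, 30), y = c(25, 25), z = c(10, 10), radius = radius),
         cbind(x = c(30, 45), y = c(25, 10), z = c(10, 10), radius = radius),
         cbind(x = c(30, 45), y = c(25, 40), z = c(10, 10), radius = radius)))
}

# fine circular-arc polyline spanning `angle` radians, unit radius
arcPoly <- function(angle, nPts = 2001, radius = 1) {
  th <- seq(0, angle, length.out = nPts)
  cbind(x = radius * cos(th), y = radius * sin(th), z = 0, radius = 1)
}

# brute-force anisotropic EDT oracle (O(n^2)); distances to nearest fg voxel
bruteForceEDT <- function(mask, spacing) {
  d <- dim(mask)
  co <- which(mask == 1, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dd <- ((i - co[, 1]) * spacing[1])^2 + ((j - co[, 2]) * spacing[2])^2 +
      ((k - co[, 3]) * spacing[3])^2
    out[i, j, k] <- sqrt(min(dd))
  }
  out
}

# exhaustive Otsu oracle: maximise between-class variance over candidate cuts
otsuOracle <- function(values, nBins = 256L) {
  br <- seq(min(values), max(values), length.out = nBins + 1L)
  cuts <- br[-c(1, nBins + 1L)]
  bcv <- vapply(cuts, function(t) {
    lo <- values[values < t]; hi <- values[values >= t]
    if (!length(lo) || !length(hi)) return(-Inf)
    w <- length(lo) / length(values)
    w * (1 - w) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}

# mask with one block per requested component size, well separated
blocksMask <- function(sizes, base = c(10, 10)) {
  nb <- length(sizes)
  maxLen <- ceiling(max(sizes) / prod(base)) + 2L
  arr <- array(0, c((base[1] + 4) * nb, base[2] + 8, maxLen + 6))
  for (b in seq_len(nb)) {
    s <- sizes[b]
    x0 <- (b - 1) * (base[1] + 4) + 2
    full <- s %/% prod(base)
    rem <- s %% prod(base)
    if (full > 0) {
      arr[x0:(x0 + base[1] - 1), 3:(2 + base[2]), 3:(2 + full)] <- 1
    }
    if (rem > 0) {
      # partial slab on top, attached to the full block
      cells <- arrayInd(seq_len(rem), base)
      for (r in seq_len(rem)) {
        arr[x0 + cells[r, 1] - 1, 2 + cells[r, 2], 3 + full] <- 1
      }
    }
  }
  rasterVolume(arr)
}
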