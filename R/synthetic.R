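#' Specify a synthetic vascular network
#'
#' Builds a validated [NetworkSpec] for the synthetic vasculature generators.
#' The archetypes emulate the qualitative organisation of perfused capillary
#' beds seen in cleared-tissue light-sheet volumes: long parallel fibers with
#' sparse cross-links (skeletal muscle), short isotropically oriented arcs
#' (brain cortex), a planar high-calibre mesh fed by perpendicular vessels
#' (colonic mucosa), and a disorganised tumor network with avascular voids
#' and short dilated segments.
#'
#' @param archetype `"parallel_fiber"`, `"random_arc"`, `"planar_mesh"` or
#'   `"tumor"`.
#' @param domainSize numeric(3) box extents in um.
#' @param targetVolumeFraction fraction in (0,1) the generator calibrates its
#'   tube-union volume to, or `NA` (default) for the structural default.
#' @param meanSegmentLength um; set-point for inter-bifurcation segment
#'   length.
#' @param meanRadius um; tube radius set-point (vessel diameter is `2 *
#'   meanRadius`).
#' @param radiusCV coefficient of variation of per-segment radii (0 =
#'   uniform calibre).
#' @param tortuosity path/chord ratio of segment centerlines, `>= 1`;
#'   defaults per archetype (1 for the organised lattice archetypes, 1.15
#'   for random arcs, 1.3 for tumors).
#' @param voids optional matrix/data.frame with columns `x`, `y`, `z`, `r`
#'   (um): hard exclusion spheres no centerline may enter (tumor archetype).
#' @param seed integer; every source of randomness in the generator flows
#'   from it and the global RNG state is left untouched.
#' @param ... archetype-specific knobs stored in `extra`:
#'   `latticeSpacing`, `latticeOffset` ("half"/"zero"), `jitter`,
#'   `linkRadiusFactor`, `linkSpacing`, `fiberAxis` (parallel_fiber);
#'   `isolatedFraction` (random_arc/tumor); `meshRadius`, `feederRadius`,
#'   `pitch`, `layerZ`, `feederFraction`, `feederLength`, `nLayers`
#'   (planar_mesh); `dilatedFraction`, `dilationFactor` (tumor).
#' @return a [NetworkSpec].
#' @export
networkSpec <- function(archetype,
                        domainSize = c(200, 200, 200),
                        targetVolumeFraction = NA_real_,
                        meanSegmentLength = 50,
                        meanRadius = 4,
                        radiusCV = 0,
                        tortuosity = NULL,
                        voids = NULL,
                        seed = 1L,
                        ...) {
  if (is.null(tortuosity)) {
    tortuosity <- switch(archetype, random_arc = 1.15, tumor = 1.3, 1)
  }
  if (is.null(voids)) {
    voids <- matrix(numeric(0), 0, 4, dimnames = list(NULL, c("x", "y", "z", "r")))
  } else {
    voids <- as.matrix(as.data.frame(voids)[, c("x", "y", "z", "r")])
  }
  new("NetworkSpec", archetype = archetype, domainSize = as.numeric(domainSize),
      targetVolumeFraction = as.numeric(targetVolumeFraction),
      meanSegmentLength = as.numeric(meanSegmentLength),
      meanRadius = as.numeric(meanRadius), radiusCV = as.numeric(radiusCV),
      tortuosity = as.numeric(tortuosity), voids = voids,
      seed = as.integer(seed), extra = list(...))
}

#' Generate a synthetic vascular network
#'
#' Dispatches on the archetype of `spec`. Identical `spec` (including seed)
#' yields a bit-identical graph.
#'
#' @param spec a [NetworkSpec].
#' @return a [GroundTruth] whose `graph` slot holds the generated
#'   [VesselGraph]; accessors: [vesselGraph()].
#' @export
generateNetwork <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  validObject(spec)
  switch(spec@archetype,
    parallel_fiber = generateParallelFiberNetwork(spec),
    random_arc = generateRandomArcNetwork(spec),
    planar_mesh = generatePlanarMeshNetwork(spec),
    tumor = generateTumorNetwork(spec)
  )
}

# ---------------------------------------------------------------------------
# parallel_fiber: long straight fibers on a (optionally jittered) lattice with
# perpendicular cross-links; the union volume is closed-form because overlaps
# occur only at right-angle junctions (two perpendicular circular cylinders).

# intersection volume of two perpendicular cylinders with radii R >= rho whose
# axes cross (generalised Steinmetz solid); equals 16 r^3 / 3 for R == rho
perpCylinderOverlap <- function(R, rho) {
  if (rho > R) { tmp <- R; R <- rho; rho <- tmp }
  stats::integrate(function(z) 4 * sqrt(R^2 - z^2) * sqrt(rho^2 - z^2),
                   -rho, rho, rel.tol = 1e-10)$value
}

#' Maximal surface distance inside a square lattice of parallel cylinders
#'
#' For fibers of radius `radius` on a square lattice with centre spacing
#' `spacing`, the point farthest from any tube surface is the cell centre, at
#' `spacing / sqrt(2) - radius`.
#'
#' @param spacing lattice pitch in um.
#' @param radius tube radius in um.
#' @return maximal surface distance in um.
#' @export
latticeMaxSurfaceDistance <- function(spacing, radius) {
  spacing / sqrt(2) - radius
}

# build fibers along +x; permuted to the requested axis afterwards
#' @rdname generateNetwork
#' @export
generateParallelFiberNetwork <- function(spec) {
  stopifnot(spec@archetype == "parallel_fiber")
  ex <- spec@extra
  axis <- if (is.null(ex$fiberAxis)) "x" else ex$fiberAxis
  dom <- permuteDomain(spec@domainSize, axis, inverse = TRUE)
  Lx <- dom[1]; Ly <- dom[2]; Lz <- dom[3]
  V <- prod(dom)
  R <- spec@meanRadius
  rho <- R * (if (is.null(ex$linkRadiusFactor)) 1 else ex$linkRadiusFactor)
  offset <- if (is.null(ex$latticeOffset)) "half" else ex$latticeOffset
  jitter <- if (is.null(ex$jitter)) 0 else ex$jitter
  rs <- .seededRNG(spec@seed)
  fibvol <- pi * R^2 * Lx

  latPos <- function(L, a) {
    if (offset == "zero") return(seq(0, L + 1e-9, by = a))
    if (a >= L) return(L / 2) # one centred fiber
    seq(a / 2, L - a / 2 + 1e-9, by = a)
  }
  target <- spec@targetVolumeFraction
  if (!is.null(ex$latticeSpacing)) {
    a <- ex$latticeSpacing
    ys <- latPos(Ly, a)
    zs <- latPos(Lz, a)
    grid <- expand.grid(y = ys, z = zs)
    ay <- a; az <- a
  } else {
    if (is.na(target)) target <- 0.04
    if (fibvol > target * V) {
      stop("infeasible target_volume_fraction: a single fiber of radius ",
           R, " um already exceeds it; reduce meanRadius or raise the target")
    }
    kmax <- floor(target * V / fibvol)
    # near-square lattice with spacing >= 2.2 R in each direction
    best <- NULL
    for (ny in seq_len(max(1, floor(Ly / (2.2 * R))))) {
      nz <- min(floor(kmax / ny), floor(Lz / (2.2 * R)))
      if (nz < 1) next
      # near-square lattices first (extreme aspect ratios give fiber gaps
      # narrower than the tubes themselves), then maximise the fiber count,
      # preferring ny >= 2 so cross-links remain available as the fine
      # volume knob
      aspect <- max(Ly / ny, Lz / nz) / min(Ly / ny, Lz / nz)
      sc <- (aspect <= 2) * 1e7 + ny * nz * 1000 + (ny >= 2) * 100 + min(ny, nz)
      if (is.null(best) || sc > best$score) best <- list(ny = ny, nz = nz, score = sc)
    }
    if (is.null(best)) stop("domain too small for one fiber at this radius")
    ny <- best$ny; nz <- best$nz
    ay <- Ly / ny; az <- Lz / nz
    ys <- (seq_len(ny) - 0.5) * ay
    zs <- (seq_len(nz) - 0.5) * az
    grid <- expand.grid(y = ys, z = zs)
  }
  k <- nrow(grid)
  if (jitter > 0) {
    jmax <- min(jitter, 0.5 * (min(ay, az) - 2.2 * R))
    jmax <- max(jmax, 0)
    grid$y <- pmin(pmax(grid$y + rs$unif(k, -jmax, jmax), R), Ly - R)
    grid$z <- pmin(pmax(grid$z + rs$unif(k, -jmax, jmax), R), Lz - R)
  }
  radii <- if (spec@radiusCV > 0) {
    pmax(R * (1 + spec@radiusCV * rs$norm(k)), 0.25 * R)
  } else rep(R, k)

  # cross-links between y-adjacent fibers (same z row); staggered along x
  # (expand.grid builds the lattice with y varying fastest)
  nyy <- length(ys)
  nzz <- length(zs)
  pairs <- NULL
  if (nyy > 1) {
    for (iz in seq_len(nzz)) {
      for (iy in seq_len(nyy - 1)) {
        fa <- (iz - 1) * nyy + iy
        pairs <- rbind(pairs, c(fa, fa + 1))
      }
    }
  }
  nPairs <- if (is.null(pairs)) 0 else nrow(pairs)

  # how many links, and where along x
  margin <- if (!is.null(ex$linkMargin)) ex$linkMargin else max(0.05 * Lx, 2 * R)
  usable <- Lx - 2 * margin
  # net union volume a cross-link adds: its capsule minus the part engulfed
  # by each fiber. A capsule end whose tip sits on the fiber axis overlaps the
  # fiber by half the perpendicular-cylinder crossing plus its cap ball, and
  # the cap ball (being inside the fiber) cancels exactly, leaving half a
  # crossing per end.
  linkNet <- function(len, Ra, Rb) {
    pi * rho^2 * len - perpCylinderOverlap(Ra, min(rho, Ra)) / 2 -
      perpCylinderOverlap(Rb, min(rho, Rb)) / 2
  }
  if (nPairs == 0) {
    linkX <- list()
  } else if (!is.null(ex$latticeSpacing) || is.na(spec@targetVolumeFraction)) {
    # structural links at a fixed spacing along the fiber axis
    sx <- if (!is.null(ex$linkSpacing)) ex$linkSpacing else spec@meanSegmentLength
    if (is.infinite(sx)) {
      linkX <- rep(list(numeric(0)), nPairs)
    } else {
      m <- max(0L, round(usable / sx))
      linkX <- lapply(seq_len(nPairs), function(p) {
        if (m == 0) return(numeric(0))
        margin + (seq_len(m) - 0.5) / m * usable
      })
    }
  } else {
    # the link count is the fine calibration knob: each link adds a small,
    # exactly known net volume (capsule minus both junction overlaps)
    remainder <- target * V - sum(pi * radii^2 * Lx)
    perLink <- linkNet(ay, R, R)
    nLinks <- max(0L, round(remainder / perLink))
    # links along one fiber must not overlap each other
    capacity <- nPairs * max(1L, floor(usable / (2.5 * rho)))
    nLinks <- min(nLinks, capacity)
    mMax <- max(1L, ceiling(nLinks / nPairs))
    linkX <- rep(list(numeric(0)), nPairs)
    for (s in seq_len(nLinks)) {
      p <- (s - 1) %% nPairs + 1
      slot <- (s - 1) %/% nPairs
      linkX[[p]] <- c(linkX[[p]],
                      margin + (slot + 0.5) / mMax * usable)
    }
  }

  built <- buildParallelGraph(grid, radii, pairs, linkX, rho, Lx,
                              tau = spec@tortuosity)
  graph <- built$graph
  graph <- permuteGraph(graph, axis)
  if (spec@tortuosity > 1 + 1e-9) {
    # curved fibers: union volume by Monte Carlo, like the arc archetypes
    vol <- prod(dom) *
      mcVolumeFraction(graph, spec@domainSize, 150000L, spec@seed + 7919L)
    volMethod <- "monte_carlo"
  } else {
    vol <- sum(pi * radii^2 * Lx) + built$linkVolume
    volMethod <- "closed_form"
  }

  maxDist <- NA_real_
  linkDensity <- if (nPairs) max(lengths(linkX)) else 0
  if (jitter == 0 && spec@radiusCV == 0 && spec@tortuosity <= 1 + 1e-9) {
    d2d <- sqrt((ay / 2)^2 + (az / 2)^2) - R
    # links occupy thin slabs along the fiber axis; the planar maximum is
    # attained without links, or whenever link-free stretches longer than
    # 2*d2d remain between them
    gap <- if (linkDensity > 0) usable / linkDensity else Inf
    if (gap > 2 * d2d + 2 * rho) maxDist <- d2d
  }

  newGroundTruth(graph, spec@domainSize, vol / V,
                 maxSurfaceDistance = maxDist,
                 details = list(archetype = "parallel_fiber",
                                latticeSpacing = c(ay, az), nFibers = k,
                                nLinks = sum(lengths(linkX)),
                                volumeMethod = volMethod,
                                fiberAxis = axis))
}

# grid: data.frame(y, z) fiber axis positions; pairs: index pairs for links;
# linkX: per-pair x positions. Returns graph + exact net link volume.
buildParallelGraph <- function(grid, radii, pairs, linkX, rho, Lx, tau = 1) {
  k <- nrow(grid)
  nodePos <- NULL
  segA <- integer(0); segB <- integer(0)
  pls <- list()
  addNode <- function(p) {
    nodePos <<- rbind(nodePos, p)
    nrow(nodePos)
  }
  # junction x positions per fiber
  junctions <- rep(list(numeric(0)), k)
  nPairs <- if (is.null(pairs)) 0 else nrow(pairs)
  for (p in seq_len(nPairs)) {
    for (x in linkX[[p]]) {
      junctions[[pairs[p, 1]]] <- c(junctions[[pairs[p, 1]]], x)
      junctions[[pairs[p, 2]]] <- c(junctions[[pairs[p, 2]]], x)
    }
  }
  nodeAt <- new.env()
  nodeId <- function(f, x) {
    key <- paste0(f, "@", format(x, digits = 12))
    if (is.null(nodeAt[[key]])) {
      nodeAt[[key]] <- addNode(c(x, grid$y[f], grid$z[f]))
    }
    nodeAt[[key]]
  }
  for (f in seq_len(k)) {
    xs <- c(0, sort(unique(junctions[[f]])), Lx)
    ids <- vapply(xs, function(x) nodeId(f, x), integer(1))
    for (i in seq_len(length(xs) - 1)) {
      segA <- c(segA, ids[i]); segB <- c(segB, ids[i + 1])
      pls[[length(pls) + 1]] <- bentPolyline(
        c(xs[i], grid$y[f], grid$z[f]), c(xs[i + 1], grid$y[f], grid$z[f]),
        radii[f], tau, length(pls) + 1L)
    }
  }
  linkVolume <- 0
  for (p in seq_len(nPairs)) {
    fa <- pairs[p, 1]; fb <- pairs[p, 2]
    for (x in linkX[[p]]) {
      ia <- nodeId(fa, x); ib <- nodeId(fb, x)
      a <- c(x, grid$y[fa], grid$z[fa]); b <- c(x, grid$y[fb], grid$z[fb])
      len <- sqrt(sum((b - a)^2))
      segA <- c(segA, ia); segB <- c(segB, ib)
      pls[[length(pls) + 1]] <- cbind(x = c(a[1], b[1]), y = c(a[2], b[2]),
                                      z = c(a[3], b[3]), radius = rho)
      linkVolume <- linkVolume + pi * rho^2 * len -
        perpCylinderOverlap(radii[fa], min(rho, radii[fa])) / 2 -
        perpCylinderOverlap(radii[fb], min(rho, radii[fb])) / 2
    }
  }
  graph <- makeVesselGraph(nodePos, data.frame(node_a = segA, node_b = segB),
                           pls)
  list(graph = graph, linkVolume = linkVolume)
}

permuteDomain <- function(domainSize, axis, inverse = FALSE) {
  perm <- switch(axis, x = 1:3, y = c(2, 1, 3), z = c(3, 2, 1))
  domainSize[perm] # the permutations used are involutions
}

permuteGraph <- function(graph, axis) {
  if (axis == "x") return(graph)
  perm <- switch(axis, y = c(2, 1, 3), z = c(3, 2, 1))
  graph@nodes[, c("x", "y", "z")] <- graph@nodes[, c("x", "y", "z")[perm]]
  graph@polylines <- lapply(graph@polylines, function(pl) {
    out <- pl
    out[, 1:3] <- pl[, perm, drop = FALSE]
    colnames(out) <- c("x", "y", "z", "radius")
    out
  })
  graph
}

newGroundTruth <- function(graph, domainSize, volumeFraction,
                           maxSurfaceDistance = NA_real_, details = list()) {
  new("GroundTruth", graph = graph, domainSize = as.numeric(domainSize),
      analyticVolumeFraction = volumeFraction,
      analyticMeanSegmentLength = graphMeanSegmentLength(graph),
      analyticMeanDiameter = graphMeanDiameter(graph),
      analyticMaxSurfaceDistance = maxSurfaceDistance,
      details = details)
}

# ---------------------------------------------------------------------------
# random_arc: isotropically oriented curved segments grown from an expanding
# attachment pool (one dominant filament), plus a small fraction of isolated
# segments; used directly for the brain archetype and as the backbone of the
# tumor archetype.

# deterministic gentle arc between two junction positions: per-segment
# tortuosity and bulge direction derive from an index hash, so organised
# archetypes gain the mild natural waviness of real capillaries without any
# RNG state (builders stay reproducible during calibration sweeps)
bentPolyline <- function(a, b, radius, tau, idx) {
  if (tau <= 1 + 1e-9) {
    return(cbind(x = c(a[1], b[1]), y = c(a[2], b[2]), z = c(a[3], b[3]),
                 radius = radius))
  }
  h1 <- ((idx * 2654435761) %% 1000) / 1000
  h2 <- ((idx * 40503) %% 360) * pi / 180
  taui <- 1 + (tau - 1) * (0.5 + h1)
  u <- b - a
  L <- sqrt(sum(u^2))
  u <- u / L
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  w <- cos(h2) * e1 + sin(h2) * e2
  pl <- arcPolyline(a, u, L * taui, taui, w)
  colnames(pl) <- c("x", "y", "z")
  cbind(pl, radius = radius)
}

# circular-arc polyline from p0 along chord direction u with arc length arc
# and path/chord ratio tau; bulge direction w (unit, perpendicular to u)
arcPolyline <- function(p0, u, arc, tau, w, nPts = NULL) {
  chord <- arc / tau
  if (is.null(nPts)) nPts <- max(9, ceiling(arc / 3))
  if (tau <= 1 + 1e-9) {
    t <- seq(0, 1, length.out = nPts)
    return(matrix(p0, nPts, 3, byrow = TRUE) + outer(t * chord, u))
  }
  theta <- stats::uniroot(function(th) th / (2 * sin(th / 2)) - tau,
                          c(1e-8, 2 * pi - 1e-8), tol = 1e-12)$root
  Rc <- arc / theta
  mid <- p0 + (chord / 2) * u
  centre <- mid - w * (Rc * cos(theta / 2))
  e1 <- (p0 - centre) / Rc
  e2 <- u - sum(u * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  phi <- seq(0, theta, length.out = nPts)
  t(centre + Rc * (outer(e1, cos(phi)) + outer(e2, sin(phi))))
}

.insideDomain <- function(p, dom, margin = 0) {
  all(p >= margin & p <= rep(dom, each = nrow(p)) - margin)
}

.clearOfVoids <- function(pl, voids, clearance) {
  if (nrow(voids) == 0) return(TRUE)
  for (v in seq_len(nrow(voids))) {
    d2 <- (pl[, 1] - voids[v, 1])^2 + (pl[, 2] - voids[v, 2])^2 +
      (pl[, 3] - voids[v, 3])^2
    if (any(d2 < (voids[v, 4] + clearance)^2)) return(FALSE)
  }
  TRUE
}

buildArcNetwork <- function(spec, nSegments, dilate = FALSE) {
  rs <- .seededRNG(spec@seed)
  dom <- spec@domainSize
  L <- spec@meanSegmentLength
  tau <- spec@tortuosity
  R <- spec@meanRadius
  ex <- spec@extra
  isoFrac <- if (is.null(ex$isolatedFraction)) 0.05 else ex$isolatedFraction
  voids <- spec@voids
  if (nrow(voids) > 0 &&
      sum(4 / 3 * pi * voids[, 4]^3) > 0.9 * prod(dom)) {
    stop("voids cover (nearly) the entire domain; no room for vessels")
  }

  shape <- 16 # length distribution: Gamma with CV 0.25 around the set-point
  nCon <- round(nSegments * (1 - isoFrac))
  nIso <- nSegments - nCon

  nodePos <- NULL
  segA <- integer(0); segB <- integer(0)
  pls <- list()
  lens <- numeric(0); radv <- numeric(0)
  pool <- integer(0)
  addNode <- function(p) {
    nodePos <<- rbind(nodePos, p)
    nrow(nodePos)
  }
  randPoint <- function() {
    for (try in 1:200) {
      p <- c(rs$unif(1, R, dom[1] - R), rs$unif(1, R, dom[2] - R),
             rs$unif(1, R, dom[3] - R))
      if (.clearOfVoids(matrix(p, 1), voids, R)) return(p)
    }
    stop("could not place a seed point outside the voids")
  }
  randDir <- function() {
    repeat {
      v <- rs$norm(3)
      n <- sqrt(sum(v^2))
      if (n > 1e-12) return(v / n)
    }
  }
  growOne <- function(startId, isolated) {
    arc <- rs$gamma(1, shape = shape, rate = shape / L)
    # per-segment path/chord ratio scattered around the set-point: vessel
    # curvature varies from segment to segment (strongly so in tumors)
    taui <- min(1 + (tau - 1) * rs$gamma(1, shape = 2, rate = 2), 2)
    Ri <- if (spec@radiusCV > 0) {
      max(R * exp(rs$norm(1, 0, sqrt(log(1 + spec@radiusCV^2))) -
                    log(1 + spec@radiusCV^2) / 2), 0.2 * R)
    } else R
    p0 <- if (isolated) randPoint() else nodePos[startId, ]
    # best-candidate growth: among a handful of admissible directions keep
    # the one whose endpoint is farthest from the existing network, so the
    # dominant filament fills the domain instead of balling up at its seed
    best <- NULL
    bestScore <- -Inf
    tries <- 0L
    while (tries < 60L && (is.null(best) || tries < 12L)) {
      tries <- tries + 1L
      u <- randDir()
      w0 <- randDir()
      w <- w0 - sum(w0 * u) * u
      if (sqrt(sum(w^2)) < 1e-6) next
      w <- w / sqrt(sum(w^2))
      pl <- arcPolyline(p0, u, arc, taui, w)
      if (!.insideDomain(pl, dom, margin = 0)) next
      if (!.clearOfVoids(pl, voids, Ri)) next
      pe <- pl[nrow(pl), ]
      score <- min((nodePos[, 1] - pe[1])^2 + (nodePos[, 2] - pe[2])^2 +
                     (nodePos[, 3] - pe[3])^2)
      if (score > bestScore) { bestScore <- score; best <- pl }
    }
    if (is.null(best)) return(FALSE)
    pl <- best
    ia <- if (isolated) addNode(p0) else startId
    ib <- addNode(pl[nrow(pl), ])
    segA <<- c(segA, ia); segB <<- c(segB, ib)
    pls[[length(pls) + 1]] <<- cbind(pl, radius = Ri)
    lens <<- c(lens, polylineLength(pl))
    radv <<- c(radv, Ri)
    if (!isolated) pool <<- c(pool, ib)
    TRUE
  }
  seedId <- addNode(randPoint())
  pool <- seedId
  placed <- 0
  while (placed < nCon) {
    startId <- if (length(pool) == 1) pool else pool[rs$sample(length(pool), 1)]
    if (growOne(startId, isolated = FALSE)) placed <- placed + 1
  }
  placed <- 0
  while (placed < nIso) {
    if (growOne(NA, isolated = TRUE)) placed <- placed + 1
  }

  dilatedIdx <- integer(0)
  if (dilate) {
    dfrac <- if (is.null(spec@extra$dilatedFraction)) 0.1 else spec@extra$dilatedFraction
    dfac <- if (is.null(spec@extra$dilationFactor)) 2.5 else spec@extra$dilationFactor
    if (dfrac > 0) {
      short <- which(lens <= stats::median(lens))
      nd <- max(1L, round(dfrac * length(lens)))
      nd <- min(nd, length(short))
      dilatedIdx <- short[rs$sample(length(short), nd)]
      for (i in dilatedIdx) {
        pls[[i]][, "radius"] <- pls[[i]][, "radius"] * dfac
        radv[i] <- radv[i] * dfac
      }
    }
  }

  graph <- makeVesselGraph(nodePos, data.frame(node_a = segA, node_b = segB), pls)
  list(graph = graph, lengths = lens, radii = radv, dilated = dilatedIdx)
}

#' @rdname generateNetwork
#' @export
generateRandomArcNetwork <- function(spec) {
  stopifnot(spec@archetype == "random_arc")
  generateArcFamily(spec, dilate = FALSE, label = "random_arc")
}

#' @rdname generateNetwork
#' @export
generateTumorNetwork <- function(spec) {
  stopifnot(spec@archetype == "tumor")
  generateArcFamily(spec, dilate = TRUE, label = "tumor")
}

generateArcFamily <- function(spec, dilate, label) {
  dom <- spec@domainSize
  V <- prod(dom)
  target <- spec@targetVolumeFraction
  ex <- spec@extra
  if (!is.null(ex$nSegments)) {
    n <- ex$nSegments
  } else {
    f0 <- if (is.na(target)) 0.03 else target
    n <- max(10L, round(f0 * V / (pi * spec@meanRadius^2 * spec@meanSegmentLength)))
  }
  built <- buildArcNetwork(spec, n, dilate = dilate)
  mcSeed <- spec@seed + 7919L
  if (!is.na(target) && is.null(ex$nSegments)) {
    # junction overlaps make the capsule-sum an overestimate; correct the
    # segment count from a Monte-Carlo union measurement (two refinements)
    for (it in 1:4) {
      f <- mcVolumeFraction(built$graph, dom, nPoints = 150000L, seed = mcSeed)
      if (abs(f - target) / target < 0.01) break
      n <- max(10L, round(n * target / f))
      built <- buildArcNetwork(spec, n, dilate = dilate)
    }
  }
  fFinal <- mcVolumeFraction(built$graph, dom, nPoints = 200000L, seed = mcSeed + 1L)
  maxD <- probeGridMaxDistance(built$graph, dom, spec@voids)
  newGroundTruth(built$graph, dom, fFinal,
                 maxSurfaceDistance = maxD,
                 details = list(archetype = label, nSegments = n,
                                volumeMethod = "monte_carlo",
                                dilated = built$dilated,
                                maxDistanceMethod = "probe_grid"))
}

# lower-bound estimate of the maximal surface distance: minimum tube distance
# evaluated on a regular probe grid plus the void centres
probeGridMaxDistance <- function(graph, dom, voids = NULL, nProbe = 48L) {
  edges <- graphEdgeMatrix(graph)
  if (!nrow(edges)) return(NA_real_)
  gx <- seq(0, dom[1], length.out = nProbe)
  gy <- seq(0, dom[2], length.out = nProbe)
  gz <- seq(0, dom[3], length.out = min(nProbe, 24L))
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  if (!is.null(voids) && nrow(voids) > 0) {
    pts <- rbind(pts, voids[, 1:3, drop = FALSE])
  }
  max(cpp_signed_dist_to_tubes(pts, edges))
}

# ---------------------------------------------------------------------------
# planar_mesh: one (or two) high-calibre two-dimensional mesh layer(s) fed by
# thinner vessels perpendicular to the layer, emulating the mucosal surface
# mesh over crypt-parallel feeders.

#' @rdname generateNetwork
#' @export
generatePlanarMeshNetwork <- function(spec) {
  stopifnot(spec@archetype == "planar_mesh")
  ex <- spec@extra
  dom <- spec@domainSize
  V <- prod(dom)
  meshR <- if (is.null(ex$meshRadius)) spec@meanRadius else ex$meshRadius
  feedR <- if (is.null(ex$feederRadius)) 0.6 * spec@meanRadius else ex$feederRadius
  pitch <- if (is.null(ex$pitch)) spec@meanSegmentLength else ex$pitch
  z0 <- if (is.null(ex$layerZ)) 0.8 * dom[3] else ex$layerZ
  feederFraction <- if (is.null(ex$feederFraction)) 0.3 else ex$feederFraction
  feederLength <- if (is.null(ex$feederLength)) 0.85 * z0 else ex$feederLength
  nLayers <- if (is.null(ex$nLayers)) 1L else ex$nLayers
  layerGap <- if (is.null(ex$layerGap)) min(40, 0.3 * dom[3]) else ex$layerGap

  target <- spec@targetVolumeFraction
  mcSeed <- spec@seed + 104729L
  build <- function(pitch, feederFraction, feederLength) {
    buildMeshGraph(dom, pitch, z0, meshR, feedR, feederFraction, feederLength,
                   nLayers, layerGap, tau = spec@tortuosity)
  }
  g <- build(pitch, feederFraction, feederLength)
  if (!is.na(target)) {
    # coarse knob: mesh pitch, bisected so the mesh alone carries ~80% of the
    # target; feeders then top the fraction up (fine knob: their count/length)
    fm <- function(p) mcVolumeFraction(build(p, 0, feederLength), dom, 60000L, mcSeed)
    lo <- 2.5 * meshR
    hi <- min(dom[1], dom[2]) / 2
    fMesh <- fm(pitch)
    if (fMesh < 0.75 * target || fMesh > 0.95 * target) {
      if (fm(lo) < 0.8 * target) {
        pitch <- lo # even the densest admissible mesh is too sparse
      } else {
        for (it in 1:18) {
          mid <- (lo + hi) / 2
          if (fm(mid) > 0.8 * target) lo <- mid else hi <- mid
        }
        pitch <- lo
      }
      fMesh <- mcVolumeFraction(build(pitch, 0, feederLength), dom, 100000L, mcSeed)
    }
    fAll <- mcVolumeFraction(build(pitch, 1, feederLength), dom, 100000L, mcSeed)
    nNodes <- attr(build(pitch, 1, feederLength), "nMeshNodes")
    if (fAll <= target) {
      feederFraction <- 1
      g <- build(pitch, 1, feederLength)
    } else {
      perFeeder <- (fAll - fMesh) / nNodes
      feederFraction <- min(1, max(0, (target - fMesh) / (fAll - fMesh)))
      g <- build(pitch, feederFraction, feederLength)
      # fine knob: feeder length (continuous) over two refinements
      for (it in 1:2) {
        f <- mcVolumeFraction(g, dom, 100000L, mcSeed)
        if (abs(f - target) / target < 0.01) break
        scl <- (target - fMesh) / max(f - fMesh, 1e-6)
        feederLength <- min(0.95 * z0, max(5, feederLength * scl))
        g <- build(pitch, feederFraction, feederLength)
      }
    }
  }
  fFinal <- mcVolumeFraction(g, dom, 200000L, mcSeed + 1L)
  # closed-form maximum surface distance only for the degenerate single-layer
  # case confined to a thin domain (no feeders): the planar lattice value
  maxD <- NA_real_
  if ((is.null(attr(g, "nFeeders")) || attr(g, "nFeeders") == 0) &&
      dom[3] <= 2 * meshR + 1e-9 && spec@tortuosity <= 1 + 1e-9) {
    maxD <- latticeMaxSurfaceDistance(attr(g, "pitch"), meshR)
  }
  newGroundTruth(g, dom, fFinal, maxSurfaceDistance = maxD,
                 details = list(archetype = "planar_mesh",
                                pitch = attr(g, "pitch"),
                                nFeeders = attr(g, "nFeeders"),
                                feederLength = feederLength,
                                meshRadius = meshR, feederRadius = feedR,
                                volumeMethod = "monte_carlo"))
}

buildMeshGraph <- function(dom, pitch, z0, meshR, feedR, feederFraction,
                           feederLength, nLayers, layerGap, tau = 1) {
  zLayers <- z0 - (seq_len(nLayers) - 1) * layerGap
  nodePos <- NULL
  segA <- integer(0); segB <- integer(0)
  pls <- list()
  addNode <- function(p) { nodePos <<- rbind(nodePos, p); nrow(nodePos) }
  nMeshNodes <- 0L
  nFeeders <- 0L
  feederIds <- list()
  for (lz in zLayers) {
    xs <- seq(pitch / 2, dom[1] - pitch / 2 + 1e-9, by = pitch)
    ys <- seq(pitch / 2, dom[2] - pitch / 2 + 1e-9, by = pitch)
    ids <- matrix(0L, length(xs), length(ys))
    for (j in seq_along(ys)) for (i in seq_along(xs)) {
      ids[i, j] <- addNode(c(xs[i], ys[j], lz))
    }
    nMeshNodes <- nMeshNodes + length(ids)
    addSeg <- function(ia, ib, r) {
      a <- nodePos[ia, ]; b <- nodePos[ib, ]
      segA <<- c(segA, ia); segB <<- c(segB, ib)
      pls[[length(pls) + 1]] <<- bentPolyline(a, b, r, tau, length(pls) + 1L)
    }
    for (j in seq_along(ys)) for (i in seq_along(xs)) {
      if (i < length(xs)) addSeg(ids[i, j], ids[i + 1, j], meshR)
      if (j < length(ys)) addSeg(ids[i, j], ids[i, j + 1], meshR)
    }
    # feeders from an evenly strided, deterministic subset of mesh nodes
    if (feederFraction > 0 && lz == zLayers[length(zLayers)]) {
      cand <- as.vector(ids)
      nF <- round(feederFraction * length(cand))
      if (nF > 0) {
        pick <- if (nF >= length(cand)) cand else
          cand[unique(round(seq(1, length(cand), length.out = nF)))]
        for (id in pick) {
          p <- nodePos[id, ]
          zBot <- max(feedR, p[3] - feederLength)
          ib <- addNode(c(p[1], p[2], zBot))
          segA <- c(segA, id); segB <- c(segB, ib)
          pls[[length(pls) + 1]] <- cbind(x = c(p[1], p[1]), y = c(p[2], p[2]),
                                          z = c(p[3], zBot), radius = feedR)
          nFeeders <- nFeeders + 1L
        }
      }
    }
  }
  if (nLayers > 1) {
    # connect consecutive layers with short vertical bridges at every 4th node
    # (indices rely on identical per-layer grids)
    perLayer <- nMeshNodes / nLayers
    for (l in seq_len(nLayers - 1)) {
      for (i in seq(1, perLayer, by = 4)) {
        ia <- (l - 1) * perLayer + i
        ib <- l * perLayer + i
        a <- nodePos[ia, ]; b <- nodePos[ib, ]
        segA <- c(segA, ia); segB <- c(segB, ib)
        pls[[length(pls) + 1]] <- cbind(x = c(a[1], b[1]), y = c(a[2], b[2]),
                                        z = c(a[3], b[3]), radius = feedR)
      }
    }
  }
  g <- makeVesselGraph(nodePos, data.frame(node_a = segA, node_b = segB), pls)
  attr(g, "pitch") <- pitch
  attr(g, "nMeshNodes") <- nMeshNodes
  attr(g, "nFeeders") <- nFeeders
  g
}

#' Calibrate a generator knob to a ground-truth mean segment length
#'
#' Greedy grid search over a single structural knob (cross-link spacing for
#' the parallel-fiber archetype, mesh pitch for the planar mesh) so that the
#' generated network's exact mean inter-bifurcation segment length matches a
#' set-point. Uses the generator's own graph bookkeeping, no rasterization.
#'
#' @param spec a [NetworkSpec] (`parallel_fiber` or `planar_mesh`).
#' @param targetLength um.
#' @param knobRange numeric(2), search interval for the knob (um); default
#'   `targetLength * c(0.3, 4)`.
#' @param nGrid number of candidate values.
#' @return the input spec with the calibrated knob set in `extra`.
#' @export
calibrateSegmentLength <- function(spec, targetLength,
                                   knobRange = targetLength * c(0.3, 4),
                                   nGrid = 40L) {
  knob <- switch(spec@archetype, parallel_fiber = "linkSpacing",
                 planar_mesh = "pitch",
                 stop("length calibration supports parallel_fiber and planar_mesh"))
  # objective: mean length of rim-filtered segments — the quantity the
  # tracing statistics report (cut-off segments are excluded there too)
  interiorMean <- function(s) {
    gt <- generateNetwork(s)
    tab <- measureSegments(gt@graph)
    tab <- removeBoundarySegments(tab, c(0, 0, 0), s@domainSize, rep(2, 3))
    if (!nrow(tab)) return(NA_real_)
    mean(tab$length)
  }
  tryKnob <- function(value, marginValue = NULL) {
    s <- spec
    s@extra[[knob]] <- value
    if (!is.null(marginValue)) s@extra$linkMargin <- marginValue
    s@targetVolumeFraction <- NA_real_
    abs(interiorMean(s) - targetLength)
  }
  cand <- seq(knobRange[1], knobRange[2], length.out = nGrid)
  errs <- vapply(cand, tryKnob, numeric(1))
  best <- cand[which.min(errs)]
  cand2 <- seq(max(knobRange[1], best * 0.8), min(knobRange[2], best * 1.2),
               length.out = 15L)
  errs2 <- vapply(cand2, tryKnob, numeric(1))
  spec@extra[[knob]] <- cand2[which.min(errs2)]
  spec@targetVolumeFraction <- NA_real_
  if (spec@archetype == "parallel_fiber") {
    # continuous refinement: the rim margin shifts fiber piece lengths
    R <- spec@meanRadius
    mcand <- seq(2 * R, 0.22 * spec@domainSize[1], length.out = 15L)
    merrs <- vapply(mcand, function(m) tryKnob(spec@extra[[knob]], m), numeric(1))
    spec@extra$linkMargin <- mcand[which.min(merrs)]
  }
  spec
}
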