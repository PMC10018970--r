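#' Skeletonize a binary vessel mask
#'
#' Topology-preserving curve thinning to a one-voxel-wide, 26-connected
#' medial skeleton: simple points (whose removal does not change the number
#' of foreground or background components in the 26/6 connectivity pairing)
#' are deleted sequentially in six directional subiterations until stable;
#' curve endpoints are retained. The component count of the mask is
#' preserved.
#'
#' @param mask binary [RasterVolume] or [VesselMask].
#' @return a binary [RasterVolume] holding the skeleton.
#' @export
skeletonizeMask <- function(mask) {
  stopifnot(is(mask, "RasterVolume"))
  v <- mask@voxels
  if (!all(v %in% c(0, 1))) stop("mask must be binary")
  d <- dim(v)
  sk <- cpp_skeletonize_3d(as.logical(v), d)
  rasterVolume(array(as.numeric(sk), d), mask@spacing, mask@origin)
}

#' Interior radius field of a vessel mask
#'
#' Euclidean distance (um, anisotropic) from each foreground voxel centre to
#' the nearest background voxel: the local tube radius when evaluated on the
#' centerline.
#'
#' @param mask binary [RasterVolume].
#' @return numeric 3D array of radii (0 outside the mask).
#' @export
interiorRadiusField <- function(mask) {
  v <- mask@voxels
  d <- dim(v)
  edt <- cpp_edt_3d(!as.logical(v), d, mask@spacing)
  r <- array(edt, d)
  r[v == 0] <- 0
  r
}

#' Build a vessel centerline graph from a skeleton
#'
#' Nodes are skeleton voxels with a number of 26-neighbours different from 2
#' (endpoints and bifurcations); clusters of mutually adjacent branch voxels
#' are collapsed to their centroid so one anatomical bifurcation yields one
#' node. Segments are the maximal skeleton paths between nodes; per-point
#' radii are read from the interior distance field. Terminal spurs shorter
#' than `pruneFactor` times their local radius (thinning artifacts) are
#' removed before the final graph is assembled.
#'
#' @param skeleton binary [RasterVolume] (from [skeletonizeMask()]).
#' @param radiusField numeric array from [interiorRadiusField()], or `NULL`
#'   to fall back to half the in-plane spacing everywhere.
#' @param pruneFactor spur-pruning threshold as a multiple of the local
#'   radius (default 2; 0 disables pruning).
#' @return a [VesselGraph] with positions in um.
#' @export
buildVesselGraph <- function(skeleton, radiusField = NULL, pruneFactor = 2) {
  stopifnot(is(skeleton, "RasterVolume"))
  v <- skeleton@voxels
  d <- dim(v)
  spacing <- skeleton@spacing
  origin <- skeleton@origin
  minR <- 0.5 * min(spacing)
  radiusAt <- function(lin) {
    if (is.null(radiusField)) return(rep(minR, length(lin)))
    pmax(radiusField[lin], minR)
  }

  g <- skeletonGraphRaw(v, d, spacing, origin, radiusAt)
  if (pruneFactor > 0 && nrow(g$segments)) {
    keepVox <- pruneSpurVoxels(g, pruneFactor)
    if (!is.null(keepVox)) {
      v2 <- array(0, d)
      v2[keepVox] <- 1
      g <- skeletonGraphRaw(v2, d, spacing, origin, radiusAt)
    }
  }
  makeVesselGraph(g$nodePos, g$segments, g$polylines)
}

# core skeleton-to-graph extraction; returns plain lists for reuse by pruning
skeletonGraphRaw <- function(v, d, spacing, origin, radiusAt) {
  minRadius <- 0.5 * min(spacing)
  lin <- which(v != 0)
  n <- length(lin)
  empty <- list(nodePos = matrix(numeric(0), 0, 3),
                segments = data.frame(node_a = integer(0), node_b = integer(0)),
                polylines = list(), segVox = list())
  if (n == 0) return(empty)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ix <- ((lin - 1) %% nx)
  iy <- ((lin - 1) %/% nx) %% ny
  iz <- (lin - 1) %/% (nx * ny)
  id <- integer(prod(d))
  id[lin] <- seq_len(n)

  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  eA <- integer(0); eB <- integer(0); eStep <- integer(0) # 1, 2, 3 = |offset|^2
  for (o in seq_len(nrow(off))) {
    jx <- ix + off[o, 1]; jy <- iy + off[o, 2]; jz <- iz + off[o, 3]
    ok <- jx >= 0 & jx < nx & jy >= 0 & jy < ny & jz >= 0 & jz < nz
    nb <- integer(n)
    nb[ok] <- id[1 + jx[ok] + nx * (jy[ok] + ny * jz[ok])]
    hit <- which(nb > 0 & nb > seq_len(n)) # undirected, once
    if (length(hit)) {
      eA <- c(eA, hit); eB <- c(eB, nb[hit])
      eStep <- c(eStep, rep.int(sum(abs(off[o, ])), length(hit)))
    }
  }
  adj <- vector("list", n)
  for (k in seq_along(eA)) {
    adj[[eA[k]]] <- c(adj[[eA[k]]], eB[k])
    adj[[eB[k]]] <- c(adj[[eB[k]]], eA[k])
  }
  # triangle reduction: a staircase in a one-voxel-wide chain forms 3-cliques
  # whose long diagonal edge would masquerade as a bifurcation; drop any edge
  # that is bypassed by a strictly shorter two-step path
  drop <- logical(length(eA))
  for (k in order(eStep, decreasing = TRUE)) {
    if (eStep[k] == 1L) break
    u <- eA[k]; w <- eB[k]
    common <- intersect(adj[[u]], adj[[w]])
    for (v in common) {
      su <- sum(abs(c(ix[u] - ix[v], iy[u] - iy[v], iz[u] - iz[v])))
      sw <- sum(abs(c(ix[w] - ix[v], iy[w] - iy[v], iz[w] - iz[v])))
      if (max(su, sw) < eStep[k]) {
        drop[k] <- TRUE
        adj[[u]] <- setdiff(adj[[u]], w)
        adj[[w]] <- setdiff(adj[[w]], u)
        break
      }
    }
  }
  deg <- lengths(adj)

  isNode <- deg != 2L
  # collapse adjacent node voxels into clusters
  clusterOf <- integer(n)
  nClusters <- 0L
  for (i in which(isNode)) {
    if (clusterOf[i] != 0L) next
    nClusters <- nClusters + 1L
    stack <- i
    clusterOf[i] <- nClusters
    while (length(stack)) {
      c0 <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (w in adj[[c0]]) {
        if (isNode[w] && clusterOf[w] == 0L) {
          clusterOf[w] <- nClusters
          stack <- c(stack, w)
        }
      }
    }
  }

  posUm <- cbind(origin[1] + ix * spacing[1], origin[2] + iy * spacing[2],
                 origin[3] + iz * spacing[3])
  nodePos <- matrix(0, nClusters, 3)
  for (cl in seq_len(nClusters)) {
    member <- which(clusterOf == cl)
    nodePos[cl, ] <- colMeans(posUm[member, , drop = FALSE])
  }

  segsA <- integer(0); segsB <- integer(0)
  polylines <- list()
  segVox <- list()
  visited <- logical(n)          # chain voxels already swallowed
  usedStart <- new.env()         # directed starts already walked

  addSegment <- function(clA, clB, chain, rEmpty = minRadius) {
    vox <- lin[chain]
    pts <- posUm[chain, , drop = FALSE]
    pl <- rbind(c(nodePos[clA, ], NA), cbind(pts, radiusAt(vox)),
                c(nodePos[clB, ], NA))
    pl[1, 4] <- if (length(chain)) pl[2, 4] else rEmpty
    pl[nrow(pl), 4] <- if (length(chain)) pl[nrow(pl) - 1, 4] else rEmpty
    colnames(pl) <- c("x", "y", "z", "radius")
    segsA <<- c(segsA, clA); segsB <<- c(segsB, clB)
    polylines[[length(polylines) + 1]] <<- pl
    segVox[[length(segVox) + 1]] <<- vox # linear voxel indices of the chain
  }

  for (i in which(isNode)) {
    for (w in adj[[i]]) {
      if (isNode[w]) {
        if (clusterOf[w] == clusterOf[i]) next # internal cluster edge
        key <- paste(min(i, w), max(i, w))
        if (!is.null(usedStart[[key]])) next
        usedStart[[key]] <- TRUE
        addSegment(clusterOf[i], clusterOf[w], integer(0),
                   rEmpty = mean(radiusAt(lin[c(i, w)])))
      } else {
        if (visited[w]) next
        chain <- integer(0)
        prev <- i; cur <- w
        repeat {
          chain <- c(chain, cur)
          visited[cur] <- TRUE
          nxt <- adj[[cur]][adj[[cur]] != prev]
          if (length(nxt) == 0) { # dangling chain end (no terminal node voxel)
            nxt <- NA_integer_
            break
          }
          nxt <- nxt[1]
          if (isNode[nxt]) break
          prev <- cur; cur <- nxt
        }
        if (is.na(nxt)) {
          # chain ends mid-air (should not happen: deg-1 voxels are nodes)
          next
        }
        addSegment(clusterOf[i], clusterOf[nxt], chain)
      }
    }
  }

  # pure cycles: components of degree-2 voxels never reached above
  leftover <- which(!visited & !isNode)
  while (length(leftover)) {
    start <- leftover[1]
    nClusters <- nClusters + 1L
    nodePos <- rbind(nodePos, posUm[start, ])
    chain <- integer(0)
    prev <- start; cur <- adj[[start]][1]
    visited[start] <- TRUE
    while (cur != start) {
      chain <- c(chain, cur)
      visited[cur] <- TRUE
      nxt <- adj[[cur]][adj[[cur]] != prev][1]
      prev <- cur; cur <- nxt
    }
    addSegment(nClusters, nClusters, chain)
    leftover <- which(!visited & !isNode)
  }

  list(nodePos = nodePos,
       segments = data.frame(node_a = segsA, node_b = segsB),
       polylines = polylines, segVox = segVox,
       clusterVox = split(lin[isNode], clusterOf[isNode]))
}

# voxels (linear indices) to keep after removing short terminal spurs
pruneSpurVoxels <- function(g, pruneFactor) {
  ns <- nrow(g$segments)
  degCl <- tabulate(c(g$segments$node_a, g$segments$node_b))
  drop <- logical(ns)
  for (s in seq_len(ns)) {
    a <- g$segments$node_a[s]; b <- g$segments$node_b[s]
    if (a == b) next
    terminal <- (degCl[a] == 1L) || (degCl[b] == 1L)
    if (!terminal) next
    pl <- g$polylines[[s]]
    len <- polylineLength(pl)
    if (len < pruneFactor * mean(pl[, 4])) drop[s] <- TRUE
  }
  if (!any(drop)) return(NULL)
  keep <- unlist(g$segVox[!drop], use.names = FALSE)
  clusters <- g$clusterVox
  # keep node clusters that still carry a surviving segment
  usedCl <- unique(c(g$segments$node_a[!drop], g$segments$node_b[!drop]))
  keep <- c(keep, unlist(clusters[names(clusters) %in% as.character(usedCl)],
                         use.names = FALSE))
  unique(keep)
}

#' Per-segment morphometrics
#'
#' One row per segment: arc length (um, consecutive Euclidean steps),
#' mean diameter (2 x mean per-point radius, um), straightness (chord/arc,
#' in (0,1]; 0 with `loop = TRUE` for closed segments), XY-plane orientation
#' of the chord in degrees mapped to (-90, 90] (`NA` for segments
#' perpendicular to the XY plane), and the endpoint coordinates used by
#' [removeBoundarySegments()].
#'
#' @param graph a [VesselGraph].
#' @return a `data.frame` segment table.
#' @export
measureSegments <- function(graph) {
  segs <- graph@segments
  ns <- nrow(segs)
  out <- data.frame(segment_id = segs$segment_id,
                    filament_id = segs$filament_id,
                    length = numeric(ns), mean_diameter = numeric(ns),
                    straightness = numeric(ns), orientation_xy = numeric(ns),
                    loop = logical(ns),
                    xa = numeric(ns), ya = numeric(ns), za = numeric(ns),
                    xb = numeric(ns), yb = numeric(ns), zb = numeric(ns))
  for (i in seq_len(ns)) {
    pl <- graph@polylines[[i]]
    m <- measureSegment(pl)
    out$length[i] <- m$length
    out$mean_diameter[i] <- m$mean_diameter
    out$straightness[i] <- m$straightness
    out$orientation_xy[i] <- m$orientation_xy
    out$loop[i] <- m$loop
    out[i, c("xa", "ya", "za")] <- pl[1, 1:3]
    out[i, c("xb", "yb", "zb")] <- pl[nrow(pl), 1:3]
  }
  out
}

#' @rdname measureSegments
#' @param polyline numeric matrix with columns x, y, z, radius (um).
#' @export
measureSegment <- function(polyline) {
  stopifnot(nrow(polyline) >= 2)
  len <- polylineLength(polyline)
  chord <- polyline[nrow(polyline), 1:3] - polyline[1, 1:3]
  chordLen <- sqrt(sum(chord^2))
  loop <- chordLen < 1e-9
  straight <- if (loop) 0 else chordLen / len
  dxy <- unname(chord[1:2])
  ori <- if (sqrt(sum(dxy^2)) < 1e-9) {
    NA_real_
  } else {
    a <- atan2(dxy[2], dxy[1]) * 180 / pi
    a <- a %% 180
    if (a > 90) a - 180 else a
  }
  list(length = len, mean_diameter = 2 * mean(polyline[, 4]),
       straightness = straight, orientation_xy = ori, loop = loop)
}

#' Remove segments cut off at the field-of-view rim
#'
#' Imaging restricts the analysable volume to a small field of view, so
#' vessels are necessarily cut at its rim; those partial segments would bias
#' the morphometric statistics and are removed: any segment with an endpoint
#' within `marginVoxels` voxels of a volume face is dropped.
#'
#' @param table a segment table from [measureSegments()].
#' @param lower,upper numeric(3), physical bounds of the volume in um
#'   (voxel-centre convention: `lower = origin`,
#'   `upper = origin + (dim - 1) * spacing`).
#' @param spacing numeric(3) voxel pitch in um.
#' @param marginVoxels rim width in voxels (default 1).
#' @return the filtered segment table.
#' @export
removeBoundarySegments <- function(table, lower, upper, spacing,
                                   marginVoxels = 1) {
  m <- marginVoxels * spacing
  nearFace <- function(x, y, z) {
    (x <= lower[1] + m[1]) | (x >= upper[1] - m[1]) |
    (y <= lower[2] + m[2]) | (y >= upper[2] - m[2]) |
    (z <= lower[3] + m[3]) | (z >= upper[3] - m[3])
  }
  bad <- nearFace(table$xa, table$ya, table$za) |
         nearFace(table$xb, table$yb, table$zb)
  table[!bad, , drop = FALSE]
}

#' Centre an axial orientation distribution on its mode
#'
#' Orientation angles of vessel chords in the XY plane are axial (period
#' 180 degrees). The mode of their histogram (default 5-degree bins) is
#' shifted to 0 so organs with different absolute preferred directions
#' become comparable; output angles lie in (-90, 90].
#'
#' @param angles numeric vector of degrees in (-90, 90]; `NA`s dropped.
#' @param binWidth histogram bin width in degrees.
#' @return list with `angles` (shifted), `mode` (degrees shifted to 0),
#'   `histogram` (data.frame of bin centres and relative frequencies).
#' @export
centerOrientationDistribution <- function(angles, binWidth = 5) {
  angles <- angles[!is.na(angles)]
  stopifnot(length(angles) >= 1)
  nb <- round(180 / binWidth)
  binOf <- function(a) pmin(pmax(ceiling((a + 90) / binWidth), 1L), nb)
  counts <- tabulate(binOf(angles), nbins = nb)
  mid <- -90 + (seq_len(nb) - 0.5) * binWidth
  # refine the mode inside the modal bin so identical angles map exactly to 0
  modalBin <- which.max(counts)
  mode <- mean(angles[binOf(angles) == modalBin])
  shifted <- ((angles - mode + 90) %% 180) - 90
  shifted[shifted <= -90 + 1e-12] <- 90
  counts2 <- tabulate(binOf(shifted), nbins = nb)
  list(angles = shifted, mode = mode,
       histogram = data.frame(bin_center = mid,
                              frequency = counts2 / sum(counts2)))
}

#' Circular standard deviation of axial angles
#'
#' Standard deviation for 180-degree-periodic (axial) data via the
#' double-angle transform, in degrees.
#'
#' @param angles degrees; `NA`s dropped.
#' @return circular SD in degrees.
#' @export
axialCircularSD <- function(angles) {
  a <- angles[!is.na(angles)] * pi / 180 * 2
  R <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  R <- min(max(R, 1e-12), 1)
  sqrt(-2 * log(R)) / 2 * 180 / pi
}

#' Trace a vessel mask into a measured segment table
#'
#' Convenience wrapper: interior radius field, skeletonization, graph
#' extraction, morphometrics, and (optionally) rim-segment removal.
#'
#' @param mask a [VesselMask] or binary [RasterVolume].
#' @param pruneFactor spur-pruning factor, see [buildVesselGraph()].
#' @param removeBoundary drop segments ending at the volume rim.
#' @param marginVoxels rim width in voxels for the cut-off filter. The
#'   default 1 catches segments ending on a face; thinning retracts the free
#'   end of a cut tube inwards by about one tube radius, so phantom studies
#'   that compare against ground truth use a margin of the order of the
#'   vessel radius.
#' @return list with `graph` ([VesselGraph]) and `table` (segment table).
#' @export
traceMask <- function(mask, pruneFactor = 2, removeBoundary = TRUE,
                      marginVoxels = 1) {
  rf <- interiorRadiusField(mask)
  sk <- skeletonizeMask(mask)
  graph <- buildVesselGraph(sk, rf, pruneFactor)
  tab <- measureSegments(graph)
  if (removeBoundary && nrow(tab)) {
    d <- dim(mask@voxels)
    lower <- mask@origin
    upper <- mask@origin + (d - 1) * mask@spacing
    tab <- removeBoundarySegments(tab, lower, upper, mask@spacing, marginVoxels)
  }
  list(graph = graph, table = tab)
}
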