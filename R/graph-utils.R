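#' Polyline arc length
#'
#' Sum of consecutive Euclidean steps of a polyline, in um.
#'
#' @param pl numeric matrix with columns x, y, z (further columns ignored).
#' @return arc length in um.
#' @export
polylineLength <- function(pl) {
  d <- diff(pl[, 1:3, drop = FALSE])
  sum(sqrt(rowSums(d^2)))
}

# Assemble a VesselGraph from node positions and polylines, computing degrees
# and filament ids (connected components of the node/segment graph).
makeVesselGraph <- function(nodePos, segs, polylines) {
  nodePos <- as.matrix(nodePos)
  nn <- nrow(nodePos)
  nodes <- data.frame(id = seq_len(nn),
                      x = if (nn) nodePos[, 1] else numeric(0),
                      y = if (nn) nodePos[, 2] else numeric(0),
                      z = if (nn) nodePos[, 3] else numeric(0),
                      degree = integer(nn))
  segs <- as.data.frame(segs)
  ns <- nrow(segs)
  if (ns) {
    tab <- table(factor(c(segs$node_a, segs$node_b), levels = nodes$id))
    nodes$degree <- as.integer(tab)
    g <- igraph::graph_from_data_frame(
      data.frame(from = segs$node_a, to = segs$node_b),
      directed = FALSE,
      vertices = data.frame(name = nodes$id))
    comp <- igraph::components(g)$membership
    segs$filament_id <- as.integer(comp[as.character(segs$node_a)])
    segs$segment_id <- seq_len(ns)
  } else {
    segs <- data.frame(segment_id = integer(0), node_a = integer(0),
                       node_b = integer(0), filament_id = integer(0))
  }
  new("VesselGraph", nodes = nodes,
      segments = segs[, c("segment_id", "node_a", "node_b", "filament_id")],
      polylines = polylines)
}

# All polyline edges of a graph as a matrix x1,y1,z1,x2,y2,z2,r (per-edge
# radius = mean of its two endpoint radii).
graphEdgeMatrix <- function(graph) {
  pls <- graph@polylines
  if (!length(pls)) return(matrix(numeric(0), 0, 7))
  out <- lapply(pls, function(pl) {
    n <- nrow(pl)
    cbind(pl[-n, 1:3, drop = FALSE], pl[-1, 1:3, drop = FALSE],
          (pl[-n, 4] + pl[-1, 4]) / 2)
  })
  m <- do.call(rbind, out)
  colnames(m) <- c("x1", "y1", "z1", "x2", "y2", "z2", "r")
  m
}

# Exact per-graph bookkeeping used by the generators' GroundTruth.
graphMeanSegmentLength <- function(graph) {
  if (!length(graph@polylines)) return(NA_real_)
  mean(vapply(graph@polylines, polylineLength, numeric(1)))
}

graphMeanDiameter <- function(graph) {
  if (!length(graph@polylines)) return(NA_real_)
  mean(vapply(graph@polylines, function(pl) 2 * mean(pl[, 4]), numeric(1)))
}

#' Monte-Carlo volume fraction of a tube network
#'
#' Estimates the fraction of a box domain occupied by the union of the
#' capsule tubes of a [VesselGraph] by uniform point sampling. Used by the
#' generators when junction overlaps make a closed-form union volume
#' impractical; deterministic given `seed`.
#'
#' @param graph a [VesselGraph].
#' @param domainSize numeric(3) box extents in um (box corner at the origin).
#' @param nPoints number of sample points.
#' @param seed integer seed.
#' @return estimated volume fraction.
#' @export
mcVolumeFraction <- function(graph, domainSize, nPoints = 100000L, seed = 1L) {
  edges <- graphEdgeMatrix(graph)
  if (!nrow(edges)) return(0)
  rs <- .seededRNG(seed)
  pts <- cbind(rs$unif(nPoints) * domainSize[1],
               rs$unif(nPoints) * domainSize[2],
               rs$unif(nPoints) * domainSize[3])
  d <- cpp_signed_dist_to_tubes(pts, edges)
  mean(d <= 0)
}

# Local RNG stream: all generator randomness flows from one explicit seed,
# without touching the global .Random.seed.
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(unif = draw(stats::runif), norm = draw(stats::rnorm),
       gamma = draw(stats::rgamma), pois = draw(stats::rpois),
       sample = draw(base::sample))
}
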