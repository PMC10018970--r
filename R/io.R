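#' Read a multi-page TIFF stack as a RasterVolume
#'
#' Pages become z slices. Voxel spacing must be supplied explicitly (CLI or
#' config) or through a sidecar JSON (`<path>.json` with a `spacing` field);
#' spacing embedded in image metadata is treated as advisory only, since
#' stack parameters are routinely mis-read from acquisition metadata and
#' corrected by hand. An explicit `spacing` argument always wins.
#'
#' @param path TIFF file.
#' @param spacing numeric(3) um, or `NULL` to fall back to the sidecar.
#' @return a [RasterVolume].
#' @export
readVolume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("not a readable TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("truncated or inconsistent stack: page sizes differ in ", path)
  }
  if (is.null(spacing)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::fromJSON(sidecar)
      spacing <- as.numeric(meta$spacing)
    }
  }
  if (is.null(spacing) || length(spacing) != 3 || any(!is.finite(spacing))) {
    stop("voxel spacing absent for ", path,
         ": give spacing= (um) or provide a sidecar ", path, ".json")
  }
  # readTIFF returns row-major matrices (rows = y); store as [x, y, z]
  vox <- array(0, c(dims[2, 1], dims[1, 1], length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- t(pages[[k]])
  rasterVolume(vox, spacing)
}

#' Write a RasterVolume as a multi-page TIFF with a sidecar JSON
#'
#' Values are scaled to the requested bit depth (binary masks become 0/255
#' in 8-bit mode); the scale, spacing and origin are recorded in
#' `<path>.json` so the volume round-trips.
#'
#' @param volume a [RasterVolume].
#' @param path output TIFF path.
#' @param bitsPerSample 8 or 16.
#' @param maxValue value mapped to full scale; default the volume maximum
#'   (255 for 8-bit data and binary masks stay voxel-exact).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path, bitsPerSample = 8L, maxValue = NULL) {
  v <- volume@voxels
  if (is.null(maxValue)) {
    mx <- max(v)
    maxValue <- if (mx <= 1) 1 else if (mx <= 255 && bitsPerSample == 8) 255 else mx
  }
  scaled <- pmin(pmax(v / maxValue, 0), 1)
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(scaled[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitsPerSample))
  jsonlite::write_json(
    list(spacing = volume@spacing, origin = volume@origin,
         maxValue = maxValue, bitsPerSample = bitsPerSample),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a VesselGraph as SWC
#'
#' One tree per filament (connected component). SWC is a tree format, so a
#' breadth-first spanning tree over the polyline points is written and each
#' cycle-closing connection duplicates its terminal sample point. Radii are
#' in um; the structure identifier is 0 (undefined / vessel).
#'
#' @param graph a [VesselGraph].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSWC <- function(graph, path) {
  lines <- c("# SWC vessel centerline export",
             "# columns: id type x y z radius parent")
  counter <- 0L
  emit <- function(p, r, parent) {
    counter <<- counter + 1L
    lines[[length(lines) + 1L]] <<- sprintf("%d 0 %.8g %.8g %.8g %.8g %d",
                                            counter, p[1], p[2], p[3], r, parent)
    counter
  }
  segs <- graph@segments
  swcId <- integer(nrow(graph@nodes)) # SWC sample id of each graph node
  for (fid in unique(segs$filament_id)) {
    segIdx <- which(segs$filament_id == fid)
    pending <- rep(TRUE, length(segIdx))
    root <- segs$node_a[segIdx[1]]
    pl1 <- graph@polylines[[segIdx[1]]]
    swcId[root] <- emit(pl1[1, 1:3], pl1[1, 4], -1L)
    repeat {
      nxt <- which(pending & (swcId[segs$node_a[segIdx]] > 0L |
                              swcId[segs$node_b[segIdx]] > 0L))
      if (!length(nxt)) break
      s <- segIdx[nxt[1]]
      pending[nxt[1]] <- FALSE
      pl <- graph@polylines[[s]]
      u <- segs$node_a[s]; v <- segs$node_b[s]
      if (swcId[u] == 0L) { # traverse v -> u
        pl <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
        tmp <- u; u <- v; v <- tmp
      }
      prev <- swcId[u]
      np <- nrow(pl)
      if (np > 2) {
        for (p in 2:(np - 1)) prev <- emit(pl[p, 1:3], pl[p, 4], prev)
      }
      # terminal point: fresh sample for an unseen node, duplicate for a cycle
      last <- emit(pl[np, 1:3], pl[np, 4], prev)
      if (swcId[v] == 0L) swcId[v] <- last
    }
  }
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read an SWC file as a VesselGraph
#'
#' Inverse of [writeSWC()] for tree-structured files: branch points and
#' endpoints become nodes, runs of degree-2 samples become segment
#' polylines.
#'
#' @param path SWC file.
#' @return a [VesselGraph].
#' @export
readSWC <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "radius",
                                         "parent"))
  n <- nrow(tab)
  rowOf <- integer(max(tab$id))
  rowOf[tab$id] <- seq_len(n)
  deg <- integer(n)
  for (i in seq_len(n)) {
    if (tab$parent[i] > 0) {
      deg[i] <- deg[i] + 1L
      deg[rowOf[tab$parent[i]]] <- deg[rowOf[tab$parent[i]]] + 1L
    }
  }
  children <- split(seq_len(n)[tab$parent > 0], rowOf[tab$parent[tab$parent > 0]])
  isNode <- deg != 2L
  nodePos <- NULL
  nodeIdOf <- integer(n)
  addNode <- function(i) {
    nodePos <<- rbind(nodePos, as.numeric(tab[i, c("x", "y", "z")]))
    nodeIdOf[i] <<- nrow(nodePos)
    nrow(nodePos)
  }
  for (i in which(isNode)) addNode(i)
  segA <- integer(0); segB <- integer(0); pls <- list()
  for (i in which(isNode)) {
    for (ch in children[[as.character(i)]]) {
      run <- i
      cur <- ch
      while (!isNode[cur]) {
        run <- c(run, cur)
        cur <- children[[as.character(cur)]][1]
      }
      run <- c(run, cur)
      segA <- c(segA, nodeIdOf[i]); segB <- c(segB, nodeIdOf[cur])
      pls[[length(pls) + 1]] <- as.matrix(
        stats::setNames(tab[run, c("x", "y", "z", "radius")],
                        c("x", "y", "z", "radius")))
    }
  }
  makeVesselGraph(nodePos, data.frame(node_a = segA, node_b = segB), pls)
}

#' Write a VesselGraph as GraphML
#'
#' Nodes carry position and degree; edges carry segment id, filament id,
#' arc length and mean radius.
#'
#' @param graph a [VesselGraph].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(graph, path) {
  segs <- graph@segments
  lens <- vapply(graph@polylines, polylineLength, numeric(1))
  rads <- vapply(graph@polylines, function(pl) mean(pl[, 4]), numeric(1))
  g <- igraph::graph_from_data_frame(
    data.frame(from = segs$node_a, to = segs$node_b,
               segment_id = segs$segment_id, filament_id = segs$filament_id,
               length = lens, mean_radius = rads),
    directed = FALSE,
    vertices = data.frame(name = graph@nodes$id, x = graph@nodes$x,
                          y = graph@nodes$y, z = graph@nodes$z,
                          degree = graph@nodes$degree))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write / read a segment table as CSV
#'
#' @param table segment table ([measureSegments()]).
#' @param path CSV path.
#' @return `path` / the table.
#' @export
writeSegmentTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSegmentTable
#' @export
readSegmentTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a filament-tracing spreadsheet export (Imaris dialect)
#'
#' Maps the "Dendrite Length", "Dendrite Mean Diameter" and "Dendrite
#' Straightness" columns of a tracing export to the internal segment-table
#' fields.
#'
#' @param path CSV file.
#' @return data.frame with `length`, `mean_diameter`, `straightness` (plus
#'   any passenger columns, untouched).
#' @export
readImarisTable <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- c("Dendrite Length" = "length",
           "Dendrite Mean Diameter" = "mean_diameter",
           "Dendrite Straightness" = "straightness")
  for (from in names(map)) {
    hit <- which(trimws(names(raw)) == from)
    if (length(hit)) names(raw)[hit[1]] <- map[[from]]
  }
  missing <- setdiff(unname(map), names(raw))
  if (length(missing)) {
    stop("tracing export lacks required column(s): ", paste(missing, collapse = ", "))
  }
  raw
}

#' Pipeline configuration
#'
#' All tunables of the end-to-end pipeline with their defaults; round-trips
#' losslessly through JSON ([writeConfig()], [readConfig()]).
#'
#' @param spacing voxel pitch um (x, y, z).
#' @param segmentation see [segmentationParams()].
#' @param pruneFactor spur-pruning factor ([buildVesselGraph()]).
#' @param rimMarginVoxels rim width of the cut-off segment filter
#'   ([removeBoundarySegments()]).
#' @param distanceBinWidth um ([distanceHistogram()]).
#' @param quantizedDistances logical ([distanceTransform()]).
#' @param kdeLevels KDE mass levels.
#' @param kdeGridSize KDE grid.
#' @param seed integer.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(spacing = c(0.5, 0.5, 1),
                           segmentation = segmentationParams(),
                           pruneFactor = 2,
                           rimMarginVoxels = 1,
                           distanceBinWidth = 2,
                           quantizedDistances = FALSE,
                           kdeLevels = c(0.5, 0.9),
                           kdeGridSize = 256L,
                           seed = 1L) {
  structure(list(spacing = spacing, segmentation = segmentation,
                 pruneFactor = pruneFactor,
                 rimMarginVoxels = rimMarginVoxels,
                 distanceBinWidth = distanceBinWidth,
                 quantizedDistances = quantizedDistances,
                 kdeLevels = kdeLevels, kdeGridSize = kdeGridSize,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `pipelineConfig`.
#' @param path JSON path.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readConfig <- function(path) {
  raw <- jsonlite::fromJSON(path)
  cfg <- pipelineConfig()
  for (nm in names(raw)) {
    if (nm == "segmentation") {
      for (nm2 in names(raw$segmentation)) cfg$segmentation[[nm2]] <- raw$segmentation[[nm2]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
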