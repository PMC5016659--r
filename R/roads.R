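#' Road classes, ordered by design intensity
#'
#' The six motorway classes recognised by the framework, from highest to
#' lowest design intensity. When a class enters a model as a predictor it is
#' encoded as an ordered integer (freeway = 6 ... local = 1), treating class
#' as a proximal measure of traffic intensity.
#'
#' @export
roadClasses <- function() {
  c("freeway", "highway", "arterial", "subarterial", "collector", "local")
}

#' @rdname roadClasses
#' @param class character vector of road class labels.
#' @return integer intensity codes, freeway = 6 down to local = 1.
#' @export
roadClassIntensity <- function(class) {
  i <- match(class, roadClasses())
  if (anyNA(i)) stop("unknown road class: ",
                     paste(unique(class[is.na(i)]), collapse = ", "),
                     call. = FALSE)
  7L - i
}

#' Planar road network
#'
#' Polylines in projected coordinates with a road-class attribute.
#'
#' @slot coords list of n x 2 coordinate matrices, one polyline each.
#' @slot roadClass character vector, one of the six classes per polyline.
#' @export
setClass("RoadNetwork",
  representation(coords = "list", roadClass = "character"),
  validity = function(object) {
    if (length(object@coords) != length(object@roadClass))
      return("one class label per polyline required")
    if (!all(object@roadClass %in% roadClasses()))
      return("unknown road class label")
    ok <- vapply(object@coords, function(m)
      is.matrix(m) && ncol(m) == 2L && nrow(m) >= 2L, TRUE)
    if (!all(ok)) return("each polyline needs an n x 2 matrix, n >= 2")
    TRUE
  })

#' @rdname RoadNetwork-class
#' @param coords list of n x 2 coordinate matrices.
#' @param roadClass character vector of class labels.
#' @export
roadNetwork <- function(coords, roadClass) {
  new("RoadNetwork", coords = coords, roadClass = as.character(roadClass))
}

setMethod("show", "RoadNetwork", function(object) {
  cat(sprintf("RoadNetwork: %d polylines, %.1f km total\n",
              length(object@coords),
              sum(vapply(object@coords, polylineLength, 0)) / 1000))
  print(table(factor(object@roadClass, levels = roadClasses())))
})

#' @rdname RoadNetwork-class
#' @param object a \code{RoadNetwork}.
#' @export
networkLength <- function(object) {
  sum(vapply(object@coords, polylineLength, 0))
}

polylineLength <- function(m) {
  if (nrow(m) < 2L) return(0)
  sum(sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

# Point at arc-length distance s along a polyline.
pointAlong <- function(m, s) {
  seg <- sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  cs <- cumsum(seg)
  s <- min(max(s, 0), cs[length(cs)])
  k <- which(cs >= s - 1e-12)[1L]
  s0 <- if (k == 1L) 0 else cs[k - 1L]
  t <- if (seg[k] > 0) (s - s0) / seg[k] else 0
  m[k, ] + t * (m[k + 1L, ] - m[k, ])
}

#' Split a road network at grid-cell boundaries
#'
#' Partitions every polyline where it crosses a cell boundary of the
#' analysis grid, producing the road-segment modeling units. Each maximal
#' run of a polyline within one cell becomes one segment; attributes are
#' inherited and total length is conserved. Slivers shorter than
#' \code{minLength} (numerical artifacts of clipping) are merged into the
#' neighboring segment of the same polyline.
#'
#' @param network a \linkS4class{RoadNetwork}.
#' @param grid a \linkS4class{GridSpec} covering the network.
#' @param minLength minimum segment length in meters; shorter clippings are
#'   merged into a neighbor (default 0.001).
#' @return a list with \code{table}, a data.frame of segment attributes
#'   (\code{segment_id}, \code{road_id}, \code{road_class}, \code{cell_id},
#'   \code{length}, \code{mid_x}, \code{mid_y}), and \code{geometry}, a list
#'   of coordinate matrices parallel to the table rows.
#' @export
splitRoadsByGrid <- function(network, grid, minLength = 0.001) {
  ext <- gridExtent(grid)
  outside <- vapply(network@coords, function(m)
    any(m[, 1] < ext[1] | m[, 1] > ext[2] | m[, 2] < ext[3] | m[, 2] > ext[4]),
    TRUE)
  if (any(outside)) {
    stop("road(s) outside grid extent: ",
         paste(which(outside), collapse = ", "), call. = FALSE)
  }
  geoms <- list(); tabs <- list()
  for (ri in seq_along(network@coords)) {
    pieces <- clipPolylineToCells(network@coords[[ri]], grid, minLength)
    if (!length(pieces)) next
    geoms <- c(geoms, lapply(pieces, `[[`, "coords"))
    tabs[[length(tabs) + 1L]] <- data.frame(
      road_id = ri,
      road_class = network@roadClass[ri],
      cell_id = vapply(pieces, `[[`, 0L, "cell"),
      length = vapply(pieces, function(p) polylineLength(p$coords), 0),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tabs)
  tab$segment_id <- seq_len(nrow(tab))
  mids <- t(vapply(seq_along(geoms), function(i)
    pointAlong(geoms[[i]], tab$length[i] / 2), numeric(2L)))
  tab$mid_x <- mids[, 1]; tab$mid_y <- mids[, 2]
  tab <- tab[, c("segment_id", "road_id", "road_class", "cell_id",
                 "length", "mid_x", "mid_y")]
  rownames(tab) <- NULL
  list(table = tab, geometry = geoms)
}

# Split one polyline at every grid line it crosses, then group consecutive
# sub-edges by containing cell (cell of the sub-edge midpoint; half-open
# cells make this unambiguous). Returns list of list(coords, cell).
clipPolylineToCells <- function(m, grid, minLength) {
  o <- grid@origin; w <- grid@cellSize
  pts <- list(m[1L, ])
  for (k in seq_len(nrow(m) - 1L)) {
    p <- m[k, ]; q <- m[k + 1L, ]
    d <- q - p
    ts <- numeric(0)
    for (dim in 1:2) {
      if (d[dim] != 0) {
        lo <- min(p[dim], q[dim]); hi <- max(p[dim], q[dim])
        ks <- seq.int(ceiling((lo - o[dim]) / w), floor((hi - o[dim]) / w))
        gl <- o[dim] + ks * w
        gl <- gl[gl > lo & gl < hi]
        ts <- c(ts, (gl - p[dim]) / d[dim])
      }
    }
    for (t in sort(unique(ts))) pts[[length(pts) + 1L]] <- p + t * d
    pts[[length(pts) + 1L]] <- q
  }
  P <- do.call(rbind, pts)
  keep <- c(TRUE, rowSums(abs(P[-1L, , drop = FALSE] -
                              P[-nrow(P), , drop = FALSE])) > 0)
  P <- P[keep, , drop = FALSE]
  if (nrow(P) < 2L) return(list())
  mids <- (P[-1L, , drop = FALSE] + P[-nrow(P), , drop = FALSE]) / 2
  # clamp edge midpoints on the outer boundary into the last cell
  cid <- pmin(pmax(floor((mids[, 2] - o[2]) / w), 0), grid@nRows - 1L) *
    grid@nCols +
    pmin(pmax(floor((mids[, 1] - o[1]) / w), 0), grid@nCols - 1L) + 1L
  runs <- rle(as.integer(cid))
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  pieces <- lapply(seq_along(runs$values), function(i) {
    list(coords = P[starts[i]:(ends[i] + 1L), , drop = FALSE],
         cell = runs$values[i])
  })
  # merge sub-minLength slivers into the previous (or next) piece
  lens <- vapply(pieces, function(p) polylineLength(p$coords), 0)
  while (length(pieces) > 1L && any(lens < minLength)) {
    i <- which(lens < minLength)[1L]
    j <- if (i > 1L) i - 1L else i + 1L
    a <- pieces[[min(i, j)]]; b <- pieces[[max(i, j)]]
    merged <- list(coords = rbind(a$coords,
                                  b$coords[-1L, , drop = FALSE]),
                   cell = if (lens[i] < lens[j]) pieces[[j]]$cell
                          else pieces[[i]]$cell)
    pieces[[min(i, j)]] <- merged
    pieces[[max(i, j)]] <- NULL
    lens <- vapply(pieces, function(p) polylineLength(p$coords), 0)
  }
  if (length(pieces) == 1L && lens[1L] < minLength) return(list())
  pieces
}

#' Minimum planar distance from points to a polyline
#'
#' @param x,y point coordinates in meters (vectorized).
#' @param m an n x 2 polyline coordinate matrix.
#' @return per-point distance in meters.
#' @export
pointsToPolylineDistance <- function(x, y, m) {
  best <- rep(Inf, length(x))
  for (k in seq_len(nrow(m) - 1L)) {
    p <- m[k, ]; q <- m[k + 1L, ]
    d <- q - p
    L2 <- sum(d^2)
    t <- if (L2 == 0) rep(0, length(x)) else
      pmin(pmax(((x - p[1]) * d[1] + (y - p[2]) * d[2]) / L2, 0), 1)
    best <- pmin(best, sqrt((x - (p[1] + t * d[1]))^2 +
                            (y - (p[2] + t * d[2]))^2))
  }
  best
}

#' Filter collision records by positional accuracy
#'
#' Drops records whose positional uncertainty exceeds the threshold (a
#' record at exactly the threshold is kept); input order is preserved.
#'
#' @param records data.frame with at least an \code{accuracy} column
#'   (meters).
#' @param maxAccuracy maximum retained positional uncertainty in meters
#'   (default 300).
#' @return the filtered data.frame.
#' @export
filterRecordsByAccuracy <- function(records, maxAccuracy = 300) {
  stopIfNot(is.numeric(maxAccuracy) && maxAccuracy > 0,
            "maxAccuracy must be positive")
  stopIfNot(all(records$accuracy >= 0), "accuracy must be non-negative")
  records[records$accuracy <= maxAccuracy, , drop = FALSE]
}

#' Assign collision records to their nearest road segments
#'
#' Each record is assigned to the segment minimizing point-to-polyline
#' distance (ties broken by lowest segment id). A segment hit by one or
#' more records is collision-coded exactly once.
#'
#' @param records data.frame with columns \code{x}, \code{y}.
#' @param segments segment set as returned by \code{\link{splitRoadsByGrid}}.
#' @return list with \code{assignment} (per-record segment id) and
#'   \code{collisionIds} (sorted unique collision-coded segment ids).
#' @export
assignRecordsToSegments <- function(records, segments) {
  stopIfNot(length(segments$geometry) >= 1L, "at least one segment required")
  n <- nrow(records)
  if (n == 0L) return(list(assignment = integer(0), collisionIds = integer(0)))
  best <- rep(Inf, n)
  assign <- rep(NA_integer_, n)
  ids <- segments$table$segment_id
  for (i in seq_along(segments$geometry)) {
    d <- pointsToPolylineDistance(records$x, records$y,
                                  segments$geometry[[i]])
    upd <- d < best - 1e-12  # strict improvement keeps the lowest id on ties
    best[upd] <- d[upd]
    assign[upd] <- ids[i]
  }
  list(assignment = assign, collisionIds = sort(unique(assign)))
}

#' Sample background (pseudo-absence) road segments
#'
#' Uniform sample without replacement from the segments not collision-coded,
#' of size \code{round(ratio * number of collision segments)} — by default
#' twice the collision count.
#'
#' @param segments segment set from \code{\link{splitRoadsByGrid}}.
#' @param collisionIds collision-coded segment ids.
#' @param ratio background-to-collision ratio (default 2).
#' @param seed integer seed for the draw.
#' @return integer vector of background segment ids, disjoint from
#'   \code{collisionIds}.
#' @export
drawBackgroundSegments <- function(segments, collisionIds, ratio = 2,
                                   seed = 1L) {
  nTake <- round(ratio * length(collisionIds))
  pool <- setdiff(segments$table$segment_id, collisionIds)
  if (nTake > length(pool)) {
    stop(sprintf(
      "not enough non-collision segments: need %d, have %d (short by %d)",
      nTake, length(pool), nTake - length(pool)), call. = FALSE)
  }
  if (nTake == 0L) return(integer(0))
  withSubSeed(seed, "background-segments", sort(sample(pool, nTake)))
}
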