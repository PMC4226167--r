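## Standardized 3D reference frame: columns, laminar zones, local axes.
##
## Columns are cylinders described by a center, a unit axis and a radius.
## Depth along a column is measured along its axis with the convention that
## the center sits at the midpoint of [top_depth, bottom_depth]:
##   depth(p) = dot(p - center, axis) + (top_depth + bottom_depth) / 2
## so depth == top_depth at the pia intersection and bottom_depth at the
## white-matter intersection. Depth increases from pia toward white matter.

#' Construct a reference frame
#'
#' Builds the frame and precomputes the local vertical-axis field: for each
#' voxel center, the inverse-distance-weighted mean of the \code{k} nearest
#' column axes (distance = distance to the column's axis segment),
#' renormalized to unit length.
#'
#' @param grid a [VoxelGrid-class]
#' @param columns data.frame with fields
#'   \code{id,cx,cy,cz,ax,ay,az,radius,top_depth,bottom_depth} (see
#'   [ReferenceFrame-class]); read one with [readColumnTable].
#' @param zones data.frame with fields \code{column_id,zone,depth_min,depth_max}.
#' @param k number of nearest columns used for axis interpolation (default 3).
#' @return a [ReferenceFrame-class]
#' @export
ReferenceFrame <- function(grid, columns, zones, k = 3L) {
  columns <- as.data.frame(columns)
  columns$id <- as.character(columns$id)
  zones <- as.data.frame(zones)
  zones$column_id <- as.character(zones$column_id)
  zones$zone <- as.character(zones$zone)
  .checkZones(zones)
  columns <- columns[order(columns$id), , drop = FALSE]
  rownames(columns) <- NULL
  k <- max(1L, min(as.integer(k), nrow(columns)))
  ctrs <- voxelCenters(grid)
  axf <- .interpolateAxes(ctrs, columns, k)
  fr <- new("ReferenceFrame", grid = grid, columns = columns, zones = zones,
            k = k, axisField = axf)
  validObject(fr)
  fr
}

.checkZones <- function(zones) {
  for (cid in unique(zones$column_id)) {
    z <- zones[zones$column_id == cid, , drop = FALSE]
    z <- z[order(z$depth_min), , drop = FALSE]
    if (any(z$depth_min >= z$depth_max))
      stop("zone depth intervals must have depth_min < depth_max", call. = FALSE)
    if (nrow(z) > 1L && any(z$depth_min[-1L] < z$depth_max[-nrow(z)]))
      stop("zones within column '", cid, "' must be disjoint and ordered",
           call. = FALSE)
  }
  invisible(TRUE)
}

# Per-column geometry of points: axial coordinate t (relative to center),
# depth, radial distance, and distance to the axis segment.
.columnCoords <- function(pm, col) {
  ax <- c(col$ax, col$ay, col$az)
  ctr <- c(col$cx, col$cy, col$cz)
  rel <- sweep(pm, 2L, ctr)
  t <- drop(rel %*% ax)
  perp2 <- pmax(rowSums(rel^2) - t^2, 0)
  mid <- (col$top_depth + col$bottom_depth) / 2
  tmin <- col$top_depth - mid
  tmax <- col$bottom_depth - mid
  tc <- pmin(pmax(t, tmin), tmax)
  segDist <- sqrt(perp2 + (t - tc)^2)
  list(depth = t + mid, radial = sqrt(perp2), segDist = segDist)
}

# Distance of points to every column's axis segment (n x nColumns matrix).
.columnDistances <- function(pm, columns) {
  vapply(seq_len(nrow(columns)), function(ci)
    .columnCoords(pm, columns[ci, ])$segDist, numeric(nrow(pm)))
}

.interpolateAxes <- function(pm, columns, k) {
  d <- matrix(.columnDistances(pm, columns), nrow = nrow(pm))
  axes <- as.matrix(columns[, c("ax", "ay", "az")])
  out <- matrix(NA_real_, nrow(pm), 3L)
  for (r in seq_len(nrow(pm))) {
    o <- order(d[r, ], columns$id)[seq_len(k)]
    dd <- d[r, o]
    if (dd[1L] < 1e-12) {
      v <- axes[o[1L], ]
    } else {
      w <- 1 / dd
      v <- colSums(axes[o, , drop = FALSE] * w) / sum(w)
    }
    nv <- vecNorm(v)
    if (nv < 1e-9)
      stop("degenerate local axis: interpolated vector has near-zero norm",
           call. = FALSE)
    out[r, ] <- v / nv
  }
  out
}

#' Nearest column of a point
#'
#' Returns the column minimizing the distance from \code{p} to the column's
#' axis segment; ties are broken by the lexicographically smallest column id.
#' The point is inside the column iff its radial distance is at most the
#' column radius and its depth lies within \code{[top_depth, bottom_depth]};
#' otherwise it belongs to the septum of that column.
#'
#' @param p numeric(3) point (um).
#' @param frame a [ReferenceFrame-class]
#' @return list with \code{id} (character) and \code{inside} (logical).
#' @export
nearestColumn <- function(p, frame) {
  pm <- asPointMatrix(p)
  d <- matrix(.columnDistances(pm, frame@columns), nrow = nrow(pm))[1L, ]
  ci <- order(d, frame@columns$id)[1L]  # tie-break: smallest id
  col <- frame@columns[ci, ]
  cc <- .columnCoords(pm, col)
  inside <- cc$radial[1L] <= col$radius &&
    cc$depth[1L] >= col$top_depth && cc$depth[1L] <= col$bottom_depth
  list(id = col$id, inside = inside)
}

#' Depth of a point along a column's axis
#'
#' Depth is measured along the column axis from the pia
#' (depth = \code{top_depth} at the pia intersection).
#'
#' @param p numeric(3) point (um).
#' @param frame a [ReferenceFrame-class]
#' @param columnId column to measure against; default the nearest column.
#' @return scalar depth in um.
#' @export
columnDepth <- function(p, frame, columnId = NULL) {
  if (is.null(columnId)) columnId <- nearestColumn(p, frame)$id
  ci <- match(columnId, frame@columns$id)
  if (is.na(ci)) stop("unknown column id: ", columnId, call. = FALSE)
  .columnCoords(asPointMatrix(p), frame@columns[ci, ])$depth[1L]
}

#' Local vertical axis at a point
#'
#' Inverse-distance-weighted mean of the \code{k} nearest column axes
#' (k fixed at frame construction), renormalized to unit length. A point on a
#' column's axis returns that column's axis exactly.
#'
#' @param p numeric(3) point (um), must be within the grid bounds.
#' @param frame a [ReferenceFrame-class]
#' @return unit numeric(3)
#' @export
localAxis <- function(p, frame) {
  pm <- asPointMatrix(p)
  pointToVoxel(pm, frame@grid)  # bounds check
  drop(.interpolateAxes(pm, frame@columns, frame@k))
}

#' Axis field of a frame
#'
#' @param frame a [ReferenceFrame-class]
#' @return nVoxels x 3 matrix of unit vectors (linear voxel order).
#' @export
axisField <- function(frame) frame@axisField

#' Laminar zone containing a point
#'
#' The point's depth along the nearest column's axis is looked up in that
#' column's half-open zone intervals \code{[depth_min, depth_max)}. Depths
#' outside every zone (e.g. below the white matter) return the sentinel
#' \code{"outside"}.
#'
#' @param p numeric(3) point (um), within grid bounds.
#' @param frame a [ReferenceFrame-class]
#' @return zone name (character scalar).
#' @export
laminarZoneOf <- function(p, frame) {
  pm <- asPointMatrix(p)
  pointToVoxel(pm, frame@grid)  # bounds check
  nc <- nearestColumn(p, frame)
  d <- columnDepth(p, frame, nc$id)
  z <- frame@zones[frame@zones$column_id == nc$id, , drop = FALSE]
  hit <- which(d >= z$depth_min & d < z$depth_max)
  if (length(hit)) z$zone[hit[1L]] else "outside"
}

# Zone of every voxel (by voxel center), cached per frame in a weak-ish env.
.zoneCache <- new.env(parent = emptyenv())

voxelZones <- function(frame) {
  key <- paste(c(frame@grid@origin, frame@grid@spacing, frame@grid@dims,
                 unlist(frame@columns), unlist(frame@zones)), collapse = "|")
  hit <- .zoneCache[[key]]
  if (!is.null(hit)) return(hit)
  ctrs <- voxelCenters(frame@grid)
  zn <- vapply(seq_len(nrow(ctrs)),
               function(r) laminarZoneOf(ctrs[r, ], frame), character(1))
  .zoneCache[[key]] <- zn
  zn
}

#' Read a column table
#'
#' CSV with header \code{id,cx,cy,cz,ax,ay,az,radius,top_depth,bottom_depth}.
#' @param path file path
#' @return data.frame
#' @export
readColumnTable <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "cx", "cy", "cz", "ax", "ay", "az", "radius",
            "top_depth", "bottom_depth")
  if (!all(need %in% names(tb)))
    stop("column table must have header: ", paste(need, collapse = ","),
         call. = FALSE)
  tb$id <- as.character(tb$id)
  tb
}

#' Read a laminar-zone table
#'
#' CSV with header \code{column_id,zone,depth_min,depth_max}.
#' @param path file path
#' @return data.frame
#' @export
readZoneTable <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("column_id", "zone", "depth_min", "depth_max")
  if (!all(need %in% names(tb)))
    stop("zone table must have header: ", paste(need, collapse = ","),
         call. = FALSE)
  tb$column_id <- as.character(tb$column_id)
  tb$zone <- as.character(tb$zone)
  tb
}

#' @describeIn ReferenceFrame display a short summary
#' @param object a ReferenceFrame
#' @export
setMethod("show", "ReferenceFrame", function(object) {
  cat(sprintf("ReferenceFrame: %d column(s), %d zone row(s), k = %d\n",
              nrow(object@columns), nrow(object@zones), object@k))
  show(object@grid)
})
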