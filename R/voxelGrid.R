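## VoxelGrid constructor and point/index arithmetic.

#' Construct a voxel grid
#'
#' @param origin numeric(3), lattice origin in um.
#' @param spacing voxel edge length in um (default 50, the typical precision of
#'   an averaged cortical reference frame).
#' @param dims integer(3), number of voxels per axis.
#' @return a [VoxelGrid-class]
#' @examples
#' g <- VoxelGrid(c(0, 0, 0), 50, c(10, 10, 20))
#' pointToVoxel(c(1, 1, 1), g)   # c(0, 0, 0)
#' @export
VoxelGrid <- function(origin, spacing = 50, dims) {
  g <- new("VoxelGrid", origin = as.numeric(origin),
           spacing = as.numeric(spacing), dims = as.integer(dims))
  validObject(g)
  g
}

#' Grid bounds
#'
#' Lower (inclusive) and upper (exclusive) corner of a grid.
#' @param grid a [VoxelGrid-class]
#' @return list with \code{lower} and \code{upper} numeric(3)
#' @export
gridBounds <- function(grid) {
  list(lower = grid@origin,
       upper = grid@origin + grid@dims * grid@spacing)
}

#' Number of voxels in a grid
#' @param grid a [VoxelGrid-class]
#' @export
nVoxels <- function(grid) prod(grid@dims)

#' Voxel volume in cubic millimeters
#' @param grid a [VoxelGrid-class]
#' @export
voxelVolumeMM3 <- function(grid) (grid@spacing * 1e-3)^3

#' Map a point to its voxel index
#'
#' Voxel intervals are half-open, so a point lying exactly on a face between
#' two voxels belongs to the voxel on the +side. Indices are 0-based triples
#' (i, j, k).
#'
#' @param p numeric(3) point or an n x 3 matrix of points (um).
#' @param grid a [VoxelGrid-class]
#' @return integer(3) for a single point, or an n x 3 integer matrix.
#' @export
pointToVoxel <- function(p, grid) {
  single <- !is.matrix(p)
  pm <- asPointMatrix(p)
  rel <- sweep(pm, 2L, grid@origin) / grid@spacing
  ijk <- floor(rel)
  bad <- ijk < 0 | sweep(ijk, 2L, grid@dims, `>=`)
  if (any(bad)) {
    r <- which(rowSums(bad) > 0)[1L]
    stop(sprintf("point (%s) is outside the grid bounds",
                 paste(signif(pm[r, ], 6), collapse = ", ")), call. = FALSE)
  }
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  if (single) ijk[1L, ] else ijk
}

# 0-based ijk triples <-> 1-based linear indices (column-major: i fastest)
ijkToLinear <- function(ijk, grid) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  1L + ijk[, 1L] + grid@dims[1L] * (ijk[, 2L] + grid@dims[2L] * ijk[, 3L])
}

linearToIjk <- function(idx, grid) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% grid@dims[1L]
  rest <- idx0 %/% grid@dims[1L]
  j <- rest %% grid@dims[2L]
  k <- rest %/% grid@dims[2L]
  cbind(i = i, j = j, k = k)
}

#' Voxel centers
#'
#' @param grid a [VoxelGrid-class]
#' @param index 1-based linear voxel indices (default: all voxels).
#' @return n x 3 matrix of voxel center coordinates (um).
#' @export
voxelCenters <- function(grid, index = seq_len(nVoxels(grid))) {
  ijk <- linearToIjk(index, grid)
  sweep((ijk + 0.5) * grid@spacing, 2L, grid@origin, `+`)
}

#' @describeIn VoxelGrid display a short summary
#' @param object a VoxelGrid
#' @export
setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d x %d x %d voxels, spacing %g um, origin (%s)\n",
              object@dims[1], object@dims[2], object@dims[3], object@spacing,
              paste(signif(object@origin, 6), collapse = ", ")))
})
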