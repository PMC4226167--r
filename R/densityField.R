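## Sparse per-voxel scalar fields and their arithmetic.

#' Construct a density field
#'
#' Duplicate voxel indices are summed; exact zeros are dropped.
#'
#' @param grid a [VoxelGrid-class]
#' @param index 1-based linear voxel indices.
#' @param values nonnegative values, same length as \code{index}.
#' @param quantity tag naming the stored quantity.
#' @return a [DensityField-class]
#' @export
DensityField <- function(grid, index = integer(0), values = numeric(0),
                         quantity = "value") {
  if (length(index)) {
    agg <- rowsum(as.numeric(values), as.integer(index))
    idx <- as.integer(rownames(agg))
    val <- as.numeric(agg)
    keep <- val != 0
    idx <- idx[keep]; val <- val[keep]
    o <- order(idx)
    idx <- idx[o]; val <- val[o]
  } else {
    idx <- integer(0); val <- numeric(0)
  }
  f <- new("DensityField", grid = grid, index = idx, values = val,
           quantity = quantity)
  validObject(f)
  f
}

#' Occupied voxel indices of a field
#' @param f a [DensityField-class]
#' @export
fieldIndex <- function(f) f@index

#' Values of a field (aligned with [fieldIndex])
#' @param f a [DensityField-class]
#' @export
fieldValues <- function(f) f@values

#' Sum of a field over all voxels
#' @param f a [DensityField-class]
#' @export
fieldTotal <- function(f) sum(f@values)

#' Look up field values at given voxel indices (0 where unoccupied)
#' @param f a [DensityField-class]
#' @param index 1-based linear voxel indices.
#' @export
fieldAt <- function(f, index) {
  m <- match(as.integer(index), f@index)
  out <- ifelse(is.na(m), 0, f@values[m])
  as.numeric(out)
}

.checkSameGrid <- function(a, b) {
  ga <- a@grid; gb <- b@grid
  if (!isTRUE(all.equal(ga@origin, gb@origin)) ||
      ga@spacing != gb@spacing || !all(ga@dims == gb@dims))
    stop("density fields must share the same grid", call. = FALSE)
}

#' Add density fields
#' @param ... [DensityField-class] objects on a shared grid.
#' @param quantity tag for the result.
#' @return a [DensityField-class]
#' @export
fieldAdd <- function(..., quantity = NULL) {
  fs <- list(...)
  if (length(fs) == 1L && is.list(fs[[1L]]) && !is(fs[[1L]], "DensityField"))
    fs <- fs[[1L]]
  stopifnot(length(fs) >= 1L)
  for (f in fs[-1L]) .checkSameGrid(fs[[1L]], f)
  DensityField(fs[[1L]]@grid,
               unlist(lapply(fs, fieldIndex)),
               unlist(lapply(fs, fieldValues)),
               quantity %||% fs[[1L]]@quantity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxelwise product of two fields
#' @param a,b [DensityField-class] objects on a shared grid.
#' @param quantity tag for the result.
#' @return a [DensityField-class] supported on the index intersection.
#' @export
fieldMultiply <- function(a, b, quantity = "product") {
  .checkSameGrid(a, b)
  common <- intersect(a@index, b@index)
  DensityField(a@grid, common,
               fieldAt(a, common) * fieldAt(b, common), quantity)
}

#' Scale a field by a constant or per-voxel factors
#' @param f a [DensityField-class]
#' @param s scalar, or numeric vector aligned with [fieldIndex].
#' @param quantity tag for the result.
#' @return a [DensityField-class]
#' @export
fieldScale <- function(f, s, quantity = f@quantity) {
  DensityField(f@grid, f@index, f@values * s, quantity)
}

#' Densify a field into a 3D array
#' @param f a [DensityField-class]
#' @return numeric array of dimension \code{dims(grid)}.
#' @export
fieldAsArray <- function(f) {
  a <- array(0, dim = f@grid@dims)
  a[f@index] <- f@values
  a
}

#' Collapse a field to the grid's z-axis
#'
#' Sums values over each layer of voxels with equal k index (the depth axis of
#' the grid), as used for the 1D surface-PST balance fit.
#' @param f a [DensityField-class]
#' @return numeric vector of length \code{dims[3]}.
#' @export
fieldDepthProfile <- function(f) {
  prof <- numeric(f@grid@dims[3L])
  if (length(f@index)) {
    k <- linearToIjk(f@index, f@grid)[, "k"] + 1L
    agg <- rowsum(f@values, k)
    prof[as.integer(rownames(agg))] <- as.numeric(agg)
  }
  prof
}

#' Write a sparse field as CSV
#'
#' Plain-text export with columns \code{i,j,k,value} (0-based voxel indices).
#' @param f a [DensityField-class]
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFieldCSV <- function(f, path) {
  ijk <- linearToIjk(f@index, f@grid)
  df <- data.frame(i = ijk[, 1L], j = ijk[, 2L], k = ijk[, 3L],
                   value = f@values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn DensityField display a short summary
#' @param object a DensityField
#' @export
setMethod("show", "DensityField", function(object) {
  cat(sprintf("DensityField[%s]: %d occupied voxel(s), total %.6g\n",
              object@quantity, length(object@index), sum(object@values)))
})
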