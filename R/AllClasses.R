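## Central S4 classes. Accessors and methods live in the per-module files.

#' VoxelGrid: an axis-aligned cubic voxel lattice
#'
#' The lattice over which all density and innervation computations are
#' performed. Voxels are half-open boxes
#' \code{[origin + i*spacing, origin + (i+1)*spacing)} per axis, so every
#' in-bounds point belongs to exactly one voxel. Coordinates are in
#' micrometers; the default spacing of 50 um reflects the inter-animal
#' variability of typical cortical reference frames.
#'
#' @slot origin numeric(3), lattice origin (um).
#' @slot spacing scalar voxel edge length (um), > 0.
#' @slot dims integer(3), number of voxels per axis, >= 1.
#' @export
setClass("VoxelGrid",
  representation(origin = "numeric", spacing = "numeric", dims = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be finite numeric(3)")
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive number")
    if (length(object@dims) != 3L || any(object@dims < 1L))
      msg <- c(msg, "dims must be integer(3) with all entries >= 1")
    if (length(msg)) msg else TRUE
  })

#' ReferenceFrame: standardized 3D geometry of the modeled brain region
#'
#' Bundles the voxel grid, the cylindrical columns (e.g. barrel columns), the
#' laminar zones of each column, and a per-voxel field of local vertical unit
#' axes interpolated from the nearest column axes.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot columns data.frame with columns
#'   \code{id,cx,cy,cz,ax,ay,az,radius,top_depth,bottom_depth}. The center is
#'   the midpoint of the column's axis segment; \code{top_depth} (pia) and
#'   \code{bottom_depth} (white matter) are depths along the axis with depth
#'   increasing from the pia.
#' @slot zones data.frame with columns \code{column_id,zone,depth_min,depth_max}
#'   (half-open depth intervals, disjoint and ordered within a column).
#' @slot k integer, number of nearest columns used for inverse-distance
#'   interpolation of the local axis field.
#' @slot axisField numeric matrix (nVoxels x 3) of unit vectors, one row per
#'   voxel in linear-index order.
#' @export
setClass("ReferenceFrame",
  representation(grid = "VoxelGrid", columns = "data.frame",
                 zones = "data.frame", k = "integer",
                 axisField = "matrix"),
  validity = function(object) {
    msg <- character()
    need <- c("id", "cx", "cy", "cz", "ax", "ay", "az", "radius",
              "top_depth", "bottom_depth")
    if (!all(need %in% names(object@columns)))
      msg <- c(msg, paste("columns table must have fields:",
                          paste(need, collapse = ",")))
    else {
      cl <- object@columns
      if (nrow(cl) < 1L) msg <- c(msg, "at least one column is required")
      n <- sqrt(cl$ax^2 + cl$ay^2 + cl$az^2)
      if (any(abs(n - 1) > 1e-9))
        msg <- c(msg, "column axes must be unit vectors (|axis| = 1 +/- 1e-9)")
      if (any(cl$radius <= 0)) msg <- c(msg, "column radii must be > 0")
      if (any(cl$top_depth >= cl$bottom_depth))
        msg <- c(msg, "top_depth must be < bottom_depth")
      if (anyDuplicated(cl$id)) msg <- c(msg, "column ids must be unique")
      lo <- object@grid@origin
      hi <- lo + object@grid@dims * object@grid@spacing
      ctr <- as.matrix(cl[, c("cx", "cy", "cz")])
      if (any(t(ctr) < lo) || any(t(ctr) >= hi))
        msg <- c(msg, "every column center must lie inside the grid bounds")
    }
    needz <- c("column_id", "zone", "depth_min", "depth_max")
    if (!all(needz %in% names(object@zones)))
      msg <- c(msg, paste("zones table must have fields:",
                          paste(needz, collapse = ",")))
    nv <- prod(object@grid@dims)
    if (!is.numeric(object@axisField) || nrow(object@axisField) != nv ||
        ncol(object@axisField) != 3L)
      msg <- c(msg, "axisField must be an nVoxels x 3 matrix")
    else if (any(abs(sqrt(rowSums(object@axisField^2)) - 1) > 1e-9))
      msg <- c(msg, "axisField rows must be unit vectors")
    if (length(msg)) msg else TRUE
  })

#' Morphology: a labeled neuron reconstruction
#'
#' A rooted tree (or forest) of 3D nodes with radii, each node carrying one of
#' the four branch labels \code{soma}, \code{apical}, \code{basal},
#' \code{axon}. Parent indices are 1-based into the node table; roots have
#' parent \code{NA}.
#'
#' @slot nodes data.frame with columns \code{x,y,z,radius,label,parent}.
#' @slot cellType character, cell-type identifier (may be \code{NA}).
#' @slot column character, substructure (column) the reconstruction is
#'   registered to (may be \code{NA}).
#' @slot somaPosition numeric(3), centroid of the soma-labeled nodes (falls
#'   back to the first root if no soma nodes exist).
#' @export
setClass("Morphology",
  representation(nodes = "data.frame", cellType = "character",
                 column = "character", somaPosition = "numeric"),
  validity = function(object) {
    msg <- character()
    nd <- object@nodes
    need <- c("x", "y", "z", "radius", "label", "parent")
    if (!all(need %in% names(nd)))
      return(paste("nodes must have fields:", paste(need, collapse = ",")))
    if (nrow(nd) < 1L) msg <- c(msg, "morphology must have at least one node")
    if (!all(nd$label %in% c("soma", "apical", "basal", "axon")))
      msg <- c(msg, "labels must be in {soma, apical, basal, axon}")
    if (any(nd$radius < 0) || any(!is.finite(nd$radius)))
      msg <- c(msg, "radii must be finite and >= 0")
    if (any(!is.finite(as.matrix(nd[, c("x", "y", "z")]))))
      msg <- c(msg, "node positions must be finite")
    par <- nd$parent
    ok <- is.na(par) | (par >= 1L & par <= nrow(nd))
    if (!all(ok)) msg <- c(msg, "parent indices out of range")
    else if (nrow(nd) >= 1L && !length(msg)) {
      # cycle check by walking to the root from every node
      depth <- rep(NA_integer_, nrow(nd))
      for (i in seq_len(nrow(nd))) {
        seen <- integer(0)
        j <- i
        while (!is.na(par[j])) {
          if (j %in% seen) { msg <- c(msg, "cyclic parent links"); break }
          seen <- c(seen, j)
          j <- par[j]
          if (length(seen) > nrow(nd)) { msg <- c(msg, "cyclic parent links"); break }
        }
        if (length(msg)) break
      }
    }
    if (length(object@somaPosition) != 3L || any(!is.finite(object@somaPosition)))
      msg <- c(msg, "somaPosition must be finite numeric(3)")
    if (length(msg)) msg else TRUE
  })

#' RigidTransform: rotation about the soma plus translation
#'
#' Maps node positions \code{p} to
#' \code{rotation \%*\% (p - somaPosition) + somaPosition + translation}, i.e.
#' a proper rotation about the morphology's soma followed by a translation.
#'
#' @slot translation numeric(3) (um).
#' @slot rotation 3x3 orthonormal matrix with determinant 1.
#' @export
setClass("RigidTransform",
  representation(translation = "numeric", rotation = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@translation) != 3L || any(!is.finite(object@translation)))
      msg <- c(msg, "translation must be finite numeric(3)")
    R <- object@rotation
    if (!is.numeric(R) || !all(dim(R) == c(3L, 3L)))
      msg <- c(msg, "rotation must be a 3x3 numeric matrix")
    else {
      if (max(abs(crossprod(R) - diag(3))) > 1e-8)
        msg <- c(msg, "rotation must be orthonormal")
      if (abs(det(R) - 1) > 1e-9)
        msg <- c(msg, "rotation determinant must be 1 +/- 1e-9")
    }
    if (length(msg)) msg else TRUE
  })

#' DensityField: a sparse per-voxel scalar field
#'
#' Stores one scalar per occupied voxel of a [VoxelGrid-class] (linear voxel
#' index -> value). Used for axon length, bouton counts, per-label dendrite
#' length and surface area, PST counts, target probabilities and innervation.
#'
#' @slot grid the underlying [VoxelGrid-class].
#' @slot index integer vector of 1-based linear voxel indices (sorted, unique).
#' @slot values numeric vector of the same length, finite and >= 0.
#' @slot quantity character tag naming what is stored (e.g. \code{"length_um"},
#'   \code{"boutons"}, \code{"pst"}).
#' @export
setClass("DensityField",
  representation(grid = "VoxelGrid", index = "integer", values = "numeric",
                 quantity = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@index) != length(object@values))
      msg <- c(msg, "index and values must have equal length")
    if (length(object@index)) {
      if (is.unsorted(object@index, strictly = TRUE))
        msg <- c(msg, "index must be strictly increasing")
      nv <- prod(object@grid@dims)
      if (min(object@index) < 1L || max(object@index) > nv)
        msg <- c(msg, "index out of range for grid")
      if (any(!is.finite(object@values)) || any(object@values < 0))
        msg <- c(msg, "values must be finite and >= 0")
    }
    if (length(msg)) msg else TRUE
  })

#' NetworkModel: a placed dense circuit model
#'
#' The output of network assembly: every soma sampled from the density fields
#' is represented by a cell type, a column/septum assignment, a rigidly
#' transformed dendrite morphology and an untransformed axon morphology.
#' Long-range axons (cell types without local somata) appear as axon-only
#' entries.
#'
#' @slot frame the [ReferenceFrame-class].
#' @slot neurons data.frame with one row per neuron: \code{id,x,y,z,column,
#'   inside_column,cell_type,excitatory,dendrite_morph,axon_morph}.
#'   \code{dendrite_morph} is \code{NA} for axon-only entries.
#' @slot morphologies named list of [Morphology-class] objects (the library).
#' @slot transforms named list of [RigidTransform-class], keyed by neuron id
#'   (dendrite transform; absent for axon-only neurons).
#' @slot cellTypes data.frame of cell-type specifications (see
#'   [readCellTypeTable]).
#' @slot cache environment memoizing derived per-neuron geometry fields.
#' @export
setClass("NetworkModel",
  representation(frame = "ReferenceFrame", neurons = "data.frame",
                 morphologies = "list", transforms = "list",
                 cellTypes = "data.frame", cache = "environment"),
  validity = function(object) {
    msg <- character()
    need <- c("id", "x", "y", "z", "column", "inside_column", "cell_type",
              "excitatory", "dendrite_morph", "axon_morph")
    if (!all(need %in% names(object@neurons)))
      msg <- c(msg, paste("neurons table must have fields:",
                          paste(need, collapse = ",")))
    else {
      nn <- object@neurons
      if (anyDuplicated(nn$id)) msg <- c(msg, "neuron ids must be unique")
      refs <- c(nn$dendrite_morph, nn$axon_morph)
      refs <- refs[!is.na(refs)]
      if (!all(refs %in% names(object@morphologies)))
        msg <- c(msg, "every neuron must resolve to concrete geometry")
      hasD <- !is.na(nn$dendrite_morph)
      if (!all(nn$id[hasD] %in% names(object@transforms)))
        msg <- c(msg, "every placed dendrite needs a transform")
    }
    if (length(msg)) msg else TRUE
  })

#' InnervationField: per-voxel expected synapse counts for one neuron pair
#'
#' @slot pre,post character neuron ids.
#' @slot field [DensityField-class] of per-voxel expected synapse counts.
#' @slot total scalar, sum of the field (the pair's total innervation).
#' @export
setClass("InnervationField",
  representation(pre = "character", post = "character",
                 field = "DensityField", total = "numeric"),
  validity = function(object) {
    if (abs(object@total - sum(object@field@values)) >
        1e-9 * max(1, object@total))
      "total must equal the field sum within 1e-9" else TRUE
  })

#' InnervationMatrix: the sparse dense-connectome matrix
#'
#' Expected synapse counts I_ij for all selected (pre, post) neuron pairs,
#' stored sparsely; an absent entry means no axo-dendritic overlap (I = 0).
#'
#' @slot matrix a \code{dgCMatrix} (pre neurons x post neurons), dimnames are
#'   neuron ids.
#' @slot preInfo,postInfo data.frames annotating the axes
#'   (\code{id,cell_type,column,inside_column}).
#' @export
setClass("InnervationMatrix",
  representation(matrix = "Matrix", preInfo = "data.frame",
                 postInfo = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@matrix) != nrow(object@preInfo) ||
        ncol(object@matrix) != nrow(object@postInfo))
      msg <- c(msg, "axis annotations must match matrix dimensions")
    if (length(object@matrix@x) && any(object@matrix@x < 0))
      msg <- c(msg, "innervation entries must be >= 0")
    if (length(msg)) msg else TRUE
  })
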