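## Statistical innervation under the quantitative Peters' rule.
##
## Within a voxel, every PST is equally likely to receive any bouton in that
## voxel. With B_i(x) boutons of presynaptic neuron i and target probability
## p_j(x) = PST_j(x) / PST_all(x), the expected synapse count per voxel is
## Itilde_ij(x) = B_i(x) * p_j(x); the total innervation I_ij = sum_x
## Itilde_ij(x) is the rate of the Poisson synapse-count law, and the pair
## connection probability is p_ij = 1 - exp(-I_ij).

#' Per-voxel target probability of a postsynaptic neuron
#'
#' \code{p_j(x) = PST_j(x) / PST_all(x)}, 0 where \code{PST_all} is 0. It is a
#' consistency error for a neuron's own PST count to exceed the total.
#'
#' @param pstJ [DensityField-class]: the neuron's PST field.
#' @param pstAllField [DensityField-class]: total PSTs of all neurons, same
#'   grid.
#' @return a [DensityField-class] of probabilities (support of \code{pstJ}).
#' @export
targetProbability <- function(pstJ, pstAllField) {
  .checkSameGrid(pstJ, pstAllField)
  tot <- fieldAt(pstAllField, pstJ@index)
  if (any(pstJ@values > tot * (1 + 1e-9) + 1e-12))
    stop("consistency error: PST_j exceeds PST_all in some voxel",
         call. = FALSE)
  p <- ifelse(tot > 0, pstJ@values / tot, 0)
  DensityField(pstJ@grid, pstJ@index, pmin(p, 1), "probability")
}

#' Per-voxel and total innervation of a neuron pair
#'
#' The voxelwise product of the presynaptic bouton field and the postsynaptic
#' target probability, with its sum (the pair's total innervation I_ij).
#'
#' @param boutonsI [DensityField-class]: bouton counts of presynaptic neuron i.
#' @param pJ [DensityField-class]: target probabilities of postsynaptic j.
#' @param pre,post neuron ids recorded on the result.
#' @return an [InnervationField-class]
#' @export
innervationField <- function(boutonsI, pJ, pre = "i", post = "j") {
  f <- fieldMultiply(boutonsI, pJ, "innervation")
  new("InnervationField", pre = as.character(pre), post = as.character(post),
      field = f, total = sum(f@values))
}

#' Total innervation of an InnervationField
#' @param x an [InnervationField-class]
#' @export
innervationTotal <- function(x) x@total

#' Pairwise connection probability from total innervation
#'
#' \code{p_ij = 1 - exp(-I_ij)}: the probability that at least one synapse
#' connects the pair under the Poisson synapse-count law.
#'
#' @param I total innervation (expected synapse count), >= 0; vectorized.
#' @return probability in [0, 1).
#' @examples
#' connectionProbability(0.66)  # ~0.48
#' @export
connectionProbability <- function(I) {
  if (any(I < 0)) stop("innervation must be >= 0", call. = FALSE)
  -expm1(-I)
}

#' Synapse-count distribution of a neuron pair
#'
#' Poisson law \code{P(n) = I^n exp(-I) / n!} (the limit of the binomial for
#' many boutons and small per-bouton probability). Also reports the smallest
#' \code{n} whose cumulative probability reaches \code{percentile}.
#'
#' @param I total innervation, >= 0.
#' @param nMax largest count to tabulate; default the 1 - 1e-9 Poisson
#'   quantile.
#' @param percentile cumulative level for the reported count range
#'   (default 0.95).
#' @return list: \code{n} (0..nMax), \code{p} (probabilities),
#'   \code{nPercentile}.
#' @export
synapseCountDistribution <- function(I, nMax = NULL, percentile = 0.95) {
  if (length(I) != 1L || I < 0) stop("I must be a single value >= 0",
                                     call. = FALSE)
  if (is.null(nMax)) nMax <- qpois(1 - 1e-9, I)
  n <- 0:nMax
  list(n = n, p = dpois(n, I), nPercentile = qpois(percentile, I))
}

#' Select neurons of a network
#'
#' Resolves a population by cell type, column and/or explicit ids;
#' \code{NULL} filters are ignored.
#'
#' @param network a [NetworkModel-class]
#' @param cellType cell-type name(s) or NULL.
#' @param column column id(s) or NULL.
#' @param insideColumn logical or NULL: require column (TRUE) / septum (FALSE)
#'   membership.
#' @param ids explicit neuron ids or NULL.
#' @return character vector of neuron ids.
#' @export
selectNeurons <- function(network, cellType = NULL, column = NULL,
                          insideColumn = NULL, ids = NULL) {
  nn <- network@neurons
  keep <- rep(TRUE, nrow(nn))
  if (!is.null(cellType)) keep <- keep & nn$cell_type %in% cellType
  if (!is.null(column)) keep <- keep & nn$column %in% column
  if (!is.null(insideColumn))
    keep <- keep & !is.na(nn$inside_column) & nn$inside_column == insideColumn
  if (!is.null(ids)) keep <- keep & nn$id %in% ids
  out <- nn$id[keep]
  if (!length(out)) stop("empty neuron selection", call. = FALSE)
  out
}

# total-PST field for one presynaptic type, over all dendrite-bearing neurons
pstAllField <- function(network, preType, meta, geo = networkGeometry(network)) {
  nn <- network@neurons
  parts <- list()
  for (id in names(geo$length)) {
    pt <- nn$cell_type[match(id, nn$id)]
    f <- pstField(geo$length[[id]], geo$area[[id]], preType, pt, meta)
    if (length(f@index)) parts[[length(parts) + 1L]] <- f
  }
  if (!length(parts))
    return(DensityField(network@frame@grid, quantity = "pst"))
  fieldAdd(parts, quantity = "pst")
}

#' Compute the pairwise innervation matrix
#'
#' For every selected (pre, post) pair: voxelize the presynaptic axon into
#' boutons, the postsynaptic dendrites/soma into PSTs, normalize by the total
#' PSTs of ALL dendrite-bearing neurons in the network (not only the
#' selection), and sum the per-voxel products. Assembled sparsely; absent
#' entries are exact zeros (no overlap).
#'
#' @param network a [NetworkModel-class]
#' @param meta meta-connectivity table with all alphas resolved.
#' @param pre,post character vectors of neuron ids (see [selectNeurons]);
#'   defaults: all axon-bearing (pre) and all dendrite-bearing (post) neurons.
#' @return an [InnervationMatrix-class]
#' @export
pairwiseInnervation <- function(network, meta, pre = NULL, post = NULL) {
  nn <- network@neurons
  geo <- networkGeometry(network)
  if (is.null(pre)) pre <- nn$id[!is.na(nn$axon_morph)]
  if (is.null(post)) post <- nn$id[!is.na(nn$dendrite_morph)]
  if (!all(pre %in% nn$id) || !all(post %in% nn$id))
    stop("selection contains unknown neuron ids", call. = FALSE)
  if (any(is.na(nn$axon_morph[match(pre, nn$id)])))
    stop("presynaptic selection contains neurons without axons", call. = FALSE)
  if (any(is.na(nn$dendrite_morph[match(post, nn$id)])))
    stop("postsynaptic selection contains neurons without dendrites",
         call. = FALSE)
  preTypes <- nn$cell_type[match(pre, nn$id)]
  postTypes <- nn$cell_type[match(post, nn$id)]
  triplets <- list()
  for (pt in unique(preTypes)) {
    pstAll <- pstAllField(network, pt, meta, geo)
    preIdsT <- pre[preTypes == pt]
    pJs <- lapply(post, function(j) {
      pj <- pstField(geo$length[[j]], geo$area[[j]], pt, postTypes[match(j, post)],
                     meta)
      targetProbability(pj, pstAll)
    })
    for (i in preIdsT) {
      bi <- geo$bouton[[i]]
      for (jx in seq_along(post)) {
        pj <- pJs[[jx]]
        common <- intersect(bi@index, pj@index)
        if (!length(common)) next
        I <- sum(fieldAt(bi, common) * fieldAt(pj, common))
        if (I > 0)
          triplets[[length(triplets) + 1L]] <-
            c(match(i, pre), jx, I)
      }
    }
  }
  if (length(triplets)) {
    tr <- do.call(rbind, triplets)
    mat <- Matrix::sparseMatrix(i = tr[, 1L], j = tr[, 2L], x = tr[, 3L],
                                dims = c(length(pre), length(post)),
                                dimnames = list(pre, post))
  } else {
    mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(pre), length(post)),
                                dimnames = list(pre, post))
  }
  info <- function(ids) {
    r <- match(ids, nn$id)
    data.frame(id = ids, cell_type = nn$cell_type[r], column = nn$column[r],
               inside_column = nn$inside_column[r], stringsAsFactors = FALSE)
  }
  im <- new("InnervationMatrix", matrix = methods::as(mat, "CsparseMatrix"),
            preInfo = info(pre), postInfo = info(post))
  validObject(im)
  im
}

#' On-demand 3D innervation field of one pair
#'
#' @param network a [NetworkModel-class]
#' @param preId,postId neuron ids.
#' @param meta meta-connectivity table.
#' @return an [InnervationField-class]
#' @export
pairInnervationField <- function(network, preId, postId, meta) {
  nn <- network@neurons
  geo <- networkGeometry(network)
  pt <- nn$cell_type[match(preId, nn$id)]
  jt <- nn$cell_type[match(postId, nn$id)]
  pstAll <- pstAllField(network, pt, meta, geo)
  pj <- targetProbability(
    pstField(geo$length[[postId]], geo$area[[postId]], pt, jt, meta), pstAll)
  innervationField(geo$bouton[[preId]], pj, preId, postId)
}

#' Innervation values of an InnervationMatrix
#' @param im an [InnervationMatrix-class]
#' @return a sparse \code{dgCMatrix} of I_ij.
#' @export
innervationMatrix <- function(im) im@matrix

#' Axis annotations of an InnervationMatrix
#' @param im an [InnervationMatrix-class]
#' @param role \code{"pre"} or \code{"post"}.
#' @return data.frame with id, cell_type, column, inside_column.
#' @export
axisInfo <- function(im, role = c("pre", "post")) {
  role <- match.arg(role)
  if (role == "pre") im@preInfo else im@postInfo
}

#' Subset an InnervationMatrix by cell type / column
#'
#' @param im an [InnervationMatrix-class]
#' @param preType,postType cell-type filters (NULL = keep all).
#' @param preColumn,postColumn column filters.
#' @return an [InnervationMatrix-class]
#' @export
subsetInnervation <- function(im, preType = NULL, postType = NULL,
                              preColumn = NULL, postColumn = NULL) {
  keepP <- rep(TRUE, nrow(im@preInfo))
  if (!is.null(preType)) keepP <- keepP & im@preInfo$cell_type %in% preType
  if (!is.null(preColumn)) keepP <- keepP & im@preInfo$column %in% preColumn
  keepQ <- rep(TRUE, nrow(im@postInfo))
  if (!is.null(postType)) keepQ <- keepQ & im@postInfo$cell_type %in% postType
  if (!is.null(postColumn)) keepQ <- keepQ & im@postInfo$column %in% postColumn
  if (!any(keepP) || !any(keepQ)) stop("empty selection", call. = FALSE)
  new("InnervationMatrix", matrix = im@matrix[keepP, keepQ, drop = FALSE],
      preInfo = im@preInfo[keepP, , drop = FALSE],
      postInfo = im@postInfo[keepQ, , drop = FALSE])
}

#' Export per-pair innervation as CSV
#'
#' Columns \code{pre,post,I,p} (only nonzero pairs).
#' @param im an [InnervationMatrix-class]
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeInnervationCSV <- function(im, path) {
  tr <- Matrix::summary(im@matrix)
  df <- data.frame(pre = rownames(im@matrix)[tr$i],
                   post = colnames(im@matrix)[tr$j],
                   I = tr$x, p = connectionProbability(tr$x))
  write.csv(df[order(df$pre, df$post), ], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @describeIn InnervationMatrix display a short summary
#' @param object an InnervationMatrix
#' @export
setMethod("show", "InnervationMatrix", function(object) {
  cat(sprintf("InnervationMatrix: %d pre x %d post, %d nonzero pairs\n",
              nrow(object@matrix), ncol(object@matrix),
              length(object@matrix@x)))
})

#' @describeIn InnervationField display a short summary
#' @param object an InnervationField
#' @export
setMethod("show", "InnervationField", function(object) {
  cat(sprintf("InnervationField %s -> %s: I = %.6g over %d voxel(s)\n",
              object@pre, object@post, object@total,
              length(object@field@index)))
})
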