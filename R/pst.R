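## Bouton fields, postsynaptic-target (PST) fields and the surface-PST
## balance fit.
##
## PSTs come in two flavors: length-based (dendritic spines, density lambda
## per um branch) and surface-based (membrane patches, density alpha per um^2
## area). For a postsynaptic neuron j and a presynaptic cell type T(i), the
## per-voxel PST count is
##   PST_j(x, T(i)) = sum_L l_{j,L}(x) * lambda_{T(i),T(j)}(L)
##                  + sum_L a_{j,L}(x) * alpha_{T(i),T(j)}(L)
## over the subcellular labels L (soma, apical, basal). Labels without a
## meta-connectivity entry contribute 0 (the pre type cannot synapse there).

.ZONE_COLS <- c(supragranular = "bouton_supra", granular = "bouton_gran",
                infragranular = "bouton_infra")

#' Read a cell-type specification table
#'
#' CSV with header \code{name,excitatory,rotate_polar,axon_only,occupancy,}
#' \code{bouton_supra,bouton_gran,bouton_infra,long_range_count}.
#' \code{occupancy} is one of \code{column}, \code{septum}, \code{both};
#' \code{long_range_count} is empty for local cell types. Bouton densities are
#' per um axon, one value per laminar zone.
#'
#' @param path file path
#' @return data.frame (logical flags coerced, name as character)
#' @export
readCellTypeTable <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "excitatory", "rotate_polar", "axon_only", "occupancy",
            .ZONE_COLS, "long_range_count")
  if (!all(need %in% names(tb)))
    stop("cell-type table must have header: ", paste(need, collapse = ","),
         call. = FALSE)
  tb$name <- as.character(tb$name)
  for (f in c("excitatory", "rotate_polar", "axon_only"))
    tb[[f]] <- as.logical(tb[[f]])
  if (any(!tb$occupancy %in% c("column", "septum", "both")))
    stop("occupancy must be one of column, septum, both", call. = FALSE)
  if (any(tb[, .ZONE_COLS] < 0)) stop("bouton densities must be >= 0",
                                      call. = FALSE)
  bad <- !is.na(tb$long_range_count) & tb$long_range_count < 1
  if (any(bad)) stop("long_range_count must be >= 1 when set", call. = FALSE)
  tb
}

# Bouton density per zone for one cell-type row; voxels outside all zones get
# density 0, unnamed zones are a configuration error at lookup time.
.boutonDensities <- function(typeRow) {
  d <- c(unlist(typeRow[, .ZONE_COLS]), 0)
  names(d) <- c(names(.ZONE_COLS), "outside")
  d
}

#' Read a cell-type frequency table
#'
#' CSV with header \code{region,inside_column,cell_type,frequency}: the
#' relative frequency of each cell type among somata in \code{region}
#' (a column id), split by inside-column vs septum status. Frequencies are
#' conditional on the excitatory/inhibitory class of the soma (each class's
#' frequencies sum to 1 within a region stratum), since excitatory and
#' inhibitory somata are sampled from separate density fields.
#' @param path file path
#' @return data.frame
#' @export
readFrequencyTable <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "inside_column", "cell_type", "frequency")
  if (!all(need %in% names(tb)))
    stop("frequency table must have header: ", paste(need, collapse = ","),
         call. = FALSE)
  tb$region <- as.character(tb$region)
  tb$inside_column <- as.logical(tb$inside_column)
  tb$cell_type <- as.character(tb$cell_type)
  if (any(tb$frequency < 0)) stop("frequencies must be >= 0", call. = FALSE)
  tb
}

#' Read a meta-connectivity table
#'
#' CSV with header \code{pre_type,post_type,label,lambda_per_um,alpha_per_um2}.
#' An empty \code{alpha_per_um2} marks a surface-PST density to be fitted by
#' [fitSurfacePST]. At most one row per (pre_type, post_type, label).
#' @param path file path
#' @return data.frame
#' @export
readMetaConnectivity <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pre_type", "post_type", "label", "lambda_per_um", "alpha_per_um2")
  if (!all(need %in% names(tb)))
    stop("meta-connectivity table must have header: ",
         paste(need, collapse = ","), call. = FALSE)
  metaConnectivity(tb)
}

#' Validate a meta-connectivity data.frame
#' @param tb data.frame with the [readMetaConnectivity] columns.
#' @return the validated data.frame
#' @export
metaConnectivity <- function(tb) {
  tb <- as.data.frame(tb)
  tb$lambda_per_um <- as.numeric(tb$lambda_per_um)
  tb$alpha_per_um2 <- as.numeric(tb$alpha_per_um2)
  key <- paste(tb$pre_type, tb$post_type, tb$label)
  if (anyDuplicated(key))
    stop("meta-connectivity: at most one entry per (pre, post, label)",
         call. = FALSE)
  if (!all(tb$label %in% c("soma", "apical", "basal")))
    stop("meta-connectivity labels must be soma, apical or basal",
         call. = FALSE)
  if (any(tb$lambda_per_um < 0, na.rm = TRUE) ||
      any(tb$alpha_per_um2 < 0, na.rm = TRUE))
    stop("PST densities must be >= 0", call. = FALSE)
  tb
}

.metaLookup <- function(meta, pre, post, label, what) {
  hit <- meta$pre_type == pre & meta$post_type == post & meta$label == label
  if (!any(hit)) return(0)
  v <- meta[[what]][which(hit)[1L]]
  if (is.na(v)) 0 else v
}

#' Convert an axon length field into a bouton field
#'
#' Multiplies the per-voxel axon length by the cell type's bouton density of
#' the laminar zone containing the voxel center.
#'
#' @param axonLength a [DensityField-class] of axon length (um per voxel).
#' @param typeRow one row of the cell-type table ([readCellTypeTable]).
#' @param frame a [ReferenceFrame-class] (zone lookup per voxel center).
#' @return a [DensityField-class] of expected bouton counts.
#' @export
boutonField <- function(axonLength, typeRow, frame) {
  dens <- .boutonDensities(typeRow)
  zn <- voxelZones(frame)[axonLength@index]
  miss <- setdiff(unique(zn), names(dens))
  if (length(miss))
    stop("no bouton density configured for zone(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  DensityField(axonLength@grid, axonLength@index,
               axonLength@values * dens[zn], "boutons")
}

#' PST field of a postsynaptic neuron for one presynaptic type
#'
#' @param lengthFields,areaFields named lists of [DensityField-class] keyed by
#'   label (\code{soma}, \code{apical}, \code{basal}): the neuron's clipped
#'   per-voxel branch length and surface area (see [clipToVoxels]).
#' @param preType presynaptic cell type name.
#' @param postType postsynaptic cell type name.
#' @param meta meta-connectivity data.frame ([readMetaConnectivity]).
#' @return a [DensityField-class] of PST counts.
#' @export
pstField <- function(lengthFields, areaFields, preType, postType, meta) {
  grid <- NULL
  parts <- list()
  for (lab in union(names(lengthFields), names(areaFields))) {
    lam <- .metaLookup(meta, preType, postType, lab, "lambda_per_um")
    alp <- .metaLookup(meta, preType, postType, lab, "alpha_per_um2")
    lf <- lengthFields[[lab]]; af <- areaFields[[lab]]
    if (!is.null(lf)) grid <- lf@grid else if (!is.null(af)) grid <- af@grid
    if (lam > 0 && !is.null(lf))
      parts[[length(parts) + 1L]] <- fieldScale(lf, lam, "pst")
    if (alp > 0 && !is.null(af))
      parts[[length(parts) + 1L]] <- fieldScale(af, alp, "pst")
  }
  if (!length(parts)) return(DensityField(grid, quantity = "pst"))
  fieldAdd(parts, quantity = "pst")
}

#' Fit surface-PST densities from the bouton balance
#'
#' Derives unknown surface-PST densities alpha from the assumption that, per
#' depth layer, the total bouton count matches the total PST count:
#' \code{B_all(z) - PST_spines(z) - PST_surface_known(z) = A(z) \%*\% alpha}.
#' The 3D fields are collapsed to the grid's depth axis and alpha is solved by
#' nonnegative least squares (\code{pracma::lsqnonneg}).
#'
#' Unknowns (rows of \code{meta} with \code{NA} \code{alpha_per_um2}) are tied
#' by default over (presynaptic excitatory class, post type, label), because a
#' single 1D profile cannot identify a full type-by-type-by-label tensor; pass
#' \code{tying = "full"} to fit each row separately.
#'
#' @param network a [NetworkModel-class]
#' @param meta meta-connectivity data.frame with \code{NA} alphas to fit.
#' @param boutonProfile optional depth profile of total boutons (length
#'   \code{dims[3]}). Default: computed from the network's axons.
#' @param tying \code{"class"} (default) or \code{"full"}.
#' @return list: \code{meta} (alphas filled), \code{alpha} (named vector of
#'   fitted group values), \code{residual} (per-depth residual profile).
#' @export
fitSurfacePST <- function(network, meta, boutonProfile = NULL,
                          tying = c("class", "full")) {
  tying <- match.arg(tying)
  grid <- network@frame@grid
  geo <- networkGeometry(network)
  types <- network@cellTypes
  if (is.null(boutonProfile)) {
    tot <- DensityField(grid, quantity = "boutons")
    for (id in names(geo$bouton))
      tot <- fieldAdd(tot, geo$bouton[[id]])
    boutonProfile <- fieldDepthProfile(tot)
  }
  nz <- grid@dims[3L]
  stopifnot(length(boutonProfile) == nz)
  # depth profiles of length/area per (post neuron type, label)
  postIds <- names(geo$length)
  postType <- network@neurons$cell_type[match(postIds, network@neurons$id)]
  profFor <- function(kind, type, lab) {
    ids <- postIds[postType == type]
    p <- numeric(nz)
    for (id in ids) {
      f <- geo[[kind]][[id]][[lab]]
      if (!is.null(f)) p <- p + fieldDepthProfile(f)
    }
    p
  }
  known <- !is.na(meta$alpha_per_um2)
  spines <- numeric(nz); surfKnown <- numeric(nz)
  for (r in seq_len(nrow(meta))) {
    if (!is.na(meta$lambda_per_um[r]) && meta$lambda_per_um[r] > 0)
      spines <- spines + meta$lambda_per_um[r] *
        profFor("length", meta$post_type[r], meta$label[r])
    if (known[r] && meta$alpha_per_um2[r] > 0)
      surfKnown <- surfKnown + meta$alpha_per_um2[r] *
        profFor("area", meta$post_type[r], meta$label[r])
  }
  unkRows <- which(!known)
  if (!length(unkRows))
    return(list(meta = meta, alpha = numeric(0),
                residual = boutonProfile - spines - surfKnown))
  preClass <- function(pt) {
    ex <- types$excitatory[match(pt, types$name)]
    if (isTRUE(ex)) "exc" else "inh"
  }
  groupOf <- vapply(unkRows, function(r) {
    if (tying == "full")
      paste(meta$pre_type[r], meta$post_type[r], meta$label[r], sep = ":")
    else
      paste(preClass(meta$pre_type[r]), meta$post_type[r], meta$label[r],
            sep = ":")
  }, character(1))
  groups <- unique(groupOf)
  A <- matrix(0, nz, length(groups), dimnames = list(NULL, groups))
  for (gi in seq_along(groups)) {
    rows <- unkRows[groupOf == groups[gi]]
    for (r in rows)
      A[, gi] <- A[, gi] + profFor("area", meta$post_type[r], meta$label[r])
  }
  keep <- colSums(A) > 0
  if (!all(keep))
    stop("surface-PST fit: no membrane area in the network for group(s): ",
         paste(groups[!keep], collapse = ", "), call. = FALSE)
  if (qr(A)$rank < ncol(A)) {
    stop("surface-PST fit: rank-deficient design; collinear group(s) among: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  b <- boutonProfile - spines - surfKnown
  fit <- pracma::lsqnonneg(A, b)
  alpha <- fit$x
  names(alpha) <- groups
  meta$alpha_per_um2[unkRows] <- alpha[groupOf]
  list(meta = meta, alpha = alpha, residual = b - drop(A %*% alpha))
}
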