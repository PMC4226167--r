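## Network assembly: place somata from density fields, assign cell types,
## select and rigidly transform dendrite morphologies, attach untransformed
## axons, and up-scale long-range axon types into a NetworkModel.

#' Sample soma positions from a density field
#'
#' Per voxel, the expected count \code{density * 1e3 * voxelVolume_mm3} is
#' rounded half-up to an integer and that many positions are drawn
#' independently and uniformly inside the voxel. Densities are in units of
#' 10^3 somata per mm^3.
#'
#' @param density 3D numeric array with \code{dim == dims(grid)}, >= 0.
#' @param grid a [VoxelGrid-class]
#' @param seed integer seed (reproducible).
#' @return n x 3 matrix of soma positions (um); zero rows if density is 0.
#' @export
sampleSomata <- function(density, grid, seed) {
  if (!all(dim(density) == grid@dims))
    stop("density array dimensions must match the grid", call. = FALSE)
  if (any(density < 0)) stop("soma density must be >= 0", call. = FALSE)
  counts <- roundHalfUp(as.numeric(density) * 1e3 * voxelVolumeMM3(grid))
  total <- sum(counts)
  if (total == 0) return(matrix(numeric(0), 0L, 3L))
  idx <- rep(seq_along(counts), counts)
  ijk <- linearToIjk(idx, grid)
  withSeed(seed, {
    u <- matrix(runif(3 * total), ncol = 3L)
    sweep((ijk + u) * grid@spacing, 2L, grid@origin, `+`)
  })
}

# Eligible cell types for a (region, inside) stratum, respecting occupancy
# flags, with their normalized frequencies.
.eligibleTypes <- function(columnId, inside, freqs, cellTypes) {
  fr <- freqs[freqs$region == columnId & freqs$inside_column == inside, ,
              drop = FALSE]
  fr <- fr[fr$frequency > 0, , drop = FALSE]
  if (nrow(fr)) {
    occ <- cellTypes$occupancy[match(fr$cell_type, cellTypes$name)]
    ok <- ifelse(inside, occ %in% c("column", "both"),
                 occ %in% c("septum", "both"))
    if (!all(ok))
      stop("frequency table lists type(s) violating occupancy in region '",
           columnId, "': ", paste(fr$cell_type[!ok], collapse = ", "),
           call. = FALSE)
  }
  if (!nrow(fr))
    stop("no eligible cell type for region '", columnId, "' (",
         if (inside) "column" else "septum", ")", call. = FALSE)
  if (abs(sum(fr$frequency) - 1) > 1e-9)
    stop("frequencies for region '", columnId, "' (",
         if (inside) "column" else "septum", ") must sum to 1", call. = FALSE)
  fr
}

#' Assign a cell type to a soma position
#'
#' Categorical draw over the cell types eligible for the soma's region (its
#' nearest column) and column/septum status, with the relative frequencies of
#' the frequency table.
#'
#' @param p numeric(3) soma position (um).
#' @param frame a [ReferenceFrame-class]
#' @param freqs frequency table ([readFrequencyTable]).
#' @param cellTypes cell-type table ([readCellTypeTable]).
#' @param seed integer seed.
#' @return cell-type name (character scalar).
#' @export
assignCellType <- function(p, frame, freqs, cellTypes, seed) {
  nc <- nearestColumn(p, frame)
  fr <- .eligibleTypes(nc$id, nc$inside, freqs, cellTypes)
  withSeed(seed,
    fr$cell_type[sample.int(nrow(fr), 1L, prob = fr$frequency)])
}

#' Read a morphology library manifest
#'
#' CSV with header \code{morphology_id,path,cell_type,column_id,soma_depth,kind}
#' where \code{kind} is \code{dendrite} or \code{axon} and \code{soma_depth}
#' is the depth (um along the registered column's axis) of the
#' reconstruction's soma.
#' @param path file path
#' @return data.frame
#' @export
readManifest <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("morphology_id", "path", "cell_type", "column_id", "soma_depth",
            "kind")
  if (!all(need %in% names(tb)))
    stop("manifest must have header: ", paste(need, collapse = ","),
         call. = FALSE)
  if (any(!tb$kind %in% c("dendrite", "axon")))
    stop("manifest kind must be dendrite or axon", call. = FALSE)
  tb$morphology_id <- as.character(tb$morphology_id)
  tb$column_id <- as.character(tb$column_id)
  tb
}

# signed azimuth from bearing b0 to b1 around unit axis u
.azimuthBetween <- function(b0, b1, u) {
  atan2(sum(pracma::cross(b0, b1) * u), sum(b0 * b1))
}

.perpComponent <- function(v, u) v - sum(v * u) * u

#' Select and transform a dendrite morphology for a new soma
#'
#' Candidates must (1) match the assigned cell type, (2) be registered to the
#' column nearest to the new soma, and (3) have their original soma within one
#' voxel spacing of the new soma's depth along that column's axis. One
#' candidate is chosen uniformly at random. The transform translates the
#' morphology soma to the new position and rotates it about the local vertical
#' axis: by a uniform random azimuth for ordinary types, or, for
#' \code{rotate_polar} types, by the azimuth that maps the reconstruction's
#' soma-to-column-center bearing onto the new soma's bearing (preserving polar
#' projections toward the column center).
#'
#' @param p numeric(3) new soma position (um).
#' @param cellType assigned cell-type name.
#' @param manifest morphology manifest ([readManifest]).
#' @param morphologies named list of [Morphology-class] (the library).
#' @param frame a [ReferenceFrame-class]
#' @param cellTypes cell-type table.
#' @param seed integer seed.
#' @return list with \code{id} (morphology id) and \code{transform}
#'   ([RigidTransform-class]).
#' @export
selectDendrite <- function(p, cellType, manifest, morphologies, frame,
                           cellTypes, seed) {
  nc <- nearestColumn(p, frame)
  depth <- columnDepth(p, frame, nc$id)
  cand <- manifest[manifest$kind == "dendrite", , drop = FALSE]
  c1 <- cand$cell_type == cellType
  c2 <- cand$column_id == nc$id
  c3 <- abs(cand$soma_depth - depth) <= frame@grid@spacing
  ok <- which(c1 & c2 & c3)
  if (!length(ok))
    stop(sprintf(paste0("no dendrite candidate for type '%s' near (%s): ",
                        "%d fail cell type, %d fail column, %d fail depth"),
                 cellType, paste(signif(p, 5), collapse = ", "),
                 sum(!c1), sum(c1 & !c2), sum(c1 & c2 & !c3)), call. = FALSE)
  pick <- withSeed(childSeed(seed, 1L), ok[sample.int(length(ok), 1L)])
  mid <- cand$morphology_id[pick]
  m <- morphologies[[mid]]
  u <- localAxis(p, frame)
  polar <- isTRUE(cellTypes$rotate_polar[match(cellType, cellTypes$name)])
  if (polar) {
    ci <- match(nc$id, frame@columns$id)
    ctr <- unlist(frame@columns[ci, c("cx", "cy", "cz")])
    b0 <- .perpComponent(ctr - somaPosition(m), u)
    b1 <- .perpComponent(ctr - p, u)
    theta <- if (vecNorm(b0) < 1e-9 || vecNorm(b1) < 1e-9) 0
             else .azimuthBetween(b0 / vecNorm(b0), b1 / vecNorm(b1), u)
  } else {
    theta <- withSeed(childSeed(seed, 2L), runif(1L, 0, 2 * pi))
  }
  list(id = mid,
       transform = RigidTransform(translation = p - somaPosition(m),
                                  rotation = rotationAboutAxis(u, theta)))
}

#' Select an axon morphology for a new soma
#'
#' Candidates must match the cell type and be registered to the column nearest
#' to the soma; one is chosen uniformly at random. Axons are deliberately NOT
#' transformed to the new soma location, so location-specific projection
#' patterns are preserved; the returned id refers to the library geometry
#' as-is.
#'
#' @inheritParams selectDendrite
#' @return morphology id (character scalar).
#' @export
selectAxon <- function(p, cellType, manifest, frame, seed) {
  nc <- nearestColumn(p, frame)
  cand <- manifest[manifest$kind == "axon", , drop = FALSE]
  ok <- which(cand$cell_type == cellType & cand$column_id == nc$id)
  if (!length(ok))
    stop(sprintf("no axon candidate for type '%s' in column '%s'",
                 cellType, nc$id), call. = FALSE)
  pick <- withSeed(seed, ok[sample.int(length(ok), 1L)])
  cand$morphology_id[pick]
}

#' Up-scale a long-range axon library by duplication
#'
#' Duplicates the library round-robin (in a seed-determined random order)
#' until \code{count} instances exist, so per-morphology multiplicities differ
#' by at most one. Axon geometry is never transformed.
#'
#' @param morphIds character vector of library morphology ids.
#' @param count target number of axon instances (>= 1).
#' @param seed integer seed.
#' @return character vector of length \code{count} of morphology ids.
#' @export
upscaleLongRange <- function(morphIds, count, seed) {
  stopifnot(length(morphIds) >= 1L, count >= 1L)
  perm <- withSeed(seed, sample(morphIds))
  rep_len(perm, count)
}

#' Assemble a dense network model
#'
#' Runs the full assembly pipeline: sample excitatory and inhibitory somata
#' from the density fields, label each soma with its nearest column,
#' column/septum status and a cell type drawn from the regional frequencies,
#' select and rigidly transform a dendrite morphology and select an
#' untransformed axon morphology for every soma, and up-scale long-range
#' axon-only cell types to their specified per-column counts.
#'
#' All randomness derives from \code{seed} through per-stage, per-neuron child
#' seeds, so results do not depend on iteration order.
#'
#' @param frame a [ReferenceFrame-class]
#' @param densityExc,densityInh 3D arrays of soma densities (10^3 per mm^3)
#'   for excitatory and inhibitory neurons.
#' @param cellTypes cell-type table ([readCellTypeTable]).
#' @param freqs frequency table ([readFrequencyTable]).
#' @param morphologies named list of [Morphology-class].
#' @param manifest morphology manifest ([readManifest]).
#' @param seed integer seed.
#' @param verbose log per-cell-type counts (default FALSE).
#' @return a [NetworkModel-class]
#' @export
buildNetwork <- function(frame, densityExc, densityInh, cellTypes, freqs,
                         morphologies, manifest, seed, verbose = FALSE) {
  miss <- setdiff(manifest$morphology_id, names(morphologies))
  if (length(miss))
    stop("assembly: manifest references missing morphologies: ",
         paste(miss, collapse = ", "), call. = FALSE)
  grid <- frame@grid
  ptsE <- sampleSomata(densityExc, grid, childSeed(seed, 101L))
  ptsI <- sampleSomata(densityInh, grid, childSeed(seed, 102L))
  pts <- rbind(ptsE, ptsI)
  excFlag <- c(rep(TRUE, nrow(ptsE)), rep(FALSE, nrow(ptsI)))
  n <- nrow(pts)
  ids <- sprintf("n%05d", seq_len(n))
  colId <- character(n); inside <- logical(n); type <- character(n)
  dend <- character(n); axon <- character(n)
  transforms <- list()
  freqsE <- freqs
  for (i in seq_len(n)) {
    p <- pts[i, ]
    nc <- nearestColumn(p, frame)
    colId[i] <- nc$id; inside[i] <- nc$inside
    # restrict the draw to types of the right excitatory class
    classTypes <- cellTypes$name[cellTypes$excitatory == excFlag[i] &
                                 !cellTypes$axon_only]
    frSub <- freqsE[freqsE$cell_type %in% classTypes, , drop = FALSE]
    type[i] <- assignCellType(p, frame, frSub, cellTypes,
                              childSeed(seed, 2L, i))
    sel <- selectDendrite(p, type[i], manifest, morphologies, frame,
                          cellTypes, childSeed(seed, 3L, i))
    dend[i] <- sel$id
    transforms[[ids[i]]] <- sel$transform
    axon[i] <- selectAxon(p, type[i], manifest, frame, childSeed(seed, 4L, i))
  }
  neurons <- data.frame(
    id = ids, x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
    column = colId, inside_column = inside, cell_type = type,
    excitatory = excFlag, dendrite_morph = dend, axon_morph = axon,
    stringsAsFactors = FALSE)
  # long-range axon-only types, up-scaled per registered column
  lr <- cellTypes[cellTypes$axon_only & !is.na(cellTypes$long_range_count), ,
                  drop = FALSE]
  for (t in seq_len(nrow(lr))) {
    tn <- lr$name[t]
    cols <- unique(manifest$column_id[manifest$cell_type == tn &
                                      manifest$kind == "axon"])
    if (!length(cols))
      stop("assembly: long-range type '", tn, "' has no axon morphologies",
           call. = FALSE)
    for (cid in cols) {
      lib <- manifest$morphology_id[manifest$cell_type == tn &
                                    manifest$kind == "axon" &
                                    manifest$column_id == cid]
      inst <- upscaleLongRange(lib, lr$long_range_count[t],
                               childSeed(seed, 5L, t, match(cid, cols)))
      for (q in seq_along(inst)) {
        sp <- somaPosition(morphologies[[inst[q]]])
        neurons <- rbind(neurons, data.frame(
          id = sprintf("lr_%s_%s_%04d", tn, cid, q),
          x = sp[1L], y = sp[2L], z = sp[3L],
          column = cid, inside_column = NA, cell_type = tn,
          excitatory = lr$excitatory[t],
          dendrite_morph = NA_character_, axon_morph = inst[q],
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(neurons) <- NULL
  if (verbose) {
    tb <- table(neurons$cell_type)
    message("assembled ", nrow(neurons), " neurons: ",
            paste(sprintf("%s=%d", names(tb), tb), collapse = ", "))
  }
  nm <- new("NetworkModel", frame = frame, neurons = neurons,
            morphologies = morphologies, transforms = transforms,
            cellTypes = cellTypes, cache = new.env(parent = emptyenv()))
  validObject(nm)
  nm
}

#' Neuron table of a network
#' @param network a [NetworkModel-class]
#' @return data.frame (one row per neuron)
#' @export
networkNeurons <- function(network) network@neurons

#' Concrete geometry of one placed neuron
#'
#' @param network a [NetworkModel-class]
#' @param id neuron id.
#' @param part \code{"dendrite"} (transformed) or \code{"axon"}
#'   (untransformed library geometry).
#' @return a [Morphology-class]
#' @export
placedMorphology <- function(network, id, part = c("dendrite", "axon")) {
  part <- match.arg(part)
  r <- match(id, network@neurons$id)
  if (is.na(r)) stop("unknown neuron id: ", id, call. = FALSE)
  mid <- network@neurons[[paste0(part, "_morph")]][r]
  if (is.na(mid)) stop("neuron ", id, " has no ", part, call. = FALSE)
  m <- network@morphologies[[mid]]
  if (part == "dendrite") applyTransform(m, network@transforms[[id]]) else m
}

# Per-neuron clipped geometry fields, memoized on the network's cache:
# $length[[id]][[label]], $area[[id]][[label]] (dendrite-bearing neurons),
# $bouton[[id]] (axon-bearing neurons; shared across duplicated axons).
networkGeometry <- function(network) {
  if (!is.null(network@cache$geometry)) return(network@cache$geometry)
  grid <- network@frame@grid
  nn <- network@neurons
  lenL <- list(); areaL <- list(); bout <- list()
  boutonByMorph <- list()
  droppedTotal <- 0
  for (r in seq_len(nrow(nn))) {
    id <- nn$id[r]
    if (!is.na(nn$dendrite_morph[r])) {
      dm <- placedMorphology(network, id, "dendrite")
      lf <- list(); af <- list()
      for (lab in c("soma", "apical", "basal")) {
        if (any(dm@nodes$label == lab)) {
          cl <- clipToVoxels(dm, lab, grid, warnDropped = FALSE)
          droppedTotal <- droppedTotal + attr(cl, "dropped")
          lf[[lab]] <- cl$length; af[[lab]] <- cl$area
        }
      }
      lenL[[id]] <- lf; areaL[[id]] <- af
    }
    if (!is.na(nn$axon_morph[r])) {
      key <- paste(nn$axon_morph[r], nn$cell_type[r])
      bf <- boutonByMorph[[key]]
      if (is.null(bf)) {
        am <- network@morphologies[[nn$axon_morph[r]]]
        cla <- clipToVoxels(am, "axon", grid, warnDropped = FALSE)
        droppedTotal <- droppedTotal + attr(cla, "dropped")
        axl <- cla$length
        trow <- network@cellTypes[match(nn$cell_type[r],
                                        network@cellTypes$name), ,
                                  drop = FALSE]
        bf <- boutonField(axl, trow, network@frame)
        boutonByMorph[[key]] <- bf
      }
      bout[[id]] <- bf
    }
  }
  if (droppedTotal > 0)
    warning(sprintf(
      "voxelization dropped %.4g um of branch length outside grid bounds",
      droppedTotal), call. = FALSE)
  geo <- list(length = lenL, area = areaL, bouton = bout)
  assign("geometry", geo, envir = network@cache)
  geo
}

#' @describeIn NetworkModel display a short summary
#' @param object a NetworkModel
#' @export
setMethod("show", "NetworkModel", function(object) {
  nn <- object@neurons
  cat(sprintf("NetworkModel: %d neurons (%d with dendrites), %d cell types\n",
              nrow(nn), sum(!is.na(nn$dendrite_morph)),
              length(unique(nn$cell_type))))
  show(object@frame)
})
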