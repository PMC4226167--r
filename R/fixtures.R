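## Synthetic fixture generation: emulates the seven anatomical input kinds
## (reference-frame tables, soma density fields, cell-type table, frequency
## table, SWC morphology library + manifest, meta-connectivity table,
## long-range axon counts) at toy scale, fully reproducible from a seed.
##
## The generated morphologies are parametric random trees, not biological
## reconstructions; they exercise geometry handling (labels, radii, branch
## structure, registration depth), not morphological realism.

#' Fixture configuration
#'
#' Defaults describe a two-column cortical slab: 50 um voxels, columns of
#' radius 75 um spanning a 450 um pia-to-white-matter depth with three
#' laminar zones, three local cell types (an ordinary excitatory pyramid-like
#' type, a polar excitatory spiny-stellate-like type confined to columns, an
#' inhibitory type) and one long-range thalamocortical axon-only type
#' up-scaled by duplication.
#'
#' @param nColumns number of columns (laid out in a row along x).
#' @param spacing voxel edge length (um).
#' @param dims grid dimensions (voxels per axis); \code{dims[3] * spacing} is
#'   the pia-to-WM depth.
#' @param columnRadius column radius (um).
#' @param zoneDepths strictly increasing depth breaks (um) delimiting the
#'   laminar zones; first must be 0 and last the full depth.
#' @param zoneNames zone names, one fewer than \code{zoneDepths}.
#' @param excDensity,inhDensity soma density values (10^3 per mm^3) used in
#'   the occupied voxels of the excitatory / inhibitory fields. The default 8
#'   gives exactly one soma per occupied 50 um voxel.
#' @param longRangeCount long-range axon instances per column after
#'   up-scaling.
#' @param axonLibrarySize long-range axon reconstructions per column before
#'   up-scaling.
#' @param dendriteLength,axonLength target total branch length per generated
#'   morphology (um).
#' @param segmentLength growth-step length (um).
#' @param seed integer seed for all generation.
#' @return a list of class \code{fixtureConfig}.
#' @export
fixtureConfig <- function(nColumns = 2L, spacing = 50, dims = c(10L, 6L, 9L),
                          columnRadius = 75, zoneDepths = NULL,
                          zoneNames = c("supragranular", "granular",
                                        "infragranular"),
                          excDensity = 8, inhDensity = 8,
                          longRangeCount = 8L, axonLibrarySize = 3L,
                          dendriteLength = 400, axonLength = 900,
                          segmentLength = 15, seed = 1L) {
  depth <- dims[3L] * spacing
  if (is.null(zoneDepths))
    zoneDepths <- round(c(0, depth / 3, depth * 5 / 9, depth))
  stopifnot(length(zoneDepths) == length(zoneNames) + 1L,
            zoneDepths[1L] == 0, zoneDepths[length(zoneDepths)] == depth)
  structure(list(nColumns = as.integer(nColumns), spacing = spacing,
                 dims = as.integer(dims), columnRadius = columnRadius,
                 zoneDepths = zoneDepths, zoneNames = zoneNames,
                 excDensity = excDensity, inhDensity = inhDensity,
                 longRangeCount = as.integer(longRangeCount),
                 axonLibrarySize = as.integer(axonLibrarySize),
                 dendriteLength = dendriteLength, axonLength = axonLength,
                 segmentLength = segmentLength, seed = as.integer(seed)),
            class = "fixtureConfig")
}

#' Build the synthetic reference frame
#'
#' Columns are laid out in a row along x with parallel vertical axes
#' (0, 0, 1), centers at mid-depth, and identical laminar zones; with this
#' layout the depth coordinate equals the z coordinate.
#'
#' @param cfg a [fixtureConfig]
#' @param dir optional directory; if given, \code{columns.csv} and
#'   \code{zones.csv} are written there.
#' @return a [ReferenceFrame-class]
#' @export
makeReferenceFrame <- function(cfg, dir = NULL) {
  depth <- cfg$dims[3L] * cfg$spacing
  xspan <- cfg$dims[1L] * cfg$spacing
  yc <- cfg$dims[2L] * cfg$spacing / 2
  xc <- xspan * (seq_len(cfg$nColumns)) / (cfg$nColumns + 1L)
  columns <- data.frame(
    id = sprintf("C%d", seq_len(cfg$nColumns)),
    cx = xc, cy = yc, cz = depth / 2,
    ax = 0, ay = 0, az = 1,
    radius = cfg$columnRadius, top_depth = 0, bottom_depth = depth,
    stringsAsFactors = FALSE)
  nz <- length(cfg$zoneNames)
  zones <- data.frame(
    column_id = rep(columns$id, each = nz),
    zone = rep(cfg$zoneNames, cfg$nColumns),
    depth_min = rep(cfg$zoneDepths[-(nz + 1L)], cfg$nColumns),
    depth_max = rep(cfg$zoneDepths[-1L], cfg$nColumns),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(columns, file.path(dir, "columns.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(zones, file.path(dir, "zones.csv"), row.names = FALSE,
              quote = FALSE)
  }
  grid <- VoxelGrid(c(0, 0, 0), cfg$spacing, cfg$dims)
  ReferenceFrame(grid, columns, zones)
}

#' Cell-type specification table of the fixture
#' @param cfg a [fixtureConfig]
#' @return data.frame in [readCellTypeTable] layout.
#' @export
makeCellTypeTable <- function(cfg) {
  data.frame(
    name = c("PYR", "SS", "INH", "TC"),
    excitatory = c(TRUE, TRUE, FALSE, TRUE),
    rotate_polar = c(FALSE, TRUE, FALSE, FALSE),
    axon_only = c(FALSE, FALSE, FALSE, TRUE),
    occupancy = c("both", "column", "both", "column"),
    bouton_supra = c(0.15, 0.20, 0.15, 0.10),
    bouton_gran = c(0.20, 0.30, 0.15, 0.35),
    bouton_infra = c(0.25, 0.20, 0.15, 0.15),
    long_range_count = c(NA, NA, NA, cfg$longRangeCount),
    stringsAsFactors = FALSE)
}

#' Cell-type frequency table of the fixture
#'
#' Inside columns, excitatory somata split 60/40 between the pyramid-like and
#' the polar type; in the septum all excitatory somata are pyramid-like (the
#' polar type occupies columns only). Inhibitory somata are one type.
#' @param cfg a [fixtureConfig]
#' @return data.frame in [readFrequencyTable] layout.
#' @export
makeFrequencyTable <- function(cfg) {
  cols <- sprintf("C%d", seq_len(cfg$nColumns))
  do.call(rbind, lapply(cols, function(cid) data.frame(
    region = cid,
    inside_column = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    cell_type = c("PYR", "SS", "INH", "PYR", "INH"),
    frequency = c(0.6, 0.4, 1.0, 1.0, 1.0),
    stringsAsFactors = FALSE)))
}

#' Meta-connectivity table of the fixture
#'
#' Excitatory presynaptic types target spines (length-PSTs, lambda per um) on
#' excitatory dendrites and membrane surface (alpha per um^2) on inhibitory
#' neurons; the inhibitory type targets somata and dendritic shafts of all
#' types via surface PSTs.
#' @param alphaSoma,alphaDend surface-PST densities (per um^2) used for the
#'   surface-targeted entries; pass \code{NA} to mark them for fitting.
#' @return data.frame in [readMetaConnectivity] layout.
#' @export
makeMetaConnectivity <- function(alphaSoma = 0.4, alphaDend = 0.1) {
  rows <- list()
  excPre <- c("PYR", "SS", "TC")
  for (pre in excPre) {
    for (post in c("PYR", "SS")) {
      labs <- if (post == "SS") "basal" else c("basal", "apical")
      for (lab in labs)
        rows[[length(rows) + 1L]] <- data.frame(
          pre_type = pre, post_type = post, label = lab,
          lambda_per_um = 1.0, alpha_per_um2 = 0)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pre_type = pre, post_type = "INH", label = "soma",
      lambda_per_um = 0, alpha_per_um2 = alphaSoma)
    rows[[length(rows) + 1L]] <- data.frame(
      pre_type = pre, post_type = "INH", label = "basal",
      lambda_per_um = 0, alpha_per_um2 = alphaDend)
  }
  for (post in c("PYR", "SS", "INH")) {
    labs <- c("soma", "basal", if (post == "PYR") "apical")
    al <- c(alphaSoma, alphaDend, if (post == "PYR") alphaDend)
    for (q in seq_along(labs))
      rows[[length(rows) + 1L]] <- data.frame(
        pre_type = "INH", post_type = post, label = labs[q],
        lambda_per_um = 0, alpha_per_um2 = al[q])
  }
  metaConnectivity(do.call(rbind, rows))
}

#' Soma density fields of the fixture
#'
#' Excitatory density is constant in every voxel whose center lies inside a
#' column; inhibitory density occupies a deterministic sparse subset of
#' septum voxels (a lattice pattern standing in for the lower, column-blind
#' inhibitory density of real tissue).
#'
#' @param cfg a [fixtureConfig]
#' @param frame the matching [ReferenceFrame-class]
#' @return list with 3D arrays \code{exc} and \code{inh} (10^3 per mm^3).
#' @export
makeSomaDensities <- function(cfg, frame) {
  grid <- frame@grid
  ctrs <- voxelCenters(grid)
  inside <- vapply(seq_len(nrow(ctrs)),
                   function(r) nearestColumn(ctrs[r, ], frame)$inside,
                   logical(1))
  exc <- array(0, grid@dims)
  exc[inside] <- cfg$excDensity
  ijk <- linearToIjk(seq_len(nVoxels(grid)), grid)
  patt <- (ijk[, 1L] + 2L * ijk[, 2L] + 3L * ijk[, 3L]) %% 7L == 0L
  inh <- array(0, grid@dims)
  inh[!inside & patt] <- cfg$inhDensity
  list(exc = exc, inh = inh)
}

# one growth step: persistent direction with jitter, reflected at the walls
# of `box` (a list lower/upper with margin applied)
.growStep <- function(pos, dir, step, wobble, bias, box) {
  d <- dir + wobble * rnorm(3) + bias
  d <- d / max(vecNorm(d), 1e-12)
  nxt <- pos + step * d
  for (a in 1:3) {
    if (nxt[a] < box$lower[a] || nxt[a] > box$upper[a]) {
      d[a] <- -d[a]
      nxt <- pos + step * d
    }
  }
  list(pos = nxt, dir = d)
}

#' Generate a random labeled morphology
#'
#' Grows a rooted branching tree from a single-point soma until the requested
#' total branch length is reached: active tips advance by persistent random
#' walk (optionally biased toward a reference bearing for the polar kind) and
#' occasionally branch. Radii taper exponentially with path distance from the
#' soma. Geometry is kept inside \code{box} by reflecting growth directions.
#'
#' @param kind \code{"dendrite"} (one apical + basal stems),
#'   \code{"polar_dendrite"} (all basal, growth biased toward
#'   \code{bearing}) or \code{"axon"}.
#' @param soma numeric(3) soma position (um).
#' @param totalLength target total branch length (um); the result is within
#'   one growth step of the target.
#' @param seed integer seed.
#' @param box list \code{lower}/\code{upper}: bounding box for the geometry.
#' @param bearing numeric(3): reference direction for the polar kind.
#' @param cellType,column identifiers stored on the morphology.
#' @param segmentLength growth step (um).
#' @return a [Morphology-class]
#' @export
makeMorphology <- function(kind = c("dendrite", "polar_dendrite", "axon"),
                           soma, totalLength, seed, box,
                           bearing = c(1, 0, 0),
                           cellType = NA_character_, column = NA_character_,
                           segmentLength = 15) {
  kind <- match.arg(kind)
  withSeed(seed, {
    somaR <- 5
    nodes <- data.frame(x = soma[1L], y = soma[2L], z = soma[3L],
                        radius = somaR, label = "soma", parent = NA_integer_,
                        stringsAsFactors = FALSE)
    bearU <- bearing / max(vecNorm(bearing), 1e-12)
    nStems <- if (kind == "axon") 2L else 3L
    stems <- lapply(seq_len(nStems), function(s) {
      d <- switch(kind,
        dendrite = if (s == 1L) c(0, 0, -1) + 0.3 * rnorm(3)
                   else rnorm(3),
        polar_dendrite = bearU + 0.4 * rnorm(3),
        axon = rnorm(3))
      d <- d / max(vecNorm(d), 1e-12)
      lab <- switch(kind, dendrite = if (s == 1L) "apical" else "basal",
                    polar_dendrite = "basal", axon = "axon")
      list(node = 1L, dir = d, dist = 0, label = lab)
    })
    bias <- if (kind == "polar_dendrite") 0.35 * bearU else c(0, 0, 0)
    wobble <- if (kind == "axon") 0.6 else 0.4
    r0 <- if (kind == "axon") 0.5 else 1.2
    rmin <- 0.3
    total <- 0
    tips <- stems
    while (total < totalLength && length(tips)) {
      ti <- sample.int(length(tips), 1L)
      tip <- tips[[ti]]
      from <- unlist(nodes[tip$node, c("x", "y", "z")])
      st <- .growStep(from, tip$dir, segmentLength, wobble, bias, box)
      dist <- tip$dist + segmentLength
      rad <- max(r0 * exp(-dist / 400), rmin)
      nodes <- rbind(nodes, data.frame(
        x = st$pos[1L], y = st$pos[2L], z = st$pos[3L], radius = rad,
        label = tip$label, parent = tip$node, stringsAsFactors = FALSE))
      newIdx <- nrow(nodes)
      total <- total + segmentLength
      tips[[ti]] <- list(node = newIdx, dir = st$dir, dist = dist,
                         label = tip$label)
      if (runif(1) < 0.10) {
        bd <- st$dir + 0.8 * rnorm(3)
        tips[[length(tips) + 1L]] <- list(node = newIdx,
                                          dir = bd / max(vecNorm(bd), 1e-12),
                                          dist = dist, label = tip$label)
      }
    }
    Morphology(nodes, cellType = cellType, column = column)
  })
}

# interior box for morphology growth: the grid bounds shrunk by a margin
.growthBox <- function(cfg, margin = 5) {
  depth <- cfg$dims * cfg$spacing
  list(lower = c(0, 0, 0) + margin, upper = depth - margin)
}

#' Generate the fixture morphology library and manifest
#'
#' For every column and dendrite-bearing cell type, one dendrite
#' reconstruction per 50 um depth step (so the assembly depth criterion
#' always finds a candidate), plus per-column axon reconstructions for local
#' types and \code{axonLibrarySize} long-range axons for the thalamocortical
#' type. Library somata sit 40 um off the column axis so polar bearings are
#' well defined.
#'
#' @param cfg a [fixtureConfig]
#' @param frame the matching [ReferenceFrame-class]
#' @param dir optional directory; if given, SWC files and \code{manifest.csv}
#'   are written under it.
#' @return list with \code{morphologies} (named list) and \code{manifest}
#'   (data.frame).
#' @export
makeLibrary <- function(cfg, frame, dir = NULL) {
  types <- makeCellTypeTable(cfg)
  box <- .growthBox(cfg)
  depth <- cfg$dims[3L] * cfg$spacing
  depthSteps <- seq(cfg$spacing / 2, depth - cfg$spacing / 2,
                    by = cfg$spacing)
  morphs <- list()
  man <- list()
  addRow <- function(id, type, cid, sdep, kind) {
    man[[length(man) + 1L]] <<- data.frame(
      morphology_id = id, path = paste0("swc/", id, ".swc"),
      cell_type = type, column_id = cid, soma_depth = sdep, kind = kind,
      stringsAsFactors = FALSE)
  }
  for (ci in seq_len(nrow(frame@columns))) {
    col <- frame@columns[ci, ]
    ctr <- c(col$cx, col$cy, col$cz)
    for (tn in types$name[!types$axon_only]) {
      polar <- types$rotate_polar[types$name == tn]
      for (q in seq_along(depthSteps)) {
        dep <- depthSteps[q]
        soma <- c(col$cx + 40, col$cy, dep)
        id <- sprintf("d_%s_%s_%02d", tn, col$id, q)
        morphs[[id]] <- makeMorphology(
          if (polar) "polar_dendrite" else "dendrite",
          soma = soma, totalLength = cfg$dendriteLength,
          seed = childSeed(cfg$seed, 11L, ci, match(tn, types$name), q),
          box = box, bearing = c(ctr[1L] - soma[1L], ctr[2L] - soma[2L], 0),
          cellType = tn, column = col$id,
          segmentLength = cfg$segmentLength)
        addRow(id, tn, col$id, dep, "dendrite")
      }
      for (q in 1:2) {
        dep <- depth * q / 3
        soma <- c(col$cx - 30, col$cy + 20, dep)
        id <- sprintf("a_%s_%s_%02d", tn, col$id, q)
        morphs[[id]] <- makeMorphology(
          "axon", soma = soma, totalLength = cfg$axonLength,
          seed = childSeed(cfg$seed, 12L, ci, match(tn, types$name), q),
          box = box, cellType = tn, column = col$id,
          segmentLength = cfg$segmentLength)
        addRow(id, tn, col$id, dep, "axon")
      }
    }
    for (q in seq_len(cfg$axonLibrarySize)) {
      dep <- depth - cfg$spacing / 2
      soma <- c(col$cx, col$cy, dep)
      id <- sprintf("a_TC_%s_%02d", col$id, q)
      morphs[[id]] <- makeMorphology(
        "axon", soma = soma, totalLength = cfg$axonLength,
        seed = childSeed(cfg$seed, 13L, ci, q), box = box,
        cellType = "TC", column = col$id,
        segmentLength = cfg$segmentLength)
      addRow(id, "TC", col$id, dep, "axon")
    }
  }
  manifest <- do.call(rbind, man)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "swc"), showWarnings = FALSE, recursive = TRUE)
    for (id in names(morphs))
      writeSWC(morphs[[id]], file.path(dir, "swc", paste0(id, ".swc")))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
              quote = FALSE)
  }
  list(morphologies = morphs, manifest = manifest)
}

#' Generate the complete fixture input bundle
#'
#' Emulates all seven input kinds in memory and (optionally) on disk:
#' reference-frame tables, soma density fields (sparse CSV), cell-type,
#' frequency and meta-connectivity tables, the SWC morphology library with
#' its manifest (including the long-range axon counts via the cell-type
#' table), and a small JSON run config holding the seed and grid.
#'
#' @param cfg a [fixtureConfig]
#' @param dir optional output directory.
#' @return list: \code{frame}, \code{densities} (exc/inh arrays),
#'   \code{cellTypes}, \code{freqs}, \code{meta}, \code{morphologies},
#'   \code{manifest}, \code{cfg}.
#' @export
makeFixtureBundle <- function(cfg = fixtureConfig(), dir = NULL) {
  frame <- makeReferenceFrame(cfg, dir)
  dens <- makeSomaDensities(cfg, frame)
  lib <- makeLibrary(cfg, frame, dir)
  types <- makeCellTypeTable(cfg)
  freqs <- makeFrequencyTable(cfg)
  meta <- makeMetaConnectivity()
  if (!is.null(dir)) {
    write.csv(types, file.path(dir, "cell_types.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(freqs, file.path(dir, "frequencies.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(meta, file.path(dir, "meta_connectivity.csv"),
              row.names = FALSE, quote = FALSE)
    for (w in c("exc", "inh")) {
      arr <- dens[[w]]
      idx <- which(arr > 0)
      f <- DensityField(frame@grid, idx, arr[idx], paste0("soma_", w))
      writeFieldCSV(f, file.path(dir, paste0("density_", w, ".csv")))
    }
    writeLines(sprintf(
      '{"seed": %d, "origin": [0, 0, 0], "spacing": %g, "dims": [%s]}',
      cfg$seed, cfg$spacing, paste(cfg$dims, collapse = ", ")),
      file.path(dir, "config.json"))
  }
  list(frame = frame, densities = dens, cellTypes = types, freqs = freqs,
       meta = meta, morphologies = lib$morphologies,
       manifest = lib$manifest, cfg = cfg)
}

#' Read a fixture bundle from disk
#'
#' Inverse of [makeFixtureBundle] with a directory argument.
#' @param dir bundle directory.
#' @return the same structure as [makeFixtureBundle] (without \code{cfg};
#'   grid parameters are taken from \code{config.json}).
#' @export
readFixtureBundle <- function(dir) {
  cfgLine <- paste(readLines(file.path(dir, "config.json")), collapse = "")
  num <- function(key) {
    m <- regmatches(cfgLine,
                    regexec(paste0('"', key, '":\\s*\\[?([0-9eE+., -]+)'),
                            cfgLine))[[1L]][2L]
    v <- suppressWarnings(as.numeric(strsplit(m, ",")[[1L]]))
    v[!is.na(v)]
  }
  grid <- VoxelGrid(num("origin"), num("spacing"), as.integer(num("dims")))
  columns <- readColumnTable(file.path(dir, "columns.csv"))
  zones <- readZoneTable(file.path(dir, "zones.csv"))
  frame <- ReferenceFrame(grid, columns, zones)
  types <- readCellTypeTable(file.path(dir, "cell_types.csv"))
  freqs <- readFrequencyTable(file.path(dir, "frequencies.csv"))
  meta <- readMetaConnectivity(file.path(dir, "meta_connectivity.csv"))
  manifest <- readManifest(file.path(dir, "manifest.csv"))
  morphs <- list()
  for (r in seq_len(nrow(manifest)))
    morphs[[manifest$morphology_id[r]]] <-
      readSWC(file.path(dir, manifest$path[r]),
              cellType = manifest$cell_type[r],
              column = manifest$column_id[r])
  dens <- lapply(c(exc = "exc", inh = "inh"), function(w) {
    tb <- read.csv(file.path(dir, paste0("density_", w, ".csv")))
    arr <- array(0, grid@dims)
    arr[ijkToLinear(as.matrix(tb[, c("i", "j", "k")]), grid)] <- tb$value
    arr
  })
  list(frame = frame, densities = dens, cellTypes = types, freqs = freqs,
       meta = meta, morphologies = morphs, manifest = manifest,
       seed = as.integer(num("seed")))
}

#' Assemble the fixture network
#'
#' Convenience wrapper: [makeFixtureBundle] + [buildNetwork].
#' @param cfg a [fixtureConfig]
#' @param seed assembly seed (default: the config seed).
#' @return list: \code{network} ([NetworkModel-class]), \code{bundle}.
#' @export
makeFixtureNetwork <- function(cfg = fixtureConfig(), seed = cfg$seed) {
  b <- makeFixtureBundle(cfg)
  net <- buildNetwork(b$frame, b$densities$exc, b$densities$inh, b$cellTypes,
                      b$freqs, b$morphologies, b$manifest, seed)
  list(network = net, bundle = b)
}

#' Generate the ground-truth micro-network and its oracle inputs
#'
#' A deliberately tiny bundle (single column, a handful of somata, two
#' long-range axons; at most 10 neurons) for which every pipeline output can
#' be recomputed by dense brute force ([oracleInnervation]). Also returns the
#' known surface-PST densities \code{alphaStar} together with the balanced
#' bouton depth profile they imply, for the parameter-recovery check of
#' [fitSurfacePST].
#'
#' @param seed integer seed.
#' @return list: \code{network}, \code{meta} (alphas = alphaStar),
#'   \code{metaUnknown} (alphas = NA, to be fitted), \code{alphaStar},
#'   \code{balancedBoutonProfile}, \code{bundle}.
#' @export
makeGroundTruthNetwork <- function(seed = 1L) {
  cfg <- fixtureConfig(nColumns = 1L, dims = c(6L, 6L, 9L),
                       longRangeCount = 2L, axonLibrarySize = 2L,
                       dendriteLength = 300, axonLength = 600, seed = seed)
  b <- makeFixtureBundle(cfg)
  # hand-picked occupied voxels: 4 excitatory inside the column, 1
  # inhibitory in the septum
  grid <- b$frame@grid
  exc <- array(0, grid@dims)
  for (ijk in list(c(2L, 2L, 2L), c(3L, 3L, 4L), c(2L, 3L, 6L),
                   c(3L, 2L, 7L)))
    exc[ijkToLinear(matrix(ijk, 1L), grid)] <- cfg$excDensity
  inh <- array(0, grid@dims)
  inh[ijkToLinear(matrix(c(0L, 1L, 3L), 1L), grid)] <- cfg$inhDensity
  b$densities <- list(exc = exc, inh = inh)
  net <- buildNetwork(b$frame, exc, inh, b$cellTypes, b$freqs,
                      b$morphologies, b$manifest, childSeed(seed, 99L))
  alphaStar <- c(alphaSoma = 0.4, alphaDend = 0.1)
  meta <- makeMetaConnectivity(alphaStar[1L], alphaStar[2L])
  # leave only the excitatory -> inhibitory surface densities unknown: the
  # two tied groups (exc:INH:soma, exc:INH:basal) have distinct depth
  # profiles, so the 1D balance fit is identifiable
  metaUnknown <- meta
  unk <- metaUnknown$post_type == "INH" & metaUnknown$pre_type != "INH"
  metaUnknown$alpha_per_um2[unk] <- NA_real_
  # bouton depth profile that exactly balances spines + alphaStar surfaces
  fit0 <- fitSurfacePST(net, meta, boutonProfile = rep(0, grid@dims[3L]))
  balanced <- -fit0$residual
  list(network = net, meta = meta, metaUnknown = metaUnknown,
       alphaStar = alphaStar, balancedBoutonProfile = balanced,
       bundle = b)
}
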