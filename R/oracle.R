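## Dense brute-force oracle for validating the sparse pipeline on tiny
## networks. Deliberately independent of the production code paths: segments
## are clipped per voxel by Liang-Barsky slab intersection over dense arrays
## (production subdivides at plane crossings into sparse fields), laminar
## zones are looked up by raw z-depth (valid for fixtures with vertical
## column axes), and all sums run over full dense arrays.

# length and lateral area of one segment inside one voxel AABB
.slabClip <- function(p0, p1, r0, r1, lo, hi) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (a in 1:3) {
    if (d[a] == 0) {
      if (p0[a] < lo[a] || p0[a] >= hi[a]) return(c(0, 0))
    } else {
      ta <- (lo[a] - p0[a]) / d[a]
      tb <- (hi[a] - p0[a]) / d[a]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 >= t1) return(c(0, 0))
    }
  }
  L <- sqrt(sum(d * d))
  len <- (t1 - t0) * L
  ra <- r0 + t0 * (r1 - r0); rb <- r0 + t1 * (r1 - r0)
  c(len, pi * (ra + rb) * len)
}

# dense per-voxel length/area arrays for one label of a morphology
oracleClipLabel <- function(m, label, grid) {
  nd <- m@nodes
  lenArr <- array(0, grid@dims)
  areaArr <- array(0, grid@dims)
  ch <- which(nd$label == label & !is.na(nd$parent))
  for (c in ch) {
    pa <- nd$parent[c]
    p0 <- unlist(nd[pa, c("x", "y", "z")])
    p1 <- unlist(nd[c, c("x", "y", "z")])
    bb0 <- pmax(floor((pmin(p0, p1) - grid@origin) / grid@spacing), 0)
    bb1 <- pmin(floor((pmax(p0, p1) - grid@origin) / grid@spacing),
                grid@dims - 1L)
    if (any(bb0 > bb1)) next
    for (i in bb0[1L]:bb1[1L]) for (j in bb0[2L]:bb1[2L])
      for (k in bb0[3L]:bb1[3L]) {
        lo <- grid@origin + c(i, j, k) * grid@spacing
        hi <- lo + grid@spacing
        la <- .slabClip(p0, p1, nd$radius[pa], nd$radius[c], lo, hi)
        idx <- ijkToLinear(matrix(c(i, j, k), 1L), grid)
        lenArr[idx] <- lenArr[idx] + la[1L]
        areaArr[idx] <- areaArr[idx] + la[2L]
      }
  }
  if (label == "soma" && !length(ch)) {
    s <- which(nd$label == "soma")
    if (length(s) == 1L) {
      p <- unlist(nd[s, c("x", "y", "z")])
      ijk <- floor((p - grid@origin) / grid@spacing)
      if (all(ijk >= 0) && all(ijk < grid@dims)) {
        idx <- ijkToLinear(matrix(as.integer(ijk), 1L), grid)
        areaArr[idx] <- areaArr[idx] + 4 * pi * nd$radius[s]^2
      }
    }
  }
  list(length = lenArr, area = areaArr)
}

# zone of every voxel by raw depth (requires all column axes == (0,0,1))
.oracleVoxelZones <- function(frame) {
  cl <- frame@columns
  stopifnot(all(abs(cl$ax) < 1e-12), all(abs(cl$ay) < 1e-12))
  grid <- frame@grid
  zc <- voxelCenters(grid)[, 3L]
  z <- frame@zones[frame@zones$column_id == cl$id[1L], , drop = FALSE]
  out <- rep("outside", length(zc))
  for (r in seq_len(nrow(z)))
    out[zc >= z$depth_min[r] & zc < z$depth_max[r]] <- z$zone[r]
  out
}

#' Dense brute-force recomputation of the innervation pipeline
#'
#' Recomputes, from the placed geometry alone and over full dense arrays,
#' the bouton fields, PST fields, per-voxel target probabilities, pairwise
#' innervation fields and totals, and pairwise connection probabilities.
#' Intended for networks of at most a dozen neurons; shares no computation
#' code with the sparse production path.
#'
#' @param network a [NetworkModel-class] whose columns all have vertical
#'   axes.
#' @param meta meta-connectivity table with all alphas resolved.
#' @return list: \code{I} (dense pre x post matrix of total innervation,
#'   dimnames = neuron ids), \code{p} (connection probabilities),
#'   \code{boutons} (named list of dense arrays), \code{pstAll} (named list
#'   by pre type), \code{Itilde} (list of lists of dense arrays).
#' @export
oracleInnervation <- function(network, meta) {
  grid <- network@frame@grid
  nn <- network@neurons
  zones <- .oracleVoxelZones(network@frame)
  types <- network@cellTypes
  preIds <- nn$id[!is.na(nn$axon_morph)]
  postIds <- nn$id[!is.na(nn$dendrite_morph)]
  # dense per-label geometry of every dendrite-bearing neuron
  geom <- list()
  for (j in postIds) {
    dm <- applyTransform(network@morphologies[[
      nn$dendrite_morph[match(j, nn$id)]]],
      network@transforms[[j]])
    geom[[j]] <- lapply(c(soma = "soma", apical = "apical", basal = "basal"),
                        function(lab) oracleClipLabel(dm, lab, grid))
  }
  # dense bouton array per presynaptic neuron
  boutons <- list()
  for (i in preIds) {
    am <- network@morphologies[[nn$axon_morph[match(i, nn$id)]]]
    lenArr <- oracleClipLabel(am, "axon", grid)$length
    tn <- nn$cell_type[match(i, nn$id)]
    trow <- types[match(tn, types$name), , drop = FALSE]
    dens <- c(unlist(trow[, c("bouton_supra", "bouton_gran",
                              "bouton_infra")]), 0)
    names(dens) <- c("supragranular", "granular", "infragranular", "outside")
    boutons[[i]] <- array(lenArr * dens[zones], grid@dims)
  }
  densePst <- function(j, preType) {
    jt <- nn$cell_type[match(j, nn$id)]
    acc <- array(0, grid@dims)
    for (lab in c("soma", "apical", "basal")) {
      lam <- .metaLookup(meta, preType, jt, lab, "lambda_per_um")
      alp <- .metaLookup(meta, preType, jt, lab, "alpha_per_um2")
      acc <- acc + lam * geom[[j]][[lab]]$length +
        alp * geom[[j]][[lab]]$area
    }
    acc
  }
  pstAll <- list()
  for (pt in unique(nn$cell_type[match(preIds, nn$id)])) {
    acc <- array(0, grid@dims)
    for (j in postIds) acc <- acc + densePst(j, pt)
    pstAll[[pt]] <- acc
  }
  I <- matrix(0, length(preIds), length(postIds),
              dimnames = list(preIds, postIds))
  Itilde <- list()
  for (i in preIds) {
    pt <- nn$cell_type[match(i, nn$id)]
    Itilde[[i]] <- list()
    for (j in postIds) {
      pstJ <- densePst(j, pt)
      tot <- pstAll[[pt]]
      pj <- array(0, grid@dims)
      nz <- tot > 0
      pj[nz] <- pstJ[nz] / tot[nz]
      It <- boutons[[i]] * pj
      Itilde[[i]][[j]] <- It
      I[i, j] <- sum(It)
    }
  }
  list(I = I, p = 1 - exp(-I), boutons = boutons, pstAll = pstAll,
       Itilde = Itilde)
}

#' Motif spectrum by graph-isomorphism oracle
#'
#' Independent recomputation of [tripletSpectrum]: enumerates the 64 directed
#' 3-node graphs, groups them with \pkg{igraph}'s isomorphism test, and sums
#' configuration probabilities per group. Returns the spectrum aligned to the
#' production class numbering via matching representatives.
#'
#' @param p numeric(6) edge probabilities (order p12, p21, p13, p31, p23,
#'   p32).
#' @return data.frame \code{motif_id, probability} (production numbering).
#' @export
oracleTripletSpectrum <- function(p) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("oracleTripletSpectrum needs the igraph package", call. = FALSE)
  pairs <- .EDGE_PAIRS
  graphs <- lapply(0:63, function(code) {
    bits <- .configBits(code)
    el <- pairs[bits, , drop = FALSE]
    igraph::add_edges(igraph::make_empty_graph(3, directed = TRUE),
                      as.integer(t(el)))
  })
  group <- rep(NA_integer_, 64L)
  reps <- integer(0)
  for (c in 1:64) {
    placed <- FALSE
    for (g in seq_along(reps)) {
      if (igraph::isomorphic(graphs[[c]], graphs[[reps[g]]])) {
        group[c] <- g; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, c); group[c] <- length(reps) }
  }
  probs <- vapply(0:63, function(code) {
    b <- .configBits(code)
    prod(ifelse(b, p, 1 - p))
  }, numeric(1))
  bygroup <- rowsum(probs, group)
  # align to production numbering through the class of each representative
  prodClassOf <- motifClasses()$classOf
  mid <- prodClassOf[reps]
  data.frame(motif_id = mid, probability = as.numeric(bygroup))[order(mid), ]
}
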