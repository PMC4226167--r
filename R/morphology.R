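## Labeled neuron morphologies: SWC I/O, measurements, rigid transforms.
##
## SWC v1 dialect: 7 whitespace-separated columns
##   id structure x y z radius parent
## with '#' comments, 1-based ids, parent -1 for roots. Structure codes are
## mapped 1 -> soma, 2 -> axon, 3 -> basal (dendrite), 4 -> apical (dendrite);
## any other code is rejected. Radii in the file are radii (not diameters).

.SWC_CODES <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L)

#' Construct a morphology from a node table
#'
#' @param nodes data.frame with columns \code{x,y,z,radius,label,parent}
#'   (parent: 1-based row index, \code{NA} for roots).
#' @param cellType,column optional identifiers (cell type; registered
#'   substructure).
#' @return a [Morphology-class]
#' @export
Morphology <- function(nodes, cellType = NA_character_, column = NA_character_) {
  nodes <- as.data.frame(nodes)
  nodes$label <- as.character(nodes$label)
  nodes$parent <- as.integer(nodes$parent)
  rownames(nodes) <- NULL
  soma <- nodes$label == "soma"
  sp <- if (any(soma)) colMeans(nodes[soma, c("x", "y", "z")])
        else unlist(nodes[which(is.na(nodes$parent))[1L], c("x", "y", "z")])
  m <- new("Morphology", nodes = nodes, cellType = as.character(cellType),
           column = as.character(column), somaPosition = as.numeric(sp))
  validObject(m)
  m
}

#' Soma position of a morphology
#'
#' The unweighted centroid of the soma-labeled nodes (the first root node if
#' no node is labeled soma).
#' @param m a [Morphology-class]
#' @return numeric(3)
#' @export
somaPosition <- function(m) m@somaPosition

#' Node table of a morphology
#' @param m a [Morphology-class]
#' @return data.frame
#' @export
morphologyNodes <- function(m) m@nodes

#' Read an SWC morphology file
#'
#' @param path SWC file path.
#' @param cellType,column optional identifiers attached to the result.
#' @return a validated [Morphology-class]
#' @export
readSWC <- function(path, cellType = NA_character_, column = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineNo <- which(keep)
  rows <- strsplit(trimws(raw[keep]), "\\s+")
  if (!length(rows)) stop("SWC file has no data lines: ", path, call. = FALSE)
  bad <- which(lengths(rows) != 7L)
  if (length(bad))
    stop(sprintf("SWC parse error at line %d: expected 7 fields", lineNo[bad[1L]]),
         call. = FALSE)
  mat <- matrix(as.numeric(unlist(rows)), ncol = 7L, byrow = TRUE)
  if (any(!is.finite(mat)))
    stop(sprintf("SWC parse error at line %d: non-numeric field",
                 lineNo[which(rowSums(!is.finite(mat)) > 0)[1L]]), call. = FALSE)
  ids <- as.integer(mat[, 1L]); codes <- as.integer(mat[, 2L])
  unk <- which(!codes %in% .SWC_CODES)
  if (length(unk))
    stop(sprintf("SWC parse error at line %d: unknown structure code %d",
                 lineNo[unk[1L]], codes[unk[1L]]), call. = FALSE)
  neg <- which(mat[, 6L] < 0)
  if (length(neg))
    stop(sprintf("SWC parse error at line %d: negative radius", lineNo[neg[1L]]),
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("SWC parse error: duplicated node ids", call. = FALSE)
  par <- as.integer(mat[, 7L])
  parIdx <- ifelse(par == -1L, NA_integer_, match(par, ids))
  orphan <- which(par != -1L & is.na(parIdx))
  if (length(orphan))
    stop(sprintf("SWC parse error at line %d: orphan node (parent %d undefined)",
                 lineNo[orphan[1L]], par[orphan[1L]]), call. = FALSE)
  nodes <- data.frame(
    x = mat[, 3L], y = mat[, 4L], z = mat[, 5L], radius = mat[, 6L],
    label = names(.SWC_CODES)[match(codes, .SWC_CODES)],
    parent = parIdx, stringsAsFactors = FALSE)
  tryCatch(Morphology(nodes, cellType = cellType, column = column),
           error = function(e)
             stop("SWC parse error in ", path, ": ", conditionMessage(e),
                  call. = FALSE))
}

#' Write a morphology as SWC
#'
#' Emits the same 7-column dialect accepted by [readSWC].
#' @param m a [Morphology-class]
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSWC <- function(m, path) {
  nd <- m@nodes
  par <- ifelse(is.na(nd$parent), -1L, nd$parent)
  lines <- sprintf("%d %d %.12g %.12g %.12g %.12g %d",
                   seq_len(nrow(nd)), .SWC_CODES[nd$label],
                   nd$x, nd$y, nd$z, nd$radius, par)
  writeLines(c("# SWC generated by DenseConnectome", lines), path)
  invisible(path)
}

# Parent-child segments whose child carries `label`: start/end positions and
# radii, as a list of matrices/vectors.
.labelSegments <- function(m, label) {
  nd <- m@nodes
  ch <- which(nd$label == label & !is.na(nd$parent))
  pa <- nd$parent[ch]
  list(p0 = as.matrix(nd[pa, c("x", "y", "z")]),
       p1 = as.matrix(nd[ch, c("x", "y", "z")]),
       r0 = nd$radius[pa], r1 = nd$radius[ch])
}

#' Total branch length by label
#'
#' Sum of Euclidean parent-child segment lengths over segments whose child
#' node carries the given label.
#'
#' @param m a [Morphology-class]
#' @param label one of \code{"soma"}, \code{"apical"}, \code{"basal"},
#'   \code{"axon"}.
#' @return length in um.
#' @export
branchLength <- function(m, label) {
  sg <- .labelSegments(m, label)
  if (!nrow(sg$p0)) return(0)
  sum(sqrt(rowSums((sg$p1 - sg$p0)^2)))
}

#' Membrane surface area by label
#'
#' Lateral (frustum) area per segment,
#' \code{pi * (r_parent + r_child) * length}, summed over segments whose child
#' carries the label; equals trapezoidal integration of the diameter along the
#' branch. A morphology whose soma is a single point (one soma node, no
#' soma-labeled segments) contributes a sphere area \code{4*pi*r^2} for
#' \code{label = "soma"}.
#'
#' @inheritParams branchLength
#' @return area in um^2.
#' @export
surfaceArea <- function(m, label) {
  sg <- .labelSegments(m, label)
  if (!nrow(sg$p0)) {
    if (label == "soma") {
      s <- which(m@nodes$label == "soma")
      if (length(s) == 1L) return(4 * pi * m@nodes$radius[s]^2)
    }
    return(0)
  }
  len <- sqrt(rowSums((sg$p1 - sg$p0)^2))
  sum(pi * (sg$r0 + sg$r1) * len)
}

#' Construct a rigid transform
#'
#' @param translation numeric(3) (um).
#' @param rotation 3x3 proper orthonormal matrix (default: identity).
#' @return a [RigidTransform-class]
#' @export
RigidTransform <- function(translation = c(0, 0, 0), rotation = diag(3)) {
  t <- new("RigidTransform", translation = as.numeric(translation),
           rotation = rotation)
  validObject(t)
  t
}

#' Rotation matrix about an arbitrary unit axis
#'
#' Rodrigues' formula.
#' @param axis unit numeric(3).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix
#' @export
rotationAboutAxis <- function(axis, angle) {
  u <- stopifnot3(axis, "axis")
  n <- vecNorm(u)
  if (abs(n - 1) > 1e-6) stop("axis must be a unit vector", call. = FALSE)
  u <- u / n
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Apply a rigid transform to a morphology
#'
#' Positions map as \code{p -> R (p - soma) + soma + translation}: the
#' rotation acts about the soma, then the whole morphology is translated.
#' Radii, labels and topology are unchanged.
#'
#' @param m a [Morphology-class]
#' @param transform a [RigidTransform-class]
#' @return the transformed [Morphology-class]
#' @export
applyTransform <- function(m, transform) {
  stopifnot(is(m, "Morphology"), is(transform, "RigidTransform"))
  validObject(transform)
  nd <- m@nodes
  pos <- as.matrix(nd[, c("x", "y", "z")])
  rel <- sweep(pos, 2L, m@somaPosition)
  new_ <- rel %*% t(transform@rotation)
  new_ <- sweep(new_, 2L, m@somaPosition + transform@translation, `+`)
  nd$x <- new_[, 1L]; nd$y <- new_[, 2L]; nd$z <- new_[, 3L]
  Morphology(nd, cellType = m@cellType, column = m@column)
}

#' @describeIn Morphology display a short summary
#' @param object a Morphology
#' @export
setMethod("show", "Morphology", function(object) {
  nd <- object@nodes
  cat(sprintf("Morphology: %d nodes (%s), cell type %s, column %s\n",
              nrow(nd),
              paste(sprintf("%s:%d", names(table(nd$label)), table(nd$label)),
                    collapse = " "),
              object@cellType, object@column))
})
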