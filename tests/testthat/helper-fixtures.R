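# Shared fixtures, built lazily and cached for the whole test run.

.testCache <- new.env(parent = emptyenv())

# tiny single-column ground-truth network (<= 10 neurons) with known alphas
gtFixture <- function() {
  if (is.null(.testCache$gt))
    .testCache$gt <- suppressWarnings(makeGroundTruthNetwork(seed = 42))
  .testCache$gt
}

# the standard two-column fixture network and its innervation matrix
fullFixture <- function() {
  if (is.null(.testCache$full)) {
    fx <- suppressWarnings(makeFixtureNetwork(fixtureConfig(seed = 7)))
    im <- suppressWarnings(pairwiseInnervation(fx$network, fx$bundle$meta))
    .testCache$full <- list(network = fx$network, bundle = fx$bundle,
                            im = im)
  }
  .testCache$full
}

# a simple two-column test frame; optionally tilt the second column's axis
testFrame <- function(tilt = FALSE, zoneMax = 450) {
  grid <- VoxelGrid(c(0, 0, 0), 50, c(10L, 6L, 9L))
  ax2 <- if (tilt) c(0.2, 0, 1) / sqrt(1.04) else c(0, 0, 1)
  columns <- data.frame(
    id = c("A", "B"),
    cx = c(150, 350), cy = 150, cz = 225,
    ax = c(0, ax2[1L]), ay = c(0, ax2[2L]), az = c(1, ax2[3L]),
    radius = 75, top_depth = 0, bottom_depth = 450,
    stringsAsFactors = FALSE)
  zones <- data.frame(
    column_id = rep(c("A", "B"), each = 3L),
    zone = rep(c("supragranular", "granular", "infragranular"), 2L),
    depth_min = rep(c(0, 150, 250), 2L),
    depth_max = rep(c(150, 250, zoneMax), 2L),
    stringsAsFactors = FALSE)
  ReferenceFrame(grid, columns, zones)
}

# hand-built straight morphology: n nodes along `dir` at `spacing`, first
# node labeled soma, the rest `label`
straightMorphology <- function(n, spacing, label = "axon", radius = 1,
                               dir = c(1, 0, 0), start = c(0, 0, 0),
                               radii = NULL) {
  pos <- t(vapply(seq_len(n) - 1L, function(i) start + i * spacing * dir,
                  numeric(3)))
  if (is.null(radii)) radii <- rep(radius, n)
  Morphology(data.frame(
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L], radius = radii,
    label = c("soma", rep(label, n - 1L)),
    parent = c(NA_integer_, seq_len(n - 1L)),
    stringsAsFactors = FALSE))
}

# build an InnervationMatrix from a dense matrix of I values
imFromDense <- function(M, preIds = NULL, postIds = NULL) {
  if (is.null(preIds)) preIds <- sprintf("a%03d", seq_len(nrow(M)))
  if (is.null(postIds)) postIds <- sprintf("b%03d", seq_len(ncol(M)))
  dimnames(M) <- list(preIds, postIds)
  info <- function(ids) data.frame(id = ids, cell_type = "T", column = "A",
                                   inside_column = TRUE,
                                   stringsAsFactors = FALSE)
  new("InnervationMatrix",
      matrix = methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                       "generalMatrix"), "CsparseMatrix"),
      preInfo = info(preIds), postInfo = info(postIds))
}
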