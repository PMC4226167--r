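test_that("soma sampling rounds expected counts half-up per voxel", {
  g1 <- VoxelGrid(c(0, 0, 0), 50, c(1, 1, 1))
  expect_equal(nrow(sampleSomata(array(8, c(1, 1, 1)), g1, 1)), 1)
  expect_equal(nrow(sampleSomata(array(19.2, c(1, 1, 1)), g1, 1)), 2)
  expect_equal(nrow(sampleSomata(array(0, c(1, 1, 1)), g1, 1)), 0)
  expect_error(sampleSomata(array(-1, c(1, 1, 1)), g1, 1), ">= 0")
  g <- VoxelGrid(c(0, 0, 0), 50, c(4, 3, 2))
  set.seed(2)
  dens <- array(runif(24, 0, 30), c(4, 3, 2))
  pts <- sampleSomata(dens, g, 5)
  expect_equal(nrow(pts),
               sum(floor(dens * 1e3 * (0.05)^3 + 0.5)))
  # positions fall in the voxels they were drawn for, and runs are reproducible
  expect_true(all(pts >= 0) &&
              all(sweep(pts, 2, g@dims * g@spacing, `<`)))
  expect_equal(sampleSomata(dens, g, 5), pts)
  expect_false(isTRUE(all.equal(sampleSomata(dens, g, 6), pts)))
})

test_that("soma positions are uniform within a voxel (octant chi-square)", {
  g1 <- VoxelGrid(c(0, 0, 0), 50, c(1, 1, 1))
  pts <- sampleSomata(array(6400, c(1, 1, 1)), g1, 31)  # 800 somata
  oct <- 1 + (pts[, 1] >= 25) + 2 * (pts[, 2] >= 25) + 4 * (pts[, 3] >= 25)
  counts <- tabulate(oct, 8)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("cell-type assignment respects regions, occupancy and frequencies", {
  fx <- fullFixture()
  b <- fx$bundle
  # a region stratum with a single eligible type always yields it
  p <- c(40, 40, 100)  # septum near column C1
  expect_false(nearestColumn(p, b$frame)$inside)
  excTypes <- b$cellTypes$name[b$cellTypes$excitatory & !b$cellTypes$axon_only]
  frE <- b$freqs[b$freqs$cell_type %in% excTypes, ]
  expect_identical(assignCellType(p, b$frame, frE, b$cellTypes, 1), "PYR")
  # the column-only polar type never appears in the septum
  nn <- networkNeurons(fx$network)
  expect_true(all(nn$inside_column[nn$cell_type == "SS"]))
  # empirical inside-column frequencies approach 0.6 / 0.4 (3 sigma binomial)
  pin <- c(150, 150, 225)  # column C1 center-ish
  draws <- vapply(1:2000, function(s)
    assignCellType(pin, b$frame, frE, b$cellTypes, s), character(1))
  fSS <- mean(draws == "SS")
  expect_lt(abs(fSS - 0.4), 3 * sqrt(0.4 * 0.6 / 2000))
  # unknown region errors
  frBad <- frE[frE$region == "nope", ]
  expect_error(assignCellType(pin, b$frame, frBad, b$cellTypes, 1),
               "no eligible cell type")
})

test_that("dendrite selection enforces the three criteria and the depth window", {
  fx <- fullFixture()
  b <- fx$bundle
  p <- c(150, 150, 225)
  sel <- selectDendrite(p, "PYR", b$manifest, b$morphologies, b$frame,
                        b$cellTypes, seed = 3)
  man <- b$manifest
  row <- man[man$morphology_id == sel$id, ]
  expect_identical(row$cell_type, "PYR")
  expect_identical(row$column_id, "C1")
  expect_lte(abs(row$soma_depth - columnDepth(p, b$frame, "C1")), 50)
  # a manifest whose only candidate is 75 um away in depth fails criterion 3
  manFar <- man[man$kind == "dendrite" & man$cell_type == "PYR" &
                man$column_id == "C1", ][1, ]
  manFar$soma_depth <- columnDepth(p, b$frame, "C1") + 75
  expect_error(selectDendrite(p, "PYR", manFar, b$morphologies, b$frame,
                              b$cellTypes, seed = 3), "fail depth")
  # transform lands the soma exactly on the requested position
  m <- applyTransform(b$morphologies[[sel$id]], sel$transform)
  expect_equal(somaPosition(m), p, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("polar types keep their azimuth relative to the column center", {
  fx <- fullFixture()
  b <- fx$bundle
  ctr <- unlist(b$frame@columns[1, c("cx", "cy", "cz")])
  p <- c(180, 120, 175)
  sel <- selectDendrite(p, "SS", b$manifest, b$morphologies, b$frame,
                        b$cellTypes, seed = 11)
  m0 <- b$morphologies[[sel$id]]
  m1 <- applyTransform(m0, sel$transform)
  azimuthOf <- function(m, soma) {
    nd <- morphologyNodes(m)
    com <- colMeans(as.matrix(nd[nd$label != "soma", c("x", "y", "z")]))
    bear <- ctr - soma
    v <- com - soma
    atan2(v[2] * bear[1] - v[1] * bear[2], v[1] * bear[1] + v[2] * bear[2])
  }
  a0 <- azimuthOf(m0, somaPosition(m0))
  a1 <- azimuthOf(m1, p)
  expect_lt(abs(atan2(sin(a0 - a1), cos(a0 - a1))), 1e-6)
})

test_that("axon selection keeps library geometry bit-identical", {
  fx <- fullFixture()
  b <- fx$bundle
  p <- c(150, 150, 225)
  id <- selectAxon(p, "PYR", b$manifest, b$frame, seed = 4)
  row <- b$manifest[b$manifest$morphology_id == id, ]
  expect_identical(row$kind, "axon")
  expect_identical(row$column_id, "C1")
  expect_identical(selectAxon(p, "PYR", b$manifest, b$frame, seed = 4), id)
  nn <- networkNeurons(fx$network)
  some <- nn$id[!is.na(nn$axon_morph)][1]
  expect_identical(
    morphologyNodes(placedMorphology(fx$network, some, "axon")),
    morphologyNodes(b$morphologies[[nn$axon_morph[nn$id == some]]]))
  # candidates registered to another column are excluded
  manB <- b$manifest[b$manifest$column_id == "C2", ]
  expect_error(selectAxon(p, "PYR", manB, b$frame, 1), "no axon candidate")
})

test_that("long-range up-scaling duplicates round-robin", {
  lib <- sprintf("m%02d", 1:14)
  inst <- upscaleLongRange(lib, 311, seed = 9)
  expect_length(inst, 311)
  mult <- table(inst)
  expect_setequal(names(mult), lib)
  expect_true(all(mult %in% c(22, 23)))   # 311 = 14 * 22 + 3
  expect_equal(sum(mult == 23), 3)
  expect_identical(sort(upscaleLongRange(lib, 14, 1)), sort(lib))
  expect_identical(upscaleLongRange("solo", 5, 1), rep("solo", 5))
})

test_that("assembly conserves soma counts, audits depth and is deterministic", {
  fx <- fullFixture()
  b <- fx$bundle
  net <- fx$network
  nn <- networkNeurons(net)
  vol <- (b$frame@grid@spacing * 1e-3)^3
  expected <- sum(floor(b$densities$exc * 1e3 * vol + 0.5)) +
    sum(floor(b$densities$inh * 1e3 * vol + 0.5))
  local <- nn[!startsWith(nn$id, "lr_"), ]
  expect_identical(nrow(local), as.integer(expected))
  # criterion-3 audit: placed vs original soma depth within one voxel
  for (r in seq_len(nrow(local))) {
    dep <- columnDepth(unlist(local[r, c("x", "y", "z")]), net@frame,
                       local$column[r])
    orig <- b$manifest$soma_depth[b$manifest$morphology_id ==
                                  local$dendrite_morph[r]]
    expect_lte(abs(dep - orig), b$frame@grid@spacing)
  }
  # per-type dendrite totals are invariant under the rigid placement
  for (tn in c("PYR", "SS")) {
    ids <- local$id[local$cell_type == tn]
    placed <- sum(vapply(ids, function(id) {
      m <- placedMorphology(net, id, "dendrite")
      branchLength(m, "basal") + branchLength(m, "apical")
    }, numeric(1)))
    fromLib <- sum(vapply(local$dendrite_morph[local$cell_type == tn],
                          function(mid) {
      m <- b$morphologies[[mid]]
      branchLength(m, "basal") + branchLength(m, "apical")
    }, numeric(1)))
    expect_equal(placed, fromLib, tolerance = 1e-9)
  }
  # determinism: same seed, same network
  net2 <- buildNetwork(b$frame, b$densities$exc, b$densities$inh,
                       b$cellTypes, b$freqs, b$morphologies, b$manifest,
                       seed = 7)
  expect_identical(networkNeurons(net2), nn)
  # a type without morphologies fails at the selection stage
  manNoSS <- b$manifest[b$manifest$cell_type != "SS", ]
  morphNoSS <- b$morphologies[manNoSS$morphology_id]
  expect_error(
    buildNetwork(b$frame, b$densities$exc, b$densities$inh, b$cellTypes,
                 b$freqs, morphNoSS, manNoSS, seed = 7),
    "no dendrite candidate")
})
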