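test_that("target probabilities normalize PSTs by the voxel total", {
  g <- VoxelGrid(c(0, 0, 0), 50, c(2, 2, 2))
  pj <- DensityField(g, 1L, 100, "pst")
  pall <- DensityField(g, 1L, 10000, "pst")
  expect_equal(fieldValues(targetProbability(pj, pall)), 0.01)
  # lone neuron: probability 1
  expect_equal(fieldValues(targetProbability(pj, pj)), 1)
  # PST_j > PST_all is inconsistent
  expect_error(targetProbability(pall, pj), "consistency")
  # over a whole network, probabilities sum to 1 wherever PST_all > 0
  gt <- gtFixture()
  net <- gt$network
  geo <- suppressWarnings(DenseConnectome:::networkGeometry(net))
  nn <- networkNeurons(net)
  post <- nn$id[!is.na(nn$dendrite_morph)]
  pall2 <- DenseConnectome:::pstAllField(net, "TC", gt$meta, geo)
  acc <- DensityField(g <- net@frame@grid, quantity = "p")
  for (j in post) {
    pjf <- pstField(geo$length[[j]], geo$area[[j]], "TC",
                    nn$cell_type[match(j, nn$id)], gt$meta)
    acc <- fieldAdd(acc, targetProbability(pjf, pall2))
  }
  expect_identical(fieldIndex(acc), fieldIndex(pall2))
  expect_equal(fieldValues(acc), rep(1, length(fieldIndex(acc))),
               tolerance = 1e-12)
})

test_that("innervation is the voxelwise bouton-probability product", {
  g <- VoxelGrid(c(0, 0, 0), 50, c(2, 2, 2))
  bi <- DensityField(g, 1L, 10, "boutons")
  pj <- DensityField(g, 1L, 0.01, "probability")
  f <- innervationField(bi, pj)
  expect_equal(innervationTotal(f), 0.1)
  # disjoint supports: zero innervation
  pj2 <- DensityField(g, 2L, 0.5, "probability")
  expect_equal(innervationTotal(innervationField(bi, pj2)), 0)
  # multi-voxel case equals the dense elementwise product-sum
  set.seed(3)
  idx <- sort(sample(8, 5))
  b2 <- DensityField(g, idx, runif(5, 0, 20), "boutons")
  p2 <- DensityField(g, sort(sample(8, 6)), runif(6), "probability")
  expect_equal(innervationTotal(innervationField(b2, p2)),
               sum(fieldAsArray(b2) * fieldAsArray(p2)))
})

test_that("boutons are exhaustively distributed over targets per voxel", {
  gt <- gtFixture()
  net <- gt$network
  geo <- suppressWarnings(DenseConnectome:::networkGeometry(net))
  nn <- networkNeurons(net)
  post <- nn$id[!is.na(nn$dendrite_morph)]
  pall <- DenseConnectome:::pstAllField(net, "TC", gt$meta, geo)
  i <- nn$id[nn$cell_type == "TC"][1]
  bi <- geo$bouton[[i]]
  acc <- DensityField(net@frame@grid, quantity = "innervation")
  for (j in post) {
    pjf <- targetProbability(
      pstField(geo$length[[j]], geo$area[[j]], "TC",
               nn$cell_type[match(j, nn$id)], gt$meta), pall)
    acc <- fieldAdd(acc, innervationField(bi, pjf, i, j)@field)
  }
  # on every voxel where targets exist, sum_j Itilde equals B_i
  withTargets <- intersect(fieldIndex(bi), fieldIndex(pall))
  expect_equal(fieldAt(acc, withTargets), fieldAt(bi, withTargets),
               tolerance = 1e-12)
})

test_that("connection probability follows the exponential law", {
  expect_equal(round(connectionProbability(0.66), 2), 0.48)
  expect_equal(round(connectionProbability(0.68), 2), 0.49)
  expect_equal(connectionProbability(0), 0)
  expect_error(connectionProbability(-0.1), ">= 0")
  # strictly increasing in I
  I <- seq(0, 5, by = 0.01)
  expect_true(all(diff(connectionProbability(I)) > 0))
})

test_that("the Poisson synapse-count law matches the worked example", {
  d <- synapseCountDistribution(0.66)
  expect_equal(round(100 * d$p[1]), 52)
  expect_equal(round(100 * d$p[2]), 34)
  expect_equal(round(100 * d$p[3]), 11)
  d0 <- synapseCountDistribution(0)
  expect_equal(d0$p[1], 1)
  # the binomial it approximates (many boutons, small probability) is within
  # 1e-4 total variation
  B <- 1e4; p <- 0.66 / B
  n <- 0:20
  tv <- 0.5 * (sum(abs(dbinom(n, B, p) - dpois(n, 0.66))) +
               (1 - sum(dbinom(n, B, p))) + (1 - sum(dpois(n, 0.66))))
  expect_lt(tv, 1e-4)
  # the per-voxel product and summed-exponent forms of p_ij agree
  set.seed(9)
  It <- runif(30, 0, 0.2)
  expect_equal(1 - prod(exp(-It)), connectionProbability(sum(It)),
               tolerance = 1e-12)
})

test_that("the pairwise matrix matches per-pair recomputation and is equivariant", {
  gt <- gtFixture()
  net <- gt$network
  nn <- networkNeurons(net)
  im <- suppressWarnings(pairwiseInnervation(net, gt$meta))
  M <- as.matrix(innervationMatrix(im))
  # every entry equals the standalone per-pair field total
  for (i in rownames(M)[1:3]) for (j in colnames(M)[1:3]) {
    f <- suppressWarnings(pairInnervationField(net, i, j, gt$meta))
    expect_equal(M[i, j], innervationTotal(f), tolerance = 1e-12)
  }
  # permuting the selections permutes rows/columns only
  pre <- nn$id[!is.na(nn$axon_morph)]
  post <- nn$id[!is.na(nn$dendrite_morph)]
  im2 <- suppressWarnings(
    pairwiseInnervation(net, gt$meta, pre = rev(pre), post = rev(post)))
  expect_equal(as.matrix(innervationMatrix(im2)),
               M[rev(pre), rev(post)], tolerance = 1e-12)
  # a presynaptic neuron with no overlap yields an all-zero row
  expect_true(all(M >= 0))
})
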