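test_that("segment clipping splits at voxel faces and conserves totals", {
  g <- VoxelGrid(c(0, 0, 0), 50, c(4, 4, 4))
  m <- straightMorphology(3, 50, "axon", start = c(0, 25, 25))
  cl <- clipToVoxels(m, "axon", g)
  expect_equal(fieldTotal(cl$length), 100)
  arr <- fieldAsArray(cl$length)
  expect_equal(arr[1, 1, 1], 50)
  expect_equal(arr[2, 1, 1], 50)
  # conservation for random branched trees
  box <- list(lower = c(5, 5, 5), upper = c(195, 195, 195))
  for (s in 1:20) {
    mr <- makeMorphology("dendrite", soma = c(100, 100, 100),
                         totalLength = 200, seed = s, box = box)
    for (lab in c("apical", "basal")) {
      cl <- clipToVoxels(mr, lab, g)
      expect_equal(fieldTotal(cl$length), branchLength(mr, lab),
                   tolerance = 1e-6)
      expect_equal(fieldTotal(cl$area), surfaceArea(mr, lab),
                   tolerance = 1e-6)
    }
  }
})

test_that("clipping agrees per voxel with a dense-resampling oracle", {
  g <- VoxelGrid(c(0, 0, 0), 50, c(4, 4, 4))
  box <- list(lower = c(5, 5, 5), upper = c(195, 195, 195))
  m <- makeMorphology("axon", soma = c(100, 100, 100), totalLength = 300,
                      seed = 23, box = box)
  cl <- clipToVoxels(m, "axon", g)
  # oracle: resample each segment at 0.01 um and bin midpoints
  nd <- morphologyNodes(m)
  arr <- array(0, g@dims)
  for (i in which(nd$label == "axon" & !is.na(nd$parent))) {
    p0 <- unlist(nd[nd$parent[i], c("x", "y", "z")])
    p1 <- unlist(nd[i, c("x", "y", "z")])
    L <- sqrt(sum((p1 - p0)^2))
    ns <- max(1L, ceiling(L / 0.01))
    tmid <- (seq_len(ns) - 0.5) / ns
    mids <- outer(tmid, p1 - p0) + matrix(p0, ns, 3, byrow = TRUE)
    ijk <- floor(mids / 50)
    idx <- 1 + ijk[, 1] + 4 * (ijk[, 2] + 4 * ijk[, 3])
    for (u in unique(idx)) arr[u] <- arr[u] + sum(idx == u) * L / ns
  }
  got <- fieldAsArray(cl$length)
  expect_lt(max(abs(got - arr)) / max(arr), 1e-3)
})

test_that("bouton fields scale clipped axon length by zone densities", {
  fx <- fullFixture()
  frame <- fx$bundle$frame
  types <- fx$bundle$cellTypes
  g <- frame@grid
  ss <- types[types$name == "SS", ]
  # 30 um of axon in one granular voxel at density 0.3 -> 9 boutons
  f <- DensityField(g, ijkToLin <- DenseConnectome:::ijkToLinear(
    matrix(c(2L, 2L, 4L), 1), g), 30, "length_um_axon")
  ctr <- voxelCenters(g, fieldIndex(f))
  expect_identical(laminarZoneOf(ctr[1, ], frame), "granular")
  bf <- boutonField(f, ss, frame)
  expect_equal(fieldValues(bf), 30 * ss$bouton_gran)
  # zero length -> zero boutons
  expect_length(fieldValues(boutonField(
    DensityField(g, quantity = "length_um_axon"), ss, frame)), 0)
  # an axon spanning two zones multiplies voxelwise
  idx2 <- DenseConnectome:::ijkToLinear(rbind(c(2L, 2L, 2L), c(2L, 2L, 4L)), g)
  f2 <- DensityField(g, idx2, c(10, 20), "length_um_axon")
  bf2 <- boutonField(f2, ss, frame)
  expect_equal(fieldAt(bf2, idx2),
               c(10 * ss$bouton_supra, 20 * ss$bouton_gran))
})

test_that("PST fields combine length and area terms per label", {
  g <- VoxelGrid(c(0, 0, 0), 50, c(2, 2, 2))
  idx <- 1L
  meta <- metaConnectivity(data.frame(
    pre_type = c("E", "E", "I"), post_type = "P",
    label = c("basal", "apical", "soma"),
    lambda_per_um = c(1, 0.5, 0), alpha_per_um2 = c(0, 0, 0.4)))
  lf <- list(basal = DensityField(g, idx, 523, "l"),
             apical = DensityField(g, idx, 100, "l"))
  af <- list(soma = DensityField(g, idx, 100, "a"))
  # spines only: 523 * 1 + 100 * 0.5
  pe <- pstField(lf, af, "E", "P", meta)
  expect_equal(fieldValues(pe), 523 + 50)
  # surface only: 100 um^2 * 0.4 = 40
  pi_ <- pstField(lf, af, "I", "P", meta)
  expect_equal(fieldValues(pi_), 40)
  # absent (pre, post, label) entries contribute nothing
  expect_length(fieldValues(pstField(lf, af, "X", "P", meta)), 0)
  # mixed-label voxel equals the label-wise brute-force sum; bilinear in lambda
  meta2 <- meta; meta2$lambda_per_um <- meta$lambda_per_um * 2
  expect_equal(fieldValues(pstField(lf, af, "E", "P", meta2)),
               2 * fieldValues(pe))
})

test_that("the surface-PST balance fit has the 1-parameter closed form", {
  gt <- gtFixture()
  net <- gt$network
  # single unknown group: only the exc -> INH soma alpha unknown
  meta1 <- gt$meta
  unk <- meta1$post_type == "INH" & meta1$pre_type != "INH" &
    meta1$label == "soma"
  meta1$alpha_per_um2[unk] <- NA_real_
  # target profile built for a known alpha: fit must recover it, and the
  # 1-parameter nonnegative LS solution matches sum(A*b)/sum(A^2)
  fit <- suppressWarnings(
    fitSurfacePST(net, meta1, boutonProfile = gt$balancedBoutonProfile))
  expect_equal(unname(fit$alpha), 0.4, tolerance = 1e-9)
  # residual at machine scale for a noise-free identifiable design
  expect_lt(max(abs(fit$residual)), 1e-9)
  # a balanced all-spine network needs no surface PSTs: alpha = 0
  metaZero <- gt$meta
  metaZero$alpha_per_um2[metaZero$post_type == "INH" &
                         metaZero$pre_type != "INH"] <- 0
  prof0 <- -suppressWarnings(
    fitSurfacePST(net, metaZero,
                  boutonProfile = rep(0, net@frame@grid@dims[3]))$residual)
  metaFit0 <- metaZero
  metaFit0$alpha_per_um2[metaFit0$post_type == "INH" &
                         metaFit0$pre_type != "INH"] <- NA_real_
  fit0 <- suppressWarnings(fitSurfacePST(net, metaFit0, boutonProfile = prof0))
  expect_true(all(fit0$alpha < 1e-9))
  # duplicating an unknown into two collinear groups is rejected
  metaBad <- gt$metaUnknown
  metaBad$alpha_per_um2[metaBad$pre_type == "INH" &
                        metaBad$post_type == "INH"] <- NA_real_
  expect_error(suppressWarnings(
    fitSurfacePST(net, metaBad, boutonProfile = gt$balancedBoutonProfile)),
    "rank-deficient")
})
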