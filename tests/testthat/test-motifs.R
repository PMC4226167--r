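test_that("the 64 configurations partition into 16 classes by S3 isomorphism", {
  mc <- motifClasses()
  cls <- mc$classes
  expect_equal(nrow(cls), 16L)
  expect_equal(sum(cls$n_members), 64L)
  expect_equal(as.integer(table(cls$edge_count)[c("3", "2", "1", "0")]),
               c(7L, 6L, 2L, 1L))
  # brute-force partition audit: same class iff related by a permutation
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  orbitOf <- function(code) {
    sort(unique(vapply(perms, function(s)
      DenseConnectome:::.permuteConfig(code, as.integer(s)), integer(1))))
  }
  for (c1 in 0:63) {
    orb <- orbitOf(c1)
    same <- which(mc$classOf == mc$classOf[c1 + 1]) - 1L
    expect_identical(sort(same), orb)
  }
})

test_that("the feedforward three-connected class has six member configurations", {
  mc <- motifClasses()
  # the configuration with edges 2->1, 3->1, 3->2 (edge slots 2, 4, 6)
  code <- sum(2^(c(2L, 4L, 6L) - 1L))
  cls <- mc$classOf[code + 1L]
  expect_equal(mc$classes$n_members[cls], 6L)
  expect_equal(mc$classes$edge_count[cls], 3L)
  # the cyclic loop class (1->2, 2->3, 3->1; slots 1, 5, 4) has two members
  loop <- sum(2^(c(1L, 5L, 4L) - 1L))
  expect_equal(mc$classes$n_members[mc$classOf[loop + 1L]], 2L)
})

test_that("triplet spectra are normalized products over the six edges", {
  spHalf <- tripletSpectrum(rep(0.5, 6))
  expect_equal(spHalf$probability, spHalf$n_members / 64, tolerance = 1e-12)
  sp0 <- tripletSpectrum(rep(0, 6))
  expect_equal(sp0$probability[sp0$edge_count == 0], 1)
  expect_equal(sum(sp0$probability), 1)
  set.seed(5)
  for (r in 1:200) {
    p <- runif(6)
    sp <- tripletSpectrum(p)
    expect_equal(sum(sp$probability), 1, tolerance = 1e-9)
  }
  expect_error(tripletSpectrum(c(0.5, 0.5, 0.5, 0.5, 0.5, 1.5)), "\\[0, 1\\]")
})

test_that("spectra match the graph-isomorphism oracle", {
  skip_if_not_installed("igraph")
  set.seed(6)
  for (r in 1:5) {
    p <- runif(6)
    sp <- tripletSpectrum(p)
    osp <- oracleTripletSpectrum(p)
    expect_equal(osp$probability, sp$probability[osp$motif_id],
                 tolerance = 1e-12)
  }
})

test_that("triplet sampling enforces the one-shared-neuron constraint", {
  tri <- DenseConnectome:::.sampleTriplets(30, 20, seed = 2)
  expect_equal(dim(tri), c(20L, 3L))
  for (a in 1:19) for (b in (a + 1):20) {
    expect_lte(length(intersect(tri[a, ], tri[b, ])), 1L)
  }
  # infeasible requests error with the feasible maximum
  expect_error(DenseConnectome:::.sampleTriplets(10, 100, seed = 2),
               "at most")
})

test_that("population spectra average triplets and reduce to the analytic case", {
  # population of exactly 3: the spectrum is the single triplet's spectrum
  set.seed(14)
  M <- matrix(rexp(9, 2), 3, 3)
  ids <- sprintf("n%d", 1:3)
  im <- imFromDense(M, ids, ids)
  sp <- populationSpectrum(im, ids, nRepeats = 2, seed = 1)
  direct <- tripletSpectrumFromMatrix(im, ids)
  expect_equal(sp$prob_mean, direct$probability, tolerance = 1e-12)
  expect_equal(sp$prob_sd, rep(0, 16))
  # uniform-I matrix: every triplet has the same spectrum, equal to the
  # analytic spectrum at that edge probability
  idsU <- sprintf("u%02d", 1:15)
  imU <- imFromDense(matrix(0.4, 15, 15), idsU, idsU)
  spU <- populationSpectrum(imU, idsU, nTriplets = 10, nRepeats = 3,
                            seed = 4)
  expect_equal(spU$prob_mean,
               tripletSpectrum(rep(connectionProbability(0.4), 6))$probability,
               tolerance = 1e-9)
})

test_that("uniform-null comparison reports deviations and signed z-scores", {
  null <- tripletSpectrum(rep(0.31, 6))
  fake <- data.frame(motif_id = null$motif_id, edge_count = null$edge_count,
                     prob_mean = null$probability,
                     prob_sd = rep(0.01, 16))
  cmp <- uniformNullComparison(fake, 0.31)
  expect_equal(cmp$deviation, rep(0, 16), tolerance = 1e-12)
  expect_equal(cmp$z, rep(0, 16), tolerance = 1e-12)
  # a perturbed spectrum has z-scores with the sign of the deviation
  fake2 <- fake
  fake2$prob_mean <- fake$prob_mean * c(rep(1.2, 8), rep(0.8, 8))
  fake2$prob_mean <- fake2$prob_mean / sum(fake2$prob_mean)
  cmp2 <- uniformNullComparison(fake2, 0.31)
  nz <- cmp2$deviation != 0
  expect_true(all(sign(cmp2$z[nz]) == sign(cmp2$deviation[nz])))
})
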