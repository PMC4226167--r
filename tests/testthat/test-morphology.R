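swcText <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

test_that("SWC reading validates structure codes, radii and topology", {
  m <- readSWC(swcText(c("# comment",
                         "1 1 0 0 0 5 -1",
                         "2 2 1 0 0 1 1",
                         "3 2 2 0 0 1 2")))
  expect_equal(branchLength(m, "axon"), 2)
  expect_error(readSWC(swcText(c("1 1 0 0 0 5 -1", "2 7 1 0 0 1 1"))),
               "unknown structure code 7")
  expect_error(readSWC(swcText(c("1 1 0 0 0 -5 -1"))), "negative radius")
  expect_error(readSWC(swcText(c("1 1 0 0 0 5 -1", "2 2 1 0 0 1 9"))),
               "orphan")
  expect_error(readSWC(swcText(c("1 1 0 0 0 5 -1", "2 2 1 0 0 1"))),
               "expected 7 fields")
})

test_that("SWC write/read round trip preserves nodes and measurements", {
  box <- list(lower = c(5, 5, 5), upper = c(445, 295, 445))
  m <- makeMorphology("dendrite", soma = c(200, 150, 200), totalLength = 300,
                      seed = 5, box = box)
  f <- tempfile(fileext = ".swc")
  writeSWC(m, f)
  m2 <- expect_no_warning(readSWC(f))
  expect_equal(as.matrix(morphologyNodes(m2)[, c("x", "y", "z", "radius")]),
               as.matrix(morphologyNodes(m)[, c("x", "y", "z", "radius")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(morphologyNodes(m2)$label, morphologyNodes(m)$label)
  expect_identical(morphologyNodes(m2)$parent, morphologyNodes(m)$parent)
  for (lab in c("soma", "apical", "basal")) {
    expect_equal(branchLength(m2, lab), branchLength(m, lab),
                 tolerance = 1e-8)
    expect_equal(surfaceArea(m2, lab), surfaceArea(m, lab),
                 tolerance = 1e-8)
  }
})

test_that("branch length sums parent-child segments of the label", {
  m <- straightMorphology(10, 5, "axon")
  expect_equal(branchLength(m, "axon"), 45)
  expect_equal(branchLength(m, "basal"), 0)
  # independent oracle: explicit edge enumeration
  box <- list(lower = c(5, 5, 5), upper = c(445, 295, 445))
  mr <- makeMorphology("dendrite", soma = c(200, 150, 200),
                       totalLength = 250, seed = 9, box = box)
  nd <- morphologyNodes(mr)
  byLabel <- sapply(c("apical", "basal"), function(lab) {
    tot <- 0
    for (i in seq_len(nrow(nd))) {
      if (nd$label[i] == lab && !is.na(nd$parent[i])) {
        pa <- nd$parent[i]
        tot <- tot + sqrt((nd$x[i] - nd$x[pa])^2 + (nd$y[i] - nd$y[pa])^2 +
                          (nd$z[i] - nd$z[pa])^2)
      }
    }
    tot
  })
  expect_equal(branchLength(mr, "apical"), byLabel[["apical"]])
  expect_equal(branchLength(mr, "basal"), byLabel[["basal"]])
})

test_that("surface area uses the frustum rule, sphere for point somata", {
  m <- straightMorphology(2, 10, "axon", radii = c(1, 1))
  expect_equal(surfaceArea(m, "axon"), pi * 2 * 10)         # 62.83
  m2 <- straightMorphology(2, 10, "axon", radii = c(1, 2))
  expect_equal(surfaceArea(m2, "axon"), pi * 3 * 10)        # 94.25
  # uniform cylinder closed form 2*pi*r*L
  m3 <- straightMorphology(11, 2, "basal", radii = rep(0.5, 11))
  expect_equal(surfaceArea(m3, "basal"), 2 * pi * 0.5 * 20)
  # zero-length segment contributes nothing
  m4 <- Morphology(data.frame(x = c(0, 0), y = 0, z = 0, radius = 1,
                              label = c("soma", "axon"),
                              parent = c(NA, 1L)))
  expect_equal(surfaceArea(m4, "axon"), 0)
  # single-node soma: sphere
  expect_equal(surfaceArea(straightMorphology(3, 5, "axon", radii = c(4, 1, 1)),
                           "soma"), 4 * pi * 16)
})

test_that("rigid transforms preserve measurements and act about the soma", {
  box <- list(lower = c(5, 5, 5), upper = c(445, 295, 445))
  m <- makeMorphology("dendrite", soma = c(200, 150, 200), totalLength = 200,
                      seed = 3, box = box)
  expect_equal(morphologyNodes(applyTransform(m, RigidTransform())),
               morphologyNodes(m), tolerance = 1e-12)
  tr <- applyTransform(m, RigidTransform(translation = c(50, 0, 0)))
  expect_equal(somaPosition(tr), somaPosition(m) + c(50, 0, 0))
  d0 <- dist(as.matrix(morphologyNodes(m)[, c("x", "y", "z")]))
  d1 <- dist(as.matrix(morphologyNodes(tr)[, c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  rot <- RigidTransform(rotation = rotationAboutAxis(c(0, 0, 1), pi / 2))
  mr <- applyTransform(m, rot)
  for (lab in c("soma", "apical", "basal")) {
    expect_equal(branchLength(mr, lab), branchLength(m, lab),
                 tolerance = 1e-6 * max(1, branchLength(m, lab)))
    expect_equal(surfaceArea(mr, lab), surfaceArea(m, lab),
                 tolerance = 1e-6 * max(1, surfaceArea(m, lab)))
  }
  expect_error(RigidTransform(rotation = matrix(2 * diag(3), 3)),
               "orthonormal")
  expect_error(RigidTransform(rotation = diag(c(1, 1, -1))), "determinant")
})
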