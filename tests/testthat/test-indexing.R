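cfg <- singleCrystalConfig()
cell <- configCell(cfg)
sym <- configSymmetry(cfg)
beam <- configBeam(cfg)
det <- configDetector(cfg)

test_that("scattering-vector mapping is exact Ewald geometry", {
  bc <- data.frame(fast = det@beamCenterFast, slow = det@beamCenterSlow)
  q0 <- peaksToScatteringVectors(bc, det, beam)
  expect_equal(max(abs(q0)), 0, tolerance = 1e-12)
  ## center-edge pixel resolves at the edge resolution
  edge <- data.frame(fast = 0, slow = det@beamCenterSlow)
  qe <- peaksToScatteringVectors(edge, det, beam)
  expect_equal(1 / sqrt(sum(qe^2)), edgeResolution(det, beam),
               tolerance = 1e-9)
  ## all q lie on the Ewald sphere: |q + k_in| = 1/lambda
  set.seed(2)
  pk <- data.frame(fast = runif(50, 0, 599), slow = runif(50, 0, 599))
  q <- peaksToScatteringVectors(pk, det, beam)
  wl <- wavelength(beam)
  expect_equal(sqrt(q[, 1]^2 + q[, 2]^2 + (q[, 3] + 1 / wl)^2),
               rep(1 / wl, 50), tolerance = 1e-12)
})

test_that("noiseless synthetic peaks index to the true orientation", {
  set.seed(17)
  Rtrue <- quaternionToMatrix(randomRotations(1)[1, ])
  pred <- predictReflectionsStill(cell, sym, Rtrue, beam, det,
                                  dMin = 2.3)
  pk <- pred[pred$onPanel & pred$partiality > 0.3, ]
  expect_gt(nrow(pk), 16)
  q <- peaksToScatteringVectors(pk, det, beam)
  ori <- indexKnownCell(q, cell, sym)
  expect_false(is.null(ori))
  expect_equal(ori@nIndexed, nrow(pk))
  expect_lt(misorientation(orientationMatrix(ori), Rtrue, sym), 0.05)
})

test_that("symmetry-rotated peak sets give equivalent orientations", {
  set.seed(17)
  Rtrue <- quaternionToMatrix(randomRotations(1)[1, ])
  S <- sym@pointOps[[3]]
  pred <- predictReflectionsStill(cell, sym, Rtrue %*% S, beam, det,
                                  dMin = 2.3)
  pk <- pred[pred$onPanel & pred$partiality > 0.3, ]
  ori <- indexKnownCell(peaksToScatteringVectors(pk, det, beam), cell, sym)
  expect_false(is.null(ori))
  expect_lt(misorientation(orientationMatrix(ori), Rtrue, sym), 0.05)
})

test_that("random non-lattice peaks fail to index", {
  set.seed(1)
  fails <- vapply(1:25, function(i) {
    fake <- data.frame(fast = runif(30, 20, 580),
                       slow = runif(30, 20, 580))
    is.null(indexKnownCell(peaksToScatteringVectors(fake, det, beam),
                           cell, sym))
  }, logical(1))
  expect_true(all(fails))
  ## too few peaks is an immediate failure, not an error
  expect_null(indexKnownCell(matrix(0.1, 2, 3), cell, sym))
})

test_that("indexing simulated frames: high success, sub-0.1-degree error", {
  stack <- fixtureStack(10, 21)
  nIdx <- 0L; errs <- c()
  for (i in seq_len(nFrames(stack))) {
    pks <- findPeaks(frameImage(stack, i))
    if (classifyFrame(pks)$label != "hit") next
    q <- peaksToScatteringVectors(pks, det, beam)
    ori <- indexKnownCell(q, cell, sym)
    if (is.null(ori)) next
    nIdx <- nIdx + 1L
    errs <- c(errs, misorientation(orientationMatrix(ori),
                                   truthRotation(stack, i), sym))
  }
  expect_gte(nIdx, 8)
  expect_lt(median(errs), 0.1)
})

test_that("cell refinement recovers the truth from a perturbed prior", {
  set.seed(23)
  Rtrue <- quaternionToMatrix(randomRotations(1)[1, ])
  pred <- predictReflectionsStill(cell, sym, Rtrue, beam, det, dMin = 2.3)
  pk <- pred[pred$onPanel & pred$partiality > 0.3, ]
  q <- peaksToScatteringVectors(pk, det, beam)
  prior <- tetragonalCell(79.5 * 1.01, 38.4 * 1.01)
  ori <- indexKnownCell(q, prior, sym)
  expect_false(is.null(ori))
  p <- cellParameters(refinedCell(ori))
  expect_equal(unname(p["a"]), 79.5, tolerance = 1e-3)
  expect_equal(unname(p["c"]), 38.4, tolerance = 1e-3)
  ## residual reduces to the excitation-error scale (spots are observed
  ## on the Ewald sphere, nodes sit slightly off it)
  expect_lt(ori@rmsResidual, 1e-3)
})

test_that("exact node positions refine to zero residual", {
  set.seed(29)
  cellT <- tetragonalCell(79.5, 38.4)
  Rtrue <- quaternionToMatrix(randomRotations(1)[1, ])
  ur <- uniqueReflections(cellT, sym, 3.5)
  H <- as.matrix(ur[sample(nrow(ur), 40), c("h", "k", "l")])
  q <- H %*% t(reciprocalMatrix(cellT)) %*% t(Rtrue)
  ori0 <- new("CrystalOrientation", rotation = Rtrue, cell = cellT,
              nIndexed = 40L, nPeaks = 40L, rmsResidual = 0)
  rc <- refineCell(ori0, q)
  expect_lt(rc$orientation@rmsResidual, 1e-10)
  expect_equal(unname(cellParameters(rc$cell)["a"]), 79.5,
               tolerance = 1e-10)
})

test_that("per-frame refined cells are unbiased within 0.5%", {
  stack <- fixtureStack(10, 21)
  as <- c(); cs <- c()
  for (i in seq_len(nFrames(stack))) {
    pks <- findPeaks(frameImage(stack, i))
    if (classifyFrame(pks)$label != "hit") next
    ori <- indexKnownCell(peaksToScatteringVectors(pks, det, beam),
                          cell, sym)
    if (is.null(ori)) next
    p <- cellParameters(refinedCell(ori))
    as <- c(as, p["a"]); cs <- c(cs, p["c"])
  }
  expect_lt(abs(mean(as) / 79.5 - 1), 0.005)
  expect_lt(abs(mean(cs) / 38.4 - 1), 0.005)
})
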