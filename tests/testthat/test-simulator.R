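cfg <- defaultConfig()
cell <- configCell(cfg)
sym <- configSymmetry(cfg)
beam <- configBeam(cfg)
det <- configDetector(cfg)

test_that("structure-factor sampling follows the Wilson model", {
  sf <- sampleStructureFactors(cell, sym, 2.1, wilsonB = 44.1, seed = 2)
  r <- reflections(sf)
  ## screw-axis absences never sampled
  expect_false(any(r$h == 0 & r$k == 0 & r$l %% 4 != 0))
  ## shell-mean intensity follows exp(-B s^2 / 2): fit recovers B
  s2h <- (1 / r$d^2) / 2
  br <- cut(s2h, 12)
  mI <- tapply(r$amp^2, br, mean)
  ms <- tapply(s2h, br, mean)
  fit <- lm(log(mI) ~ ms)
  expect_equal(-unname(coef(fit)[2]), 44.1, tolerance = 0.15)
  ## B = 0 gives flat shell means
  sf0 <- sampleStructureFactors(cell, sym, 2.1, wilsonB = 0, seed = 2)
  mI0 <- tapply(reflections(sf0)$amp^2, br, mean)
  fit0 <- lm(log(mI0) ~ ms)
  expect_lt(abs(coef(fit0)[2]), 5)   # |B| < 5 A^2 within sampling noise
})

test_that("crystal arrivals are Poisson and orientations uniform", {
  cfgP <- defaultConfig()
  cfgP$simulator$mean_crystals <- 0.3
  ev <- sampleCrystalEvents(cfgP, 20000, seed = 8)
  frac <- length(unique(ev$frame)) / 20000
  expect_equal(frac, 1 - exp(-0.3), tolerance = 0.03)
  ## mu = 0 means all frames blank
  cfg0 <- defaultConfig(); cfg0$simulator$mean_crystals <- 0
  expect_equal(nrow(sampleCrystalEvents(cfg0, 100, seed = 1)), 0L)
  ## Haar uniformity: the mean rotation matrix vanishes
  Rsum <- matrix(0, 3, 3)
  qs <- as.matrix(ev[1:4000, c("q1", "q2", "q3", "q4")])
  for (i in seq_len(nrow(qs)))
    Rsum <- Rsum + quaternionToMatrix(qs[i, ])
  expect_lt(max(abs(Rsum / nrow(qs))), 0.05)
  ## transit times within the configured bounds
  expect_true(all(ev$transit >= 1 & ev$transit <= 3))
})

test_that("still prediction respects limits, absences and geometry", {
  set.seed(5)
  R <- quaternionToMatrix(randomRotations(1)[1, ])
  pred <- predictReflectionsStill(cell, sym, R, beam, det, dMin = 2.05)
  expect_true(all(pred$d >= 2.05))
  expect_true(all(pred$partiality >= 0 & pred$partiality <= 1))
  expect_false(any(pred$h == 0 & pred$k == 0 & pred$l %% 4 != 0))
  ## widening the bandwidth only adds reflections
  wide <- beamSpec(bandwidth = 2e-3)
  predW <- predictReflectionsStill(cell, sym, R, wide, det, dMin = 2.05)
  expect_gt(nrow(predW), nrow(pred))
  expect_true(all(hklKey(as.matrix(pred[, 1:3])) %in%
                    hklKey(as.matrix(predW[, 1:3]))))
  ## detector positions invert back to the same scattering vectors
  onp <- pred[pred$onPanel, ]
  q <- peaksToScatteringVectors(onp, det, beam)
  B <- reciprocalMatrix(cell)
  g <- as.matrix(onp[, c("h", "k", "l")]) %*% t(B) %*% t(R)
  ## the observed q sits on the Ewald sphere, the node within the
  ## rocking width of it
  expect_lt(max(sqrt(rowSums((q - g)^2))), 3e-3)
})

test_that("predicted spots at d = 2.1 A land at the edge-resolution radius", {
  set.seed(31)
  R <- quaternionToMatrix(randomRotations(1)[1, ])
  pred <- predictReflectionsStill(cell, sym, R, beam, det, dMin = 2.05)
  sel <- abs(pred$d - 2.1) < 0.02 & pred$onPanel
  expect_gt(sum(sel), 0)
  rpx <- sqrt((pred$fast[sel] - det@beamCenterFast)^2 +
                (pred$slow[sel] - det@beamCenterSlow)^2) * det@pixelSize
  ## radius from inverting d = lambda / (2 sin(atan(s/L) / 2)); the
  ## excitation error displaces the projected spot by a fraction of a
  ## pixel at most
  th2 <- 2 * asin(wavelength(beam) / (2 * pred$d[sel]))
  expect_lt(max(abs(rpx - det@distance * tan(th2))), 0.3)
})

test_that("symmetry-equivalent orientations predict identical ASU lists", {
  set.seed(9)
  R <- quaternionToMatrix(randomRotations(1)[1, ])
  base <- NULL
  for (S in sym@pointOps) {
    pred <- predictReflectionsStill(cell, sym, R %*% S, beam, det,
                                    dMin = 2.3)
    asu <- mapToASU(sym, as.matrix(pred[, c("h", "k", "l")]))
    tab <- paste(hklKey(asu), round(pred$partiality, 8))
    if (is.null(base)) base <- sort(tab) else
      expect_equal(sort(tab), base)
  }
})

test_that("rendered frames conserve photons and record truth", {
  cfg1 <- singleCrystalConfig()
  cfg1$simulator$arc_fraction <- 0
  sf <- sampleStructureFactors(cell, sym, cfg1$simulator$d_min, 44.1,
                               seed = 5)
  ev <- sampleCrystalEvents(cfg1, 1, seed = 6)
  ## without background, the noiseless image integral equals the truth
  ## photon total (up to sub-0.5% stamp-window truncation)
  cfg0 <- cfg1; cfg0$simulator$bg_flat <- 0; cfg0$simulator$ring_amp <- 0
  rf0 <- renderFrame(ev, sf, cfg0, noise = FALSE)
  expect_equal(sum(rf0$expected), sum(rf0$truth$photons),
               tolerance = 0.01)
  ## every rendered spot has exactly one truth entry
  expect_equal(anyDuplicated(rf0$truth[, c("h", "k", "l")]), 0L)
  ## with noise, total counts match background + spots within Poisson
  rf <- renderFrame(ev, sf, cfg1, noise = TRUE)
  expectTot <- sum(rf$expected)
  expect_lt(abs(sum(rf$image) - expectTot), 5 * sqrt(expectTot))
  ## no events, zero background: an all-zero frame
  blank <- renderFrame(ev[0, ], sf, cfg0, noise = TRUE)
  expect_equal(sum(blank$image), 0)
})

test_that("doubling the transit time doubles spot photons exactly", {
  cfg1 <- singleCrystalConfig()
  cfg1$simulator$arc_fraction <- 0
  sf <- sampleStructureFactors(cell, sym, cfg1$simulator$d_min, 44.1,
                               seed = 5)
  ev <- sampleCrystalEvents(cfg1, 1, seed = 6)
  ev2 <- ev; ev2$transit <- 2 * ev$transit
  t1 <- renderFrame(ev, sf, cfg1, noise = FALSE)$truth
  t2 <- renderFrame(ev2, sf, cfg1, noise = FALSE)$truth
  expect_equal(t2$photons, 2 * t1$photons, tolerance = 1e-12)
})

test_that("arc smearing spreads a spot along a constant radius", {
  cfg1 <- singleCrystalConfig()
  cfg1$simulator$arc_fraction <- 1   # every crystal rolls
  sf <- sampleStructureFactors(cell, sym, cfg1$simulator$d_min, 44.1,
                               seed = 5)
  ev <- sampleCrystalEvents(cfg1, 1, seed = 6)
  expect_true(all(ev$arcAngle == 5))
  rf <- renderFrame(ev, sf, cfg1, noise = FALSE)
  ## pick the brightest truth spot and scan its arc neighborhood
  tr <- rf$truth[which.max(rf$truth$photons), ]
  bcf <- det@beamCenterFast; bcs <- det@beamCenterSlow
  rad <- sqrt((tr$fast - bcf)^2 + (tr$slow - bcs)^2)
  phi0 <- atan2(tr$slow - bcs, tr$fast - bcf)
  phis <- phi0 + seq(-4, 4, by = 0.25) * pi / 180
  prof <- vapply(phis, function(p) {
    rf$expected[round(bcs + rad * sin(p)) + 1,
                round(bcf + rad * cos(p)) + 1]
  }, numeric(1))
  lit <- range(which(prof > max(prof) / 10))
  span <- diff(phis[lit]) * 180 / pi
  expect_gt(span, 3.5)
  expect_lt(span, 7.5)
})

test_that("dataset simulation is deterministic and hits follow Poisson", {
  cfgS <- defaultConfig()
  cfgS$simulator$mean_crystals <- 0.3
  s1 <- simulateDataset(cfgS, 4, seed = 13)
  s2 <- simulateDataset(cfgS, 4, seed = 13)
  expect_identical(s1@images, s2@images)
  expect_identical(s1@truthEvents, s2@truthEvents)
  s3 <- simulateDataset(cfgS, 4, seed = 14)
  expect_false(identical(s1@images, s3@images))
  ## crystal-bearing fraction over many sampled frames
  ev <- sampleCrystalEvents(cfgS, 3000, seed = 13)
  frac <- length(unique(ev$frame)) / 3000
  p <- 1 - exp(-0.3)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 3000))
})
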