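cell <- tetragonalCell(79.5, 38.4)
sym <- symmetryP43212()

## tiny synthetic measurement stream: nRefl reflections seen on nFrames
## frames with i.i.d. noise
syntheticStream <- function(nRefl = 40, nFrames = 20, mu = 100, sigma = 10,
                           seed = 1) {
  set.seed(seed)
  ur <- head(uniqueReflections(cell, sym, 3), nRefl)
  do.call(rbind, lapply(seq_len(nFrames), function(fr)
    data.frame(frame = fr, h = ur$h, k = ur$k, l = ur$l, d = ur$d,
               I = rnorm(nRefl, mu, sigma))))
}

test_that("Monte Carlo merge averages without scaling", {
  meas <- syntheticStream()
  merged <- monteCarloMerge(meas, cell, sym)
  r <- reflections(merged)
  expect_equal(nrow(r), 40L)
  expect_true(all(r$n == 20))
  ## permutation invariance of the merge
  perm <- meas[sample(nrow(meas)), ]
  r2 <- reflections(monteCarloMerge(perm, cell, sym))
  r2 <- r2[match(hklKey(as.matrix(r[, 1:3])), hklKey(as.matrix(r2[, 1:3]))), ]
  expect_equal(r$I, r2$I, tolerance = 1e-12)
  ## single measurement: mean is the value, sigma flagged NA
  one <- monteCarloMerge(meas[1, ], cell, sym)
  expect_equal(reflections(one)$I, meas$I[1])
  expect_true(is.na(reflections(one)$sigma))
})

test_that("merged sigma approaches sigma/sqrt(n) for i.i.d. draws", {
  meas <- syntheticStream(nRefl = 200, nFrames = 100, mu = 50, sigma = 8,
                          seed = 7)
  r <- reflections(monteCarloMerge(meas, cell, sym))
  expect_equal(mean(r$sigma), 8 / sqrt(100), tolerance = 0.1)
})

test_that("half splits are balanced and keep frames together", {
  meas <- syntheticStream(nFrames = 21)
  halves <- splitHalf(meas, seed = 5)
  f1 <- unique(halves[[1]]$frame); f2 <- unique(halves[[2]]$frame)
  expect_lte(abs(length(f1) - length(f2)), 1)
  expect_length(intersect(f1, f2), 0)
  expect_setequal(c(f1, f2), 1:21)
  ## different seeds give different splits
  halves2 <- splitHalf(meas, seed = 6)
  expect_false(setequal(unique(halves2[[1]]$frame), f1))
})

test_that("R_split vanishes for identical halves and follows the closed form", {
  meas <- syntheticStream()
  m <- monteCarloMerge(meas, cell, sym)
  expect_equal(rSplit(m, m), 0)
  cc <- ccHalfStar(m, m)
  expect_equal(cc$ccHalf, 1)
  expect_equal(cc$ccStar, 1)
  ## halves (I, I (1 + eps)): R_split = 100/sqrt(2) eps / (1 + eps/2)
  eps <- 0.2
  r <- reflections(m)
  meas2 <- meas; meas2$I <- meas2$I * (1 + eps)
  m2 <- monteCarloMerge(meas2, cell, sym)
  expect_equal(rSplit(m, m2), 100 / sqrt(2) * eps / (1 + eps / 2),
               tolerance = 1e-9)
})

test_that("the CC* transform has the documented fixed points and values", {
  expect_equal(ccStar(1), 1)
  expect_equal(ccStar(0), 0)
  expect_equal(ccStar(1 / 3), sqrt(0.5))
  ## the published outer-shell pair: CC1/2 = 0.6825 maps to 0.9007
  expect_equal(ccStar(0.6825), 0.9007, tolerance = 1e-4)
  expect_true(is.na(ccStar(-0.5)))
  ## monotone increasing on (-1/3, 1] (signed extension below zero)
  x <- seq(-0.32, 1, by = 0.01)
  expect_true(all(diff(ccStar(x)) > 0))
})

test_that("shell statistics report completeness, redundancy, quality", {
  stream <- fixtureStream()
  st <- shellStatistics(stream$measurements, cell, sym, dMin = 2.09,
                        nShells = 10, seed = 1)
  expect_equal(nrow(st$shells), 10L)
  ## full synthetic coverage at this pattern count
  expect_true(all(st$shells$completeness > 99))
  expect_true(all(st$shells$completeness <= 100 + 1e-9))
  ## R_split grows toward high resolution (weak shells noisier)
  rs <- st$shells$rSplit
  expect_gt(mean(rs[8:10]), mean(rs[1:3]))
  ## CC* high in every shell at this redundancy
  expect_gt(min(st$shells$ccStar), 0.9)
  expect_gt(st$overall$redundancy, 10)
})

test_that("Wilson fit recovers the generating B factor", {
  stream <- fixtureStream()
  merged <- monteCarloMerge(stream$measurements, cell, sym)
  wf <- wilsonFit(merged)
  expect_equal(wf$B, 44.1, tolerance = 3 / 44.1)
  ## scaling all intensities changes the scale, not B
  meas2 <- stream$measurements; meas2$I <- meas2$I * 2
  wf2 <- wilsonFit(monteCarloMerge(meas2, cell, sym))
  expect_equal(wf2$B, wf$B, tolerance = 1e-9)
  expect_equal(wf2$scale, 2 * wf$scale, tolerance = 1e-6)
})

test_that("flat (B = 0) data fit a near-zero Wilson slope", {
  cfg0 <- defaultConfig()
  cfg0$simulator$wilson_b <- 0
  stream <- simulateMeasurementStream(cfg0, 150, seed = 12)
  wf <- wilsonFit(monteCarloMerge(stream$measurements, cell, sym))
  expect_lt(abs(wf$B), 1.5)
})

test_that("convergence follows the Monte Carlo 1/sqrt(n) law", {
  stream <- fixtureStream(1200, 9)
  conv <- convergenceAnalysis(stream$measurements,
                              c(75, 150, 300, 600, 1200), cell, sym,
                              seed = 2)
  expect_true(all(diff(conv$rSplit) < 0))
  expect_true(all(diff(conv$ccStar) > -0.02))
  slope <- unname(coef(lm(log(conv$rSplit) ~ log(conv$n)))[2])
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("quality report renders the data-collection block", {
  stream <- fixtureStream()
  q <- qualityReport(stream$measurements, cell, sym, dMin = 2.09,
                     nShells = 10, seed = 1)
  txt <- reportQuality(q)
  expect_true(any(grepl("Completeness", txt)))
  expect_true(any(grepl("R_split", txt)))
  expect_true(any(grepl("Wilson B", txt)))
  ## outer-shell values in parentheses
  expect_true(any(grepl("\\(\\d+\\.\\d+\\)", txt)))
})
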