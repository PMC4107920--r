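## Synthetic still-diffraction simulator with ground truth.
##
## The generator emulates a flowing-microcrystal snapshot experiment:
## Poisson crystal arrivals per frame, orientations uniform on rotations,
## Wilson-distributed true intensities with a settable Wilson B,
## excitation-error (Gaussian rocking) partiality, transit-time exposure
## spread from the laminar flow profile, flat + water-ring background with
## Poisson noise, and occasional azimuthal arc smearing of spots.

#' Sample true structure-factor amplitudes
#'
#' Draws |F|^2 for every non-absent ASU reflection with d >= dMin from an
#' exponential (acentric Wilson) intensity distribution whose shell mean
#' follows exp(-B s^2 / 2), s = 1/d, and stores |F|. Symmetry mates share
#' the ASU amplitude by construction.
#'
#' @param cell a [UnitCell-class]
#' @param sym a [SymmetryInfo-class]
#' @param dMin resolution limit, Angstrom
#' @param wilsonB Wilson B factor, Angstrom^2
#' @param seed RNG seed
#' @return a [StructureFactorSet-class]
#' @export
sampleStructureFactors <- function(cell, sym, dMin, wilsonB = 44.1,
                                   seed = 1L) {
  stopifnot(dMin > 0)
  refl <- uniqueReflections(cell, sym, dMin)
  s <- 1 / refl$d
  meanI <- exp(-wilsonB * s^2 / 2)
  set.seed(seed)
  I <- rexp(nrow(refl)) * meanI
  refl$amp <- sqrt(I)
  new("StructureFactorSet", reflections = refl, wilsonB = wilsonB,
      dMin = dMin, cell = cell, seed = as.integer(seed))
}

## transit-time sample (ms): crystals uniform over the usable capillary
## cross-section (10 um wall margin), Poiseuille velocity, truncated to
## the configured range; stands in for the turbulence-broadened spread
.sampleTransit <- function(n, flow, beam, range_ms) {
  Rin <- flow@innerDiameter / 2
  rmax <- max(Rin - 10, 0.5 * Rin)
  r <- rmax * sqrt(runif(n))
  v <- poiseuilleVelocity(flow, r)
  t <- transitTime(beam, v)
  pmin(pmax(t, range_ms[1]), range_ms[2])
}

#' Sample per-frame crystal events
#'
#' Number of crystals per frame is Poisson (or fixed when
#' `crystalsPerFrame` is an integer); orientations are i.i.d. uniform on
#' rotations; transit times follow the flow-profile-induced distribution
#' truncated to `transitRange`; a configurable fraction of crystals
#' "roll" about the beam axis, smearing their spots into constant-radius
#' arcs.
#'
#' @param config a pipeline configuration, see [defaultConfig()]
#' @param nFrames number of frames
#' @param seed RNG seed
#' @return data.frame with one row per crystal: frame, q1..q4
#'   (orientation quaternion), transit (ms), sizeScale, arcAngle (deg)
#' @export
sampleCrystalEvents <- function(config, nFrames, seed = 1L) {
  set.seed(seed)
  simc <- config$simulator
  cpf <- simc$crystals_per_frame
  if (identical(cpf, "poisson")) {
    if (simc$mean_crystals < 0) stop("mean crystals per frame must be >= 0")
    counts <- rpois(nFrames, simc$mean_crystals)
  } else {
    counts <- rep(as.integer(cpf), nFrames)
  }
  n <- sum(counts)
  if (n == 0L)
    return(data.frame(frame = integer(), q1 = numeric(), q2 = numeric(),
                      q3 = numeric(), q4 = numeric(), transit = numeric(),
                      sizeScale = numeric(), arcAngle = numeric()))
  qs <- randomRotations(n)
  beam <- configBeam(config); flow <- configFlow(config)
  transit <- .sampleTransit(n, flow, beam, simc$transit_range)
  sizeScale <- exp(rnorm(n, 0, simc$size_sigma))
  rolling <- runif(n) < simc$arc_fraction
  data.frame(frame = rep(seq_len(nFrames), counts),
             q1 = qs[, 1], q2 = qs[, 2], q3 = qs[, 3], q4 = qs[, 4],
             transit = transit, sizeScale = sizeScale,
             arcAngle = ifelse(rolling, simc$arc_angle, 0))
}

## effective rocking width (1/Angstrom) at |q|: quadrature sum of
## mosaicity, divergence and bandwidth terms (standard stills
## approximation)
.sigmaEff <- function(qlen, beam, mosaicity_deg, wl) {
  eta <- mosaicity_deg * pi / 180
  sqrt((eta * qlen)^2 + (beam@divergence / 2 * qlen)^2 +
         (beam@bandwidth * qlen^2 * wl / 2)^2)
}

## integer hkl grid within the resolution sphere, cached per (cell, dMin)
.hklGrid <- function(cell, sym, dMin) {
  p <- cellParameters(cell)
  key <- sprintf("hklgrid_%g_%g_%g_%g", p["a"], p["b"], p["c"], dMin)
  if (!is.null(.ssxCache[[key]])) return(.ssxCache[[key]])
  hmax <- floor(max(p["a"], p["b"]) / dMin); lmax <- floor(p["c"] / dMin)
  g <- as.matrix(expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -lmax:lmax))
  d <- dSpacing(cell, g)
  g <- g[is.finite(d) & d >= dMin & !isAbsent(sym, g), , drop = FALSE]
  .ssxCache[[key]] <- g
  g
}

#' Predict reflections for a still exposure
#'
#' Ewald-sphere construction for one crystal orientation: every non-absent
#' reflection out to `dMin` whose excitation error lies within
#' `nSigma` effective rocking widths (quadrature sum of mosaicity,
#' divergence and bandwidth terms) is returned with its Gaussian
#' partiality and detector position. Reflections projecting off-panel are
#' flagged (`onPanel`), not dropped.
#'
#' @param cell a [UnitCell-class]
#' @param sym a [SymmetryInfo-class]
#' @param rotation 3x3 orientation matrix (crystal -> laboratory)
#' @param beam a [BeamSpec-class]
#' @param det a [DetectorSpec-class]
#' @param mosaicity crystal mosaicity, degrees
#' @param dMin resolution limit, Angstrom
#' @param nSigma acceptance half-window in rocking widths
#' @return data.frame with h, k, l, d, qlen, zeta (excitation error,
#'   1/Angstrom), partiality, fast, slow, onPanel
#' @export
predictReflectionsStill <- function(cell, sym, rotation, beam, det,
                                    mosaicity = 0.05, dMin = 2.0,
                                    nSigma = 3) {
  wl <- wavelength(beam)
  H <- .hklGrid(cell, sym, dMin)
  B <- reciprocalMatrix(cell)
  g <- H %*% t(rotation %*% B)
  qlen <- sqrt(rowSums(g^2))
  ## excitation error: distance of the node from the Ewald sphere along
  ## the radial direction through the sphere center (positive inside)
  zeta <- 1 / wl - sqrt(g[, 1]^2 + g[, 2]^2 + (g[, 3] + 1 / wl)^2)
  sig <- .sigmaEff(qlen, beam, mosaicity, wl)
  keep <- if (all(sig > 0)) abs(zeta) <= nSigma * sig else
    abs(zeta) <= pmax(nSigma * sig, 1e-12)
  H <- H[keep, , drop = FALSE]; g <- g[keep, , drop = FALSE]
  qlen <- qlen[keep]; zeta <- zeta[keep]; sig <- sig[keep]
  part <- ifelse(sig > 0, exp(-zeta^2 / (2 * sig^2)),
                 as.numeric(abs(zeta) < 1e-12))
  px <- .qToPixel(g, det, wl)
  data.frame(h = H[, 1], k = H[, 2], l = H[, 3], d = 1 / qlen,
             qlen = qlen, zeta = zeta, partiality = part,
             fast = px$fast, slow = px$slow, onPanel = px$onPanel)
}

## background model: expected photons per pixel as a function of |q|
.backgroundMap <- function(det, beam, simc) {
  qmap <- .pixelQMap(det, wavelength(beam))
  simc$bg_flat + simc$ring_amp *
    exp(-(qmap - 1 / simc$ring_d)^2 / (2 * simc$ring_sigma_q^2))
}

## add one Gaussian spot (expected counts, no noise) to `img`; returns
## the maximum single-pixel expectation deposited
.stampSpot <- function(img, fast, slow, photons, psf, det, arcAngle = 0,
                       bcf, bcs) {
  positions <- cbind(fast, slow, photons)
  if (arcAngle > 0) {
    ## spread along a constant-radius arc about the beam center
    dx <- fast - bcf; dy <- slow - bcs
    rad <- sqrt(dx^2 + dy^2); phi0 <- atan2(dy, dx)
    narc <- max(5L, ceiling(arcAngle * 5))
    dphi <- (seq_len(narc) - (narc + 1) / 2) / narc * arcAngle * pi / 180
    positions <- cbind(bcf + rad * cos(phi0 + dphi),
                       bcs + rad * sin(phi0 + dphi), photons / narc)
  }
  w <- 3L  # stamp half-width, px (>= 3 psf sigma for psf = 1)
  maxpix <- 0
  for (i in seq_len(nrow(positions))) {
    f0 <- positions[i, 1]; s0 <- positions[i, 2]; ph <- positions[i, 3]
    fc <- round(f0); sc <- round(s0)
    ff <- (fc - w):(fc + w); ss <- (sc - w):(sc + w)
    okf <- ff >= 0 & ff <= ncol(img) - 1
    oks <- ss >= 0 & ss <= nrow(img) - 1
    if (!any(okf) || !any(oks)) next
    gf <- exp(-(ff[okf] - f0)^2 / (2 * psf^2))
    gs <- exp(-(ss[oks] - s0)^2 / (2 * psf^2))
    patch <- outer(gs, gf) / (2 * pi * psf^2) * ph
    img[ss[oks] + 1, ff[okf] + 1] <- img[ss[oks] + 1, ff[okf] + 1] + patch
    maxpix <- max(maxpix, max(patch))
  }
  list(img = img, maxpix = maxpix)
}

#' Render one synthetic frame
#'
#' Deposits every predicted spot of every crystal event as a 2D Gaussian
#' (or a constant-radius arc for rolling crystals), adds the flat +
#' water-ring background, and Poisson-samples the expected image. Spot
#' photons are `partiality x |F|^2 x intensity scale x (transit /
#' reference transit) x size scale`. A ground-truth record of every
#' rendered spot is returned alongside.
#'
#' @param events data.frame of crystal events for this frame (rows of
#'   [sampleCrystalEvents()] output)
#' @param sf a [StructureFactorSet-class]
#' @param config pipeline configuration
#' @param noise logical; Poisson-sample the image (TRUE) or return the
#'   expected image (FALSE)
#' @return list with `image` (integer matrix), `expected` (numeric
#'   matrix), and `truth` (data.frame: h, k, l, fast, slow, photons,
#'   partiality, maxPixel)
#' @export
renderFrame <- function(events, sf, config, noise = TRUE) {
  det <- configDetector(config); beam <- configBeam(config)
  simc <- config$simulator
  bg <- .backgroundMap(det, beam, simc)
  img <- matrix(0, det@nSlow, det@nFast)
  truth <- vector("list", nrow(events))
  refl <- sf@reflections
  key <- .hklKey(as.matrix(refl[, c("h", "k", "l")]))
  sym <- configSymmetry(config)
  for (i in seq_len(nrow(events))) {
    R <- quaternionToMatrix(as.numeric(events[i, c("q1", "q2", "q3", "q4")]))
    pred <- predictReflectionsStill(sf@cell, sym, R, beam, det,
                                    mosaicity = simc$mosaicity,
                                    dMin = sf@dMin,
                                    nSigma = simc$n_sigma)
    pred <- pred[pred$onPanel, , drop = FALSE]
    if (!nrow(pred)) next
    asu <- mapToASU(sym, as.matrix(pred[, c("h", "k", "l")]))
    amp <- refl$amp[match(.hklKey(asu), key)]
    photons <- simc$intensity_scale * amp^2 * pred$partiality *
      (events$transit[i] / simc$reference_transit) * events$sizeScale[i]
    keep <- !is.na(photons) & photons > 0.01
    pred <- pred[keep, , drop = FALSE]; photons <- photons[keep]
    maxpix <- numeric(length(photons))
    for (j in seq_along(photons)) {
      st <- .stampSpot(img, pred$fast[j], pred$slow[j], photons[j],
                       simc$psf_sigma, det, events$arcAngle[i],
                       det@beamCenterFast, det@beamCenterSlow)
      img <- st$img
      maxpix[j] <- st$maxpix
    }
    if (length(photons))
      truth[[i]] <- data.frame(h = pred$h, k = pred$k, l = pred$l,
                               fast = pred$fast, slow = pred$slow,
                               photons = photons,
                               partiality = pred$partiality,
                               maxPixel = maxpix)
  }
  expected <- img + bg
  out <- if (noise) {
    m <- matrix(rpois(length(expected), expected), nrow(expected))
    storage.mode(m) <- "integer"
    m
  } else expected
  truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  if (is.null(truth))
    truth <- data.frame(h = integer(), k = integer(), l = integer(),
                        fast = numeric(), slow = numeric(),
                        photons = numeric(), partiality = numeric(),
                        maxPixel = numeric())
  list(image = out, expected = expected, truth = truth)
}

#' Simulate a dataset of still frames
#'
#' Deterministic given the seed: samples structure factors once, crystal
#' events per frame, renders every frame and collects the ground-truth
#' sidecars.
#'
#' @param config pipeline configuration, see [defaultConfig()]
#' @param nFrames number of frames
#' @param seed RNG seed
#' @return a [FrameStack-class] with ground truth attached
#' @export
simulateDataset <- function(config, nFrames, seed = 1L) {
  cell <- configCell(config); sym <- configSymmetry(config)
  sf <- sampleStructureFactors(cell, sym, config$simulator$d_min,
                               config$simulator$wilson_b, seed = seed)
  events <- sampleCrystalEvents(config, nFrames, seed = seed + 1L)
  set.seed(seed + 2L)
  images <- vector("list", nFrames)
  truths <- vector("list", nFrames)
  for (fr in seq_len(nFrames)) {
    ev <- events[events$frame == fr, , drop = FALSE]
    rf <- renderFrame(ev, sf, config)
    images[[fr]] <- rf$image
    if (nrow(rf$truth)) {
      rf$truth$frame <- fr
      truths[[fr]] <- rf$truth
    }
  }
  truth <- do.call(rbind, truths[!vapply(truths, is.null, logical(1))])
  if (is.null(truth)) truth <- data.frame()
  stack <- new("FrameStack", images = images,
               detector = configDetector(config),
               beam = configBeam(config), truthEvents = events,
               truthReflections = truth)
  attr(stack, "structureFactors") <- sf
  stack
}

#' Simulate a measurement stream without rendering images
#'
#' Fast path for merging statistics at pattern counts where full image
#' rendering is unnecessary: applies the same orientation, partiality and
#' transit model as [renderFrame()] and emulates the integration step by
#' Poisson-sampling the spot photons and adding the background-subtraction
#' noise of the disc/annulus estimator, without rasterizing pixels.
#'
#' @param config pipeline configuration
#' @param nFrames number of single-crystal patterns
#' @param seed RNG seed
#' @return list with `measurements` (data.frame: frame, h, k, l (ASU), d,
#'   I, sigma) and `sf` (the [StructureFactorSet-class])
#' @export
simulateMeasurementStream <- function(config, nFrames, seed = 1L) {
  cell <- configCell(config); sym <- configSymmetry(config)
  simc <- config$simulator
  det <- configDetector(config); beam <- configBeam(config)
  sf <- sampleStructureFactors(cell, sym, simc$d_min, simc$wilson_b,
                               seed = seed)
  refl <- sf@reflections
  key <- .hklKey(as.matrix(refl[, c("h", "k", "l")]))
  set.seed(seed + 1L)
  qs <- randomRotations(nFrames)
  transit <- .sampleTransit(nFrames, configFlow(config), beam,
                            simc$transit_range)
  sizeScale <- exp(rnorm(nFrames, 0, simc$size_sigma))
  ## background-subtraction noise of the r=2/4-8 estimator at the flat
  ## background level (disc of 13 px, annulus variance propagated)
  nd <- nrow(.discOffsets(config$integration$r_disc))
  na <- nrow(.annulusOffsets(config$integration$r_bg_in,
                             config$integration$r_bg_out))
  out <- vector("list", nFrames)
  for (fr in seq_len(nFrames)) {
    R <- quaternionToMatrix(qs[fr, ])
    pred <- predictReflectionsStill(cell, sym, R, beam, det,
                                    mosaicity = simc$mosaicity,
                                    dMin = simc$d_min,
                                    nSigma = simc$n_sigma)
    pred <- pred[pred$onPanel, , drop = FALSE]
    if (!nrow(pred)) next
    asu <- mapToASU(sym, as.matrix(pred[, c("h", "k", "l")]))
    amp <- refl$amp[match(.hklKey(asu), key)]
    photons <- simc$intensity_scale * amp^2 * pred$partiality *
      (transit[fr] / simc$reference_transit) * sizeScale[fr]
    b <- simc$bg_flat + simc$ring_amp *
      exp(-(pred$qlen - 1 / simc$ring_d)^2 / (2 * simc$ring_sigma_q^2))
    sigBg <- sqrt(nd * b + nd^2 * b / na)
    I <- rpois(nrow(pred), photons) + rnorm(nrow(pred), 0, sigBg)
    out[[fr]] <- data.frame(frame = fr, h = asu[, 1], k = asu[, 2],
                            l = asu[, 3], d = pred$d, I = I,
                            sigma = sqrt(pmax(photons, 0) + sigBg^2))
  }
  meas <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  list(measurements = meas, sf = sf)
}
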