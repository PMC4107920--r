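## Central S4 containers. All user-facing geometry is in the units given in
## the slot documentation; internal computations convert where needed.

#' Beam specification
#'
#' Describes the incident X-ray beam: photon energy, flux, focal spot size,
#' fractional bandwidth and divergence. The wavelength is derived from the
#' photon energy via [energyToWavelength()] and available through
#' [wavelength()].
#'
#' @slot photonEnergy photon energy in eV
#' @slot flux photons per second through the focus
#' @slot focusH,focusV horizontal/vertical focus size (FWHM-like extent), um
#' @slot bandwidth fractional energy spread dE/E
#' @slot divergence beam divergence, rad
#' @export
setClass("BeamSpec",
  representation(photonEnergy = "numeric", flux = "numeric",
                 focusH = "numeric", focusV = "numeric",
                 bandwidth = "numeric", divergence = "numeric"))

setValidity("BeamSpec", function(object) {
  msg <- character()
  for (s in c("photonEnergy", "flux", "focusH", "focusV"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
        slot(object, s) <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  if (object@bandwidth < 0 || object@bandwidth >= 0.1)
    msg <- c(msg, "'bandwidth' must lie in [0, 0.1)")
  if (object@divergence < 0 || object@divergence >= 0.1)
    msg <- c(msg, "'divergence' must lie in [0, 0.1) rad")
  if (length(msg)) msg else TRUE
})

#' Construct a BeamSpec
#'
#' Defaults reproduce a monochromatic microfocus beamline setting:
#' 9800 eV, 2e12 photons/s focused to 9 um x 6 um with 0.01% bandwidth and
#' 1 mrad divergence.
#'
#' @param photonEnergy photon energy, eV
#' @param flux photons per second
#' @param focusH,focusV focus size, um
#' @param bandwidth fractional dE/E
#' @param divergence beam divergence, rad
#' @return a [BeamSpec-class] object
#' @examples
#' beam <- beamSpec()
#' wavelength(beam)
#' @export
beamSpec <- function(photonEnergy = 9800, flux = 2e12, focusH = 9,
                     focusV = 6, bandwidth = 1e-4, divergence = 1e-3) {
  new("BeamSpec", photonEnergy = photonEnergy, flux = flux,
      focusH = focusH, focusV = focusV, bandwidth = bandwidth,
      divergence = divergence)
}

#' Detector specification
#'
#' A single flat panel normal to the beam. Pixel indices are 0-based with
#' pixel (0, 0) at the fast/slow origin; laboratory positions are measured
#' in mm from the beam center. Images are stored as `nSlow x nFast`
#' matrices, i.e. `image[slow + 1, fast + 1]`.
#'
#' @slot nFast,nSlow panel size in pixels along the fast/slow axis
#' @slot pixelSize pixel edge, mm
#' @slot distance sample-to-detector distance, mm
#' @slot beamCenterFast,beamCenterSlow beam center in (0-based) pixels
#' @export
setClass("DetectorSpec",
  representation(nFast = "integer", nSlow = "integer", pixelSize = "numeric",
                 distance = "numeric", beamCenterFast = "numeric",
                 beamCenterSlow = "numeric"))

setValidity("DetectorSpec", function(object) {
  msg <- character()
  if (object@nFast < 1L || object@nSlow < 1L)
    msg <- c(msg, "panel must contain at least one pixel")
  if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
  if (object@distance <= 0) msg <- c(msg, "'distance' must be > 0")
  if (object@beamCenterFast < 0 || object@beamCenterFast > object@nFast - 1 ||
      object@beamCenterSlow < 0 || object@beamCenterSlow > object@nSlow - 1)
    msg <- c(msg, "beam center must lie inside the panel")
  if (length(msg)) msg else TRUE
})

#' Construct a DetectorSpec
#'
#' @param nFast,nSlow panel size, pixels
#' @param pixelSize pixel edge, mm
#' @param distance sample-detector distance, mm
#' @param beamCenterFast,beamCenterSlow beam center, 0-based pixels;
#'   default panel center
#' @return a [DetectorSpec-class]
#' @export
detectorSpec <- function(nFast, nSlow, pixelSize, distance,
                         beamCenterFast = (nFast - 1) / 2,
                         beamCenterSlow = (nSlow - 1) / 2) {
  new("DetectorSpec", nFast = as.integer(nFast), nSlow = as.integer(nSlow),
      pixelSize = pixelSize, distance = distance,
      beamCenterFast = beamCenterFast, beamCenterSlow = beamCenterSlow)
}

#' Pilatus 6M geometry at 300 mm
#'
#' Full-size hybrid pixel panel (2463 x 2527 pixels of 0.172 mm) with a
#' centered beam, as used for the closed-form geometry calculations.
#' @param distance sample-detector distance, mm
#' @return a [DetectorSpec-class]
#' @export
pilatus6M <- function(distance = 300) {
  detectorSpec(2463L, 2527L, 0.172, distance)
}

#' Reduced-scale virtual detector for simulations
#'
#' A 600 x 600 panel of 0.7 mm pixels at 300 mm covering the same angular
#' range (about 2.1 Angstrom at the center edge at 1.27 Angstrom wavelength)
#' as the full-size panel, at a pixel count tractable for simulation.
#' @param distance sample-detector distance, mm
#' @return a [DetectorSpec-class]
#' @export
virtualDetector <- function(distance = 300) {
  detectorSpec(600L, 600L, 0.7, distance)
}

#' Capillary flow specification
#'
#' @slot innerDiameter capillary inner diameter, um
#' @slot flowRate volumetric flow rate, ul/min
#' @slot viscosity dynamic viscosity, mPa s
#' @slot density fluid density, kg/m^3
#' @export
setClass("CapillaryFlow",
  representation(innerDiameter = "numeric", flowRate = "numeric",
                 viscosity = "numeric", density = "numeric"))

setValidity("CapillaryFlow", function(object) {
  vals <- c(object@innerDiameter, object@flowRate, object@viscosity,
            object@density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    "all flow parameters must be positive and finite" else TRUE
})

#' Construct a CapillaryFlow
#'
#' Defaults describe a crystal slurry pushed at 2.5 ul/min through a 100 um
#' inner-diameter capillary. The default viscosity (46 mPa s) is a plausible
#' value for a dense PEG-containing crystal suspension; it is a configuration
#' input, not a measured constant.
#'
#' @param innerDiameter inner diameter, um
#' @param flowRate flow rate, ul/min
#' @param viscosity dynamic viscosity, mPa s
#' @param density density, kg/m^3
#' @return a [CapillaryFlow-class]
#' @export
capillaryFlow <- function(innerDiameter = 100, flowRate = 2.5,
                          viscosity = 46, density = 1000) {
  new("CapillaryFlow", innerDiameter = innerDiameter, flowRate = flowRate,
      viscosity = viscosity, density = density)
}

#' Unit cell
#'
#' @slot a,b,c cell edges, Angstrom
#' @slot alpha,beta,gamma cell angles, degrees
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"))

setValidity("UnitCell", function(object) {
  msg <- character()
  if (any(c(object@a, object@b, object@c) <= 0))
    msg <- c(msg, "cell lengths must be positive")
  ang <- c(object@alpha, object@beta, object@gamma)
  if (any(ang <= 0) || any(ang >= 180))
    msg <- c(msg, "cell angles must lie in (0, 180) degrees")
  if (length(msg)) msg else TRUE
})

#' Construct a UnitCell
#' @param a,b,c cell edges, Angstrom
#' @param alpha,beta,gamma cell angles, degrees
#' @return a [UnitCell-class]
#' @export
unitCell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = a, b = b, c = c, alpha = alpha, beta = beta,
      gamma = gamma)
}

#' Tetragonal unit cell (a = b, all angles 90 degrees)
#' @param a,c cell edges, Angstrom
#' @return a [UnitCell-class]
#' @export
tetragonalCell <- function(a, c) unitCell(a = a, b = a, c = c)

#' Space-group symmetry information
#'
#' Holds the rotational point group used for orientation degeneracy, the
#' Laue group used for merging (Friedel mates included), and the
#' systematic-absence rule. The default constructor [symmetryP43212()]
#' describes space group P4(3)2(1)2 (point group 422, Laue group 4/mmm)
#' with the 4(3) screw-axis rule (0,0,l): l = 4n and the 2(1) rules
#' (h,0,0): h even, (0,k,0): k even.
#'
#' @slot spaceGroup space-group symbol
#' @slot pointGroup point-group symbol
#' @slot laueGroup Laue-group symbol
#' @slot pointOps list of 3x3 integer rotation matrices (proper rotations)
#' @slot laueOps list of 3x3 integer matrices of the Laue group (with
#'   inversion)
#' @export
setClass("SymmetryInfo",
  representation(spaceGroup = "character", pointGroup = "character",
                 laueGroup = "character", pointOps = "list",
                 laueOps = "list"))

setValidity("SymmetryInfo", function(object) {
  ok <- vapply(c(object@pointOps, object@laueOps), function(m)
    is.matrix(m) && all(dim(m) == c(3L, 3L)) && abs(abs(det(m)) - 1) < 1e-9,
    logical(1))
  if (!all(ok)) "all symmetry operations must be 3x3 unimodular matrices"
  else TRUE
})

#' Sampled structure-factor amplitudes
#'
#' True amplitudes for every non-absent reflection in the reciprocal-space
#' asymmetric unit to a resolution limit, drawn from a Wilson intensity
#' distribution with exponential falloff exp(-B s^2 / 2), s = 1/d.
#'
#' @slot reflections data.frame with columns h, k, l (ASU indices), d
#'   (Angstrom) and amp (amplitude, arbitrary scale)
#' @slot wilsonB Wilson B factor used for generation, Angstrom^2
#' @slot dMin resolution limit, Angstrom
#' @slot cell the [UnitCell-class] used
#' @slot seed RNG seed used
#' @export
setClass("StructureFactorSet",
  representation(reflections = "data.frame", wilsonB = "numeric",
                 dMin = "numeric", cell = "UnitCell", seed = "integer"))

#' A stack of still-diffraction frames
#'
#' @slot images list of integer photon-count matrices (`nSlow x nFast`)
#' @slot detector the [DetectorSpec-class]
#' @slot beam the [BeamSpec-class]
#' @slot truthEvents data.frame of simulated crystal events (one row per
#'   crystal; empty for real data)
#' @slot truthReflections data.frame of per-spot ground truth (empty for
#'   real data)
#' @export
setClass("FrameStack",
  representation(images = "list", detector = "DetectorSpec",
                 beam = "BeamSpec", truthEvents = "data.frame",
                 truthReflections = "data.frame"))

setValidity("FrameStack", function(object) {
  d <- object@detector
  ok <- vapply(object@images, function(im)
    is.matrix(im) && nrow(im) == d@nSlow && ncol(im) == d@nFast &&
      min(im) >= 0, logical(1))
  if (!all(ok)) "images must be non-negative nSlow x nFast matrices"
  else TRUE
})

#' Indexed crystal orientation for one frame
#'
#' @slot rotation 3x3 orthonormal rotation matrix (crystal -> laboratory)
#' @slot cell refined [UnitCell-class]
#' @slot nIndexed number of peaks consistent with the lattice
#' @slot nPeaks number of peaks given to the indexer
#' @slot rmsResidual rms distance between observed scattering vectors and
#'   assigned reciprocal-lattice nodes, 1/Angstrom
#' @export
setClass("CrystalOrientation",
  representation(rotation = "matrix", cell = "UnitCell",
                 nIndexed = "integer", nPeaks = "integer",
                 rmsResidual = "numeric"))

setValidity("CrystalOrientation", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    return("rotation must be a proper orthonormal 3x3 matrix")
  if (object@nIndexed > object@nPeaks)
    return("cannot index more peaks than were observed")
  TRUE
})

#' Merged unique-reflection dataset
#'
#' Monte Carlo merge of snapshot measurements: per unique (ASU) reflection
#' the mean intensity on an arbitrary common scale, the standard error of
#' that mean estimated from the scatter of the individual measurements, and
#' the redundancy.
#'
#' @slot reflections data.frame with columns h, k, l, d, I, sigma, n
#' @slot cell the [UnitCell-class]
#' @slot sym the [SymmetryInfo-class]
#' @slot nPatterns number of patterns contributing
#' @export
setClass("MergedDataset",
  representation(reflections = "data.frame", cell = "UnitCell",
                 sym = "SymmetryInfo", nPatterns = "integer"))

#' Data-quality report
#'
#' Per-resolution-shell and overall half-set statistics.
#'
#' @slot shells data.frame with one row per shell: dMax, dMin, nUnique,
#'   completeness (%), redundancy, meanIsigma, rSplit (%), ccHalf, ccStar
#' @slot overall one-row data.frame with the same columns over the full
#'   resolution range
#' @slot wilsonB fitted Wilson B factor, Angstrom^2
#' @slot nPatterns number of merged patterns
#' @export
setClass("QualityReport",
  representation(shells = "data.frame", overall = "data.frame",
                 wilsonB = "numeric", nPatterns = "integer"))
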