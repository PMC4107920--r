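## Closed-form beamline and microfluidics arithmetic.

#' Convert photon energy to wavelength
#'
#' lambda = hc / E with hc = 12398.42 eV Angstrom. 9800 eV gives 1.265
#' Angstrom (commonly quoted rounded to 1.27).
#'
#' @param photonEnergy photon energy, eV
#' @return wavelength, Angstrom
#' @examples
#' energyToWavelength(9800)
#' @export
energyToWavelength <- function(photonEnergy) {
  if (any(!is.finite(photonEnergy)) || any(photonEnergy <= 0))
    stop("'photonEnergy' must be positive")
  HC_EV_ANGSTROM / photonEnergy
}

#' Convert wavelength to photon energy
#' @param wavelength wavelength, Angstrom
#' @return photon energy, eV
#' @export
wavelengthToEnergy <- function(wavelength) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop("'wavelength' must be positive")
  HC_EV_ANGSTROM / wavelength
}

#' Mean flow velocity in a capillary
#'
#' v = Q / (pi (D/2)^2). For 2.5 ul/min in a 100 um capillary this is
#' 5.3 mm/s.
#'
#' @param flow a [CapillaryFlow-class]
#' @return mean velocity, mm/s
#' @export
meanFlowVelocity <- function(flow) {
  stopifnot(is(flow, "CapillaryFlow"))
  q_m3s <- flow@flowRate * 1e-9 / 60          # ul/min -> m^3/s
  area_m2 <- pi * (flow@innerDiameter * 1e-6 / 2)^2
  q_m3s / area_m2 * 1e3                        # m/s -> mm/s
}

#' Laminar (Poiseuille) velocity profile
#'
#' v(r) = 2 v_mean (1 - (r/R)^2) for a Newtonian laminar flow; zero at the
#' wall, 2 v_mean on the axis.
#'
#' @param flow a [CapillaryFlow-class]
#' @param r radial offset from the capillary axis, um (vectorized)
#' @return velocity, mm/s
#' @export
poiseuilleVelocity <- function(flow, r) {
  stopifnot(is(flow, "CapillaryFlow"))
  R <- flow@innerDiameter / 2
  if (any(r < 0) || any(r > R))
    stop("'r' must lie in [0, R] with R the inner radius")
  2 * meanFlowVelocity(flow) * (1 - (r / R)^2)
}

#' Flow profile summary
#'
#' @param flow a [CapillaryFlow-class]
#' @return list with `meanVelocity` and `centerlineVelocity` (mm/s),
#'   `reynolds`, and `velocityAt(r)` (r in um)
#' @export
flowProfile <- function(flow) {
  vm <- meanFlowVelocity(flow)
  list(meanVelocity = vm, centerlineVelocity = 2 * vm,
       reynolds = reynoldsNumber(flow),
       velocityAt = function(r) poiseuilleVelocity(flow, r))
}

#' Crystal transit time across the focus
#'
#' t = (horizontal focus width) / velocity. A 9 um focus crossed at
#' 3 mm/s gives 3 ms.
#'
#' @param beam a [BeamSpec-class]
#' @param velocity flow velocity, mm/s (vectorized)
#' @return transit time, ms
#' @export
transitTime <- function(beam, velocity) {
  stopifnot(is(beam, "BeamSpec"))
  if (any(velocity <= 0)) stop("'velocity' must be positive")
  beam@focusH / velocity                       # um / (mm/s) = um s/mm = ms/1000*1000
}

#' Reynolds number of the capillary flow
#'
#' Re = rho v_mean D / mu, with the mean velocity from the flow rate.
#' Values far below 1 indicate deeply laminar flow.
#'
#' @param flow a [CapillaryFlow-class]
#' @return dimensionless Reynolds number
#' @export
reynoldsNumber <- function(flow) {
  stopifnot(is(flow, "CapillaryFlow"))
  v_ms <- meanFlowVelocity(flow) * 1e-3        # m/s
  d_m <- flow@innerDiameter * 1e-6
  mu <- flow@viscosity * 1e-3                  # Pa s
  flow@density * v_ms * d_m / mu
}

## Tabulated mass energy-absorption coefficients for liquid water,
## cm^2/g, 5-20 keV; interpolated log-log.
.WATER_MU_EN <- data.frame(
  keV = c(5, 6, 8, 10, 15, 20),
  muEn = c(41.9, 23.0, 9.92, 4.94, 1.37, 0.550))

#' Mass energy-absorption coefficient of water
#'
#' Log-log interpolation of tabulated values between 5 and 20 keV.
#'
#' @param photonEnergy photon energy, eV
#' @return mu_en/rho, cm^2/g
#' @export
waterMassEnergyAbsorption <- function(photonEnergy) {
  keV <- photonEnergy / 1000
  if (any(keV < 5) || any(keV > 20))
    stop("water mu_en/rho table covers 5-20 keV")
  exp(approx(log(.WATER_MU_EN$keV), log(.WATER_MU_EN$muEn),
             xout = log(keV))$y)
}

#' Simplified absorbed-dose estimate
#'
#' Thin-sample, monochromatic mass-energy-absorption model:
#' fluence = flux t / (focus area); dose = fluence x E_photon(J) x
#' mu_en/rho, reported in MGy (1 MGy = 1e3 J/g). This is a deliberate
#' simplification of a full dose program (no photoelectron escape, no
#' explicit sample composition); the coefficient defaults to the water
#' value at the beam energy.
#'
#' @param beam a [BeamSpec-class]
#' @param exposureTime exposure, s
#' @param massEnergyAbsorption mu_en/rho, cm^2/g; default water at the
#'   beam energy
#' @return list with `exposureTime` (s), `fluence` (photons/cm^2),
#'   `energyFluence` (J/cm^2), `massEnergyAbsorption` (cm^2/g) and
#'   `dose` (MGy)
#' @examples
#' estimateDose(beamSpec(), 3e-3)$dose  # about 0.1 MGy
#' @export
estimateDose <- function(beam, exposureTime,
                         massEnergyAbsorption = NULL) {
  stopifnot(is(beam, "BeamSpec"))
  if (any(exposureTime < 0)) stop("'exposureTime' must be >= 0")
  if (is.null(massEnergyAbsorption))
    massEnergyAbsorption <- waterMassEnergyAbsorption(beam@photonEnergy)
  area_cm2 <- (beam@focusH * 1e-4) * (beam@focusV * 1e-4)
  fluence <- beam@flux * exposureTime / area_cm2
  e_joule <- beam@photonEnergy * 1.602176634e-19
  energyFluence <- fluence * e_joule
  dose <- energyFluence * massEnergyAbsorption / 1e3   # J/g -> MGy
  list(exposureTime = exposureTime, fluence = fluence,
       energyFluence = energyFluence,
       massEnergyAbsorption = massEnergyAbsorption, dose = dose)
}

#' Resolution at the center edge of the detector
#'
#' d = lambda / (2 sin theta) with 2 theta = atan(s / distance) and s the
#' shortest distance from the beam center to a panel edge.
#'
#' @param det a [DetectorSpec-class]
#' @param beam a [BeamSpec-class]
#' @return resolution, Angstrom
#' @export
edgeResolution <- function(det, beam) {
  stopifnot(is(det, "DetectorSpec"), is(beam, "BeamSpec"))
  s <- min(det@beamCenterFast, det@nFast - 1 - det@beamCenterFast,
           det@beamCenterSlow, det@nSlow - 1 - det@beamCenterSlow) *
    det@pixelSize
  tth <- atan2(s, det@distance)
  wavelength(beam) / (2 * sin(tth / 2))
}

#' Resolution at the detector corner
#' @inheritParams edgeResolution
#' @return resolution, Angstrom
#' @export
cornerResolution <- function(det, beam) {
  sx <- max(det@beamCenterFast, det@nFast - 1 - det@beamCenterFast) *
    det@pixelSize
  sy <- max(det@beamCenterSlow, det@nSlow - 1 - det@beamCenterSlow) *
    det@pixelSize
  tth <- atan2(sqrt(sx^2 + sy^2), det@distance)
  wavelength(beam) / (2 * sin(tth / 2))
}

#' Number of unit cells in a crystal
#'
#' @param crystalVolume crystal volume, um^3
#' @param cell a [UnitCell-class]
#' @return unit-cell count
#' @examples
#' unitCellCount(135, unitCell(79.5, 79.4, 38.4))  # about 5e8
#' @export
unitCellCount <- function(crystalVolume, cell) {
  if (any(crystalVolume <= 0)) stop("'crystalVolume' must be positive")
  crystalVolume * 1e12 / cellVolume(cell)      # 1 um^3 = 1e12 A^3
}

#' Acquisition budget arithmetic
#'
#' Wall-clock time, detector dead time and sample consumption for a
#' fixed-rate acquisition. 1.5e6 frames at 25 Hz take 6e4 s (about 17 h);
#' a 10 ms exposure at 25 Hz means 75% dead time.
#'
#' @param frameRate detector frame rate, Hz
#' @param exposureTime exposure per frame, s
#' @param nFrames number of frames
#' @param flow a [CapillaryFlow-class] (for consumed volume)
#' @return list with `totalTime` (s), `totalHours`, `deadTimeFraction`,
#'   `consumedVolume` (ul)
#' @export
acquisitionBudget <- function(frameRate, exposureTime, nFrames, flow) {
  if (frameRate <= 0) stop("'frameRate' must be positive")
  if (exposureTime * frameRate > 1 + 1e-12)
    stop("exposure longer than the frame period")
  totalTime <- nFrames / frameRate
  list(frameRate = frameRate, exposureTime = exposureTime,
       nFrames = nFrames, totalTime = totalTime,
       totalHours = totalTime / 3600,
       deadTimeFraction = 1 - exposureTime * frameRate,
       consumedVolume = flow@flowRate * totalTime / 60)
}

#' Rotational Brownian diffusion, order of magnitude
#'
#' D_rot = kT / (8 pi mu r^3) for a sphere of radius r in a medium of
#' viscosity mu; returns the rms rotation angle accumulated in `time`.
#' Order-of-magnitude helper only.
#'
#' @param radius particle radius, um
#' @param viscosity dynamic viscosity, mPa s
#' @param time interval, s
#' @param temperature temperature, K
#' @return rms rotation, degrees
#' @export
brownianRotation <- function(radius, viscosity, time, temperature = 293) {
  kT <- 1.380649e-23 * temperature
  Drot <- kT / (8 * pi * viscosity * 1e-3 * (radius * 1e-6)^3)  # rad^2/s
  sqrt(2 * Drot * time) * 180 / pi
}
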