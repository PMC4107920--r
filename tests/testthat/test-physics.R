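test_that("energy-wavelength conversion uses hc = 12398.42 eV A", {
  expect_equal(energyToWavelength(12398.42), 1.0)
  expect_equal(energyToWavelength(6199.21), 2.0)
  expect_equal(round(energyToWavelength(9800), 2), 1.27)
  ## round trip is the identity
  e <- c(5000, 9800, 12000, 20000)
  expect_equal(wavelengthToEnergy(energyToWavelength(e)), e,
               tolerance = 1e-12)
  expect_error(energyToWavelength(0))
  expect_error(energyToWavelength(-1))
})

test_that("mean flow velocity follows Q / (pi R^2)", {
  fl <- capillaryFlow(innerDiameter = 100, flowRate = 2.5)
  expect_equal(meanFlowVelocity(fl), 5.305, tolerance = 1e-3)
  ## linear in flow rate
  expect_equal(meanFlowVelocity(capillaryFlow(flowRate = 5)),
               2 * meanFlowVelocity(capillaryFlow(flowRate = 2.5)),
               tolerance = 1e-12)
  ## inverse square in diameter
  expect_equal(meanFlowVelocity(capillaryFlow(innerDiameter = 200)),
               meanFlowVelocity(capillaryFlow(innerDiameter = 100)) / 4,
               tolerance = 1e-12)
})

test_that("Poiseuille profile is parabolic with no-slip boundary", {
  fl <- capillaryFlow()
  vm <- meanFlowVelocity(fl)
  expect_equal(poiseuilleVelocity(fl, 0), 2 * vm)
  expect_equal(poiseuilleVelocity(fl, 50), 0)
  ## 10 um from the wall of a 100 um capillary: 0.72 x centerline
  ## (the exact parabolic value; 3.6 mm/s for v_mean = 5 mm/s)
  expect_equal(poiseuilleVelocity(fl, 40), 2 * vm * (1 - 0.8^2))
  ## monotonically decreasing in |r|
  v <- poiseuilleVelocity(fl, seq(0, 50, by = 5))
  expect_true(all(diff(v) < 0))
  expect_error(poiseuilleVelocity(fl, 60))
  ## integrates over the cross-section to v_mean x area (quadrature)
  r <- seq(0, 50, length.out = 20001)
  integrand <- poiseuilleVelocity(fl, r) * 2 * pi * r
  integral <- sum((integrand[-1] + integrand[-length(r)]) / 2 * diff(r))
  expect_equal(integral, vm * pi * 50^2, tolerance = 1e-3)
})

test_that("transit time is focus width over velocity", {
  beam <- beamSpec()        # 9 um horizontal focus
  expect_equal(transitTime(beam, 3), 3)
  expect_equal(transitTime(beam, 9), 1)
  expect_equal(transitTime(beam, 10), 0.9)
  expect_error(transitTime(beam, 0))
})

test_that("Reynolds number is rho v D / mu and deeply laminar here", {
  water <- capillaryFlow(viscosity = 1, density = 1000)
  expect_equal(reynoldsNumber(water), 0.5305, tolerance = 1e-3)
  ## inverse proportional to viscosity
  expect_equal(reynoldsNumber(capillaryFlow(viscosity = 2)),
               reynoldsNumber(capillaryFlow(viscosity = 1)) / 2,
               tolerance = 1e-12)
  ## the default slurry viscosity puts Re near 0.0115, far below
  ## turbulence onset
  expect_lt(reynoldsNumber(capillaryFlow()), 0.1)
})

test_that("dose model is linear in exposure and uses mu_en/rho", {
  beam <- beamSpec()
  d3 <- estimateDose(beam, 3e-3)
  expect_equal(estimateDose(beam, 0)$dose, 0)
  expect_equal(estimateDose(beam, 6e-3)$dose, 2 * d3$dose,
               tolerance = 1e-12)
  ## with the quoted tabulated coefficient 4.9 cm^2/g near 10 keV
  d <- estimateDose(beam, 3e-3, massEnergyAbsorption = 4.9)
  expect_equal(d$fluence, 2e12 * 3e-3 / (9e-4 * 6e-4), tolerance = 1e-9)
  expect_equal(d$dose, 0.0855, tolerance = 0.01)
})

test_that("water mu_en/rho table interpolates sensibly", {
  expect_equal(waterMassEnergyAbsorption(10000), 4.94, tolerance = 1e-6)
  m <- waterMassEnergyAbsorption(9800)
  expect_gt(m, 4.94)          # below 10 keV absorption rises
  expect_lt(m, 9.92)
  expect_error(waterMassEnergyAbsorption(3000))
})

test_that("edge resolution geometry is exact and monotone", {
  det <- pilatus6M(); beam <- beamSpec()
  d <- edgeResolution(det, beam)
  expect_equal(d, 2.09, tolerance = 0.005)
  ## monotone increasing in distance and wavelength
  expect_gt(edgeResolution(pilatus6M(400), beam), d)
  expect_gt(edgeResolution(det, beamSpec(photonEnergy = 8000)), d)
  ## corner always resolves finer than center edge
  expect_lt(cornerResolution(det, beam), d)
})

test_that("unit-cell count is volume ratio with unit conversion", {
  cell <- unitCell(79.5, 79.4, 38.4)
  n <- unitCellCount(135, cell)
  expect_equal(n, 135e12 / cellVolume(cell), tolerance = 1e-12)
  expect_equal(unitCellCount(270, cell), 2 * n, tolerance = 1e-12)
  one <- cellVolume(cell) * 1e-12
  expect_equal(unitCellCount(one, cell), 1, tolerance = 1e-9)
})

test_that("acquisition budget arithmetic", {
  fl <- capillaryFlow()
  b <- acquisitionBudget(25, 0.010, 1.5e6, fl)
  expect_equal(b$totalTime, 6e4)
  expect_equal(b$deadTimeFraction, 0.75)
  expect_equal(b$consumedVolume, 2500)   # ul = 2.5 ml
  z <- acquisitionBudget(25, 0.010, 0, fl)
  expect_equal(z$totalTime, 0)
  expect_equal(z$consumedVolume, 0)
  expect_error(acquisitionBudget(25, 0.05, 10, fl))
  ## exact linearity in frame count
  expect_equal(acquisitionBudget(25, 0.01, 3e6, fl)$totalTime,
               2 * b$totalTime, tolerance = 1e-12)
})

test_that("experiment plan collects the derived quantities", {
  plan <- planExperiment(defaultConfig())
  expect_true(all(c("wavelength", "Reynolds number", "edge resolution",
                    "dead-time fraction") %in% plan$quantity))
  expect_true(all(is.finite(plan$value)))
})
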