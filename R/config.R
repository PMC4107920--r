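## Pipeline configuration: a nested list, YAML-serializable, with every
## default equal to the published experimental parameter where one exists
## (9800 eV, 0.01% bandwidth, 1 mrad divergence, 300 mm, 25-count peak
## threshold, 15/200 peak bounds, r = 2/4/8 px integration radii).

#' Default pipeline configuration
#'
#' @param detectorPreset `"virtual"` for the reduced 600 x 600 simulation
#'   panel or `"pilatus6m"` for the full-size panel
#' @return nested configuration list (class `ssxConfig`)
#' @examples
#' cfg <- defaultConfig()
#' cfg$beam$photon_energy
#' @export
defaultConfig <- function(detectorPreset = c("virtual", "pilatus6m")) {
  detectorPreset <- match.arg(detectorPreset)
  det <- if (detectorPreset == "virtual") virtualDetector() else pilatus6M()
  cfg <- list(
    beam = list(photon_energy = 9800, flux = 2e12, focus_h = 9,
                focus_v = 6, bandwidth = 1e-4, divergence = 1e-3),
    detector = list(n_fast = det@nFast, n_slow = det@nSlow,
                    pixel_size = det@pixelSize, distance = det@distance,
                    beam_center_fast = det@beamCenterFast,
                    beam_center_slow = det@beamCenterSlow),
    flow = list(inner_diameter = 100, flow_rate = 2.5, viscosity = 46,
                density = 1000),
    crystal = list(cell_a = 79.5, cell_c = 38.4, space_group = "P43212",
                   volume = 135, edge_length = 3, long_axis = 6),
    acquisition = list(frame_rate = 25, exposure_time = 0.010),
    simulator = list(wilson_b = 44.1, d_min = 2.05,
                     crystals_per_frame = "poisson", mean_crystals = 0.3,
                     intensity_scale = 5000, psf_sigma = 1,
                     bg_flat = 0.5, ring_d = 3.5, ring_amp = 2,
                     ring_sigma_q = 0.04, arc_fraction = 0.1,
                     arc_angle = 5, transit_range = c(1, 3),
                     reference_transit = 3, size_sigma = 0.25,
                     mosaicity = 0.05, n_sigma = 3),
    peaks = list(threshold = 25, min_peaks = 15, max_peaks = 200,
                 k_sigma = 2, max_radius = 4, bg_half_width = 7),
    indexing = list(grid_step = 1.5, min_indexed_frac = 0.5,
                    min_peaks = 16, tol_frac = 0.8),
    integration = list(r_disc = 2, r_bg_in = 4, r_bg_out = 8,
                       bg_stat = "median", mosaicity = 0.05, n_sigma = 3),
    merge = list(n_shells = 10, d_min = 2.09),
    seed = 1)
  class(cfg) <- c("ssxConfig", "list")
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the schema (required blocks and fields, positivity, bounds) and
#' returns the configuration invisibly; signals a condition of class
#' `ssxConfigError` otherwise.
#'
#' @param config configuration list
#' @return config, invisibly
#' @export
validateConfig <- function(config) {
  fail <- function(msg) stop(errorCondition(msg,
    class = c("ssxConfigError", "error")))
  blocks <- c("beam", "detector", "flow", "crystal", "simulator",
              "peaks", "indexing", "integration", "merge")
  miss <- setdiff(blocks, names(config))
  if (length(miss)) fail(paste("missing config blocks:",
                               paste(miss, collapse = ", ")))
  tryCatch({
    configBeam(config); configDetector(config); configFlow(config)
    configCell(config)
  }, error = function(e) fail(conditionMessage(e)))
  if (config$peaks$threshold <= 0) fail("peak threshold must be positive")
  if (config$peaks$min_peaks >= config$peaks$max_peaks)
    fail("min_peaks must be below max_peaks")
  with(config$integration,
       if (!(r_disc < r_bg_in && r_bg_in < r_bg_out))
         fail("integration radii must satisfy r_disc < r_bg_in < r_bg_out"))
  if (config$simulator$d_min <= 0) fail("simulator d_min must be positive")
  invisible(config)
}

#' @rdname configAccessors
#' @export
configBeam <- function(config) {
  b <- config$beam
  beamSpec(b$photon_energy, b$flux, b$focus_h, b$focus_v, b$bandwidth,
           b$divergence)
}

#' Configuration block accessors
#'
#' Build the typed S4 objects from the corresponding configuration
#' blocks.
#'
#' @param config a configuration list
#' @return the corresponding S4 object
#' @name configAccessors
#' @export
configDetector <- function(config) {
  d <- config$detector
  detectorSpec(d$n_fast, d$n_slow, d$pixel_size, d$distance,
               d$beam_center_fast, d$beam_center_slow)
}

#' @rdname configAccessors
#' @export
configFlow <- function(config) {
  f <- config$flow
  capillaryFlow(f$inner_diameter, f$flow_rate, f$viscosity, f$density)
}

#' @rdname configAccessors
#' @export
configCell <- function(config) {
  tetragonalCell(config$crystal$cell_a, config$crystal$cell_c)
}

#' @rdname configAccessors
#' @export
configSymmetry <- function(config) {
  if (!identical(config$crystal$space_group, "P43212"))
    stop("only space group P43212 is built in")
  symmetryP43212()
}

#' Read a configuration file
#'
#' YAML (or JSON, a YAML subset) with the same nesting as
#' [defaultConfig()]; missing fields take their defaults, unknown fields
#' are rejected.
#'
#' @param path file path
#' @return validated configuration list
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultConfig()
  for (blk in names(user)) {
    if (blk == "seed") { cfg$seed <- user$seed; next }
    if (!blk %in% names(cfg))
      stop(errorCondition(sprintf("unknown config block '%s'", blk),
                          class = c("ssxConfigError", "error")))
    unknown <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
    if (length(unknown))
      stop(errorCondition(
        sprintf("unknown field(s) in '%s': %s", blk,
                paste(unknown, collapse = ", ")),
        class = c("ssxConfigError", "error")))
    cfg[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  validateConfig(cfg)
  cfg
}

#' Write a configuration file
#' @param config configuration list
#' @param path output path
#' @return path, invisibly
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Experiment plan report
#'
#' Derived beamline/microfluidics quantities for a configuration: the
#' wavelength, flow profile, transit-time range, Reynolds number, dose at
#' the transit-time bounds, detector-edge resolution, unit cells per
#' crystal and the acquisition budget.
#'
#' @param config configuration list
#' @param nFrames frame count for the budget arithmetic
#' @return data.frame with columns quantity, value, units
#' @export
planExperiment <- function(config, nFrames = 1.5e6) {
  beam <- configBeam(config); det <- configDetector(config)
  flow <- configFlow(config); cell <- configCell(config)
  fp <- flowProfile(flow)
  tmin <- transitTime(beam, fp$centerlineVelocity)
  ## slowest crystals considered: 10 um from the wall
  vSlow <- poiseuilleVelocity(flow, flow@innerDiameter / 2 - 10)
  tmax <- transitTime(beam, vSlow)
  bud <- acquisitionBudget(config$acquisition$frame_rate,
                           config$acquisition$exposure_time, nFrames, flow)
  rows <- list(
    c("wavelength", energyToWavelength(beam@photonEnergy), "Angstrom"),
    c("mean flow velocity", fp$meanVelocity, "mm/s"),
    c("centerline velocity", fp$centerlineVelocity, "mm/s"),
    c("Reynolds number", fp$reynolds, ""),
    c("transit time (centerline)", tmin, "ms"),
    c("transit time (10 um from wall)", tmax, "ms"),
    c("dose at centerline transit", estimateDose(beam, tmin / 1e3)$dose, "MGy"),
    c("dose at full exposure",
      estimateDose(beam, config$acquisition$exposure_time)$dose, "MGy"),
    c("edge resolution", edgeResolution(det, beam), "Angstrom"),
    c("unit cells per crystal",
      unitCellCount(config$crystal$volume, cell), ""),
    c("total time", bud$totalHours, "h"),
    c("dead-time fraction", bud$deadTimeFraction, ""),
    c("consumed volume", bud$consumedVolume / 1e3, "ml"))
  data.frame(quantity = vapply(rows, `[`, "", 1),
             value = as.numeric(vapply(rows, `[`, "", 2)),
             units = vapply(rows, `[`, "", 3))
}
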