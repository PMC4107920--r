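## Plain-text persistence: frame stacks as a directory of TSV matrices
## with a JSON geometry descriptor and TSV truth sidecars; peak lists,
## measurement streams and merged hkl tables as TSV.

#' Write a frame stack to a directory
#'
#' Layout: `geometry.json` (detector + beam), `frame_00001.tsv` ... (one
#' integer matrix per frame), `truth_events.tsv` and
#' `truth_reflections.tsv` when ground truth is present. All files are
#' plain text.
#'
#' @param stack a [FrameStack-class]
#' @param dir output directory (created)
#' @return dir, invisibly
#' @export
writeFrameStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- stack@detector; beam <- stack@beam
  geom <- list(
    detector = list(n_fast = det@nFast, n_slow = det@nSlow,
                    pixel_size = det@pixelSize, distance = det@distance,
                    beam_center_fast = det@beamCenterFast,
                    beam_center_slow = det@beamCenterSlow),
    beam = list(photon_energy = beam@photonEnergy, flux = beam@flux,
                focus_h = beam@focusH, focus_v = beam@focusV,
                bandwidth = beam@bandwidth, divergence = beam@divergence),
    n_frames = length(stack@images),
    conventions = paste("pixels 0-based; image[slow+1, fast+1];",
                        "positions mm from beam center"))
  writeLines(jsonlite::toJSON(geom, auto_unbox = TRUE, digits = NA),
             file.path(dir, "geometry.json"))
  for (i in seq_along(stack@images))
    data.table::fwrite(data.table::as.data.table(stack@images[[i]]),
                       file.path(dir, sprintf("frame_%05d.tsv", i)),
                       sep = "\t", col.names = FALSE)
  if (nrow(stack@truthEvents))
    data.table::fwrite(stack@truthEvents,
                       file.path(dir, "truth_events.tsv"), sep = "\t")
  if (nrow(stack@truthReflections))
    data.table::fwrite(stack@truthReflections,
                       file.path(dir, "truth_reflections.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a frame stack written by [writeFrameStack()]
#'
#' @param dir directory path
#' @return a [FrameStack-class]
#' @export
readFrameStack <- function(dir) {
  geom <- jsonlite::read_json(file.path(dir, "geometry.json"),
                              simplifyVector = TRUE)
  d <- geom$detector
  det <- detectorSpec(d$n_fast, d$n_slow, d$pixel_size, d$distance,
                      d$beam_center_fast, d$beam_center_slow)
  b <- geom$beam
  beam <- beamSpec(b$photon_energy, b$flux, b$focus_h, b$focus_v,
                   b$bandwidth, b$divergence)
  images <- lapply(seq_len(geom$n_frames), function(i) {
    m <- as.matrix(data.table::fread(
      file.path(dir, sprintf("frame_%05d.tsv", i)), header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  })
  readTsv <- function(f)
    if (file.exists(f)) as.data.frame(data.table::fread(f))
    else data.frame()
  new("FrameStack", images = images, detector = det, beam = beam,
      truthEvents = readTsv(file.path(dir, "truth_events.tsv")),
      truthReflections = readTsv(file.path(dir, "truth_reflections.tsv")))
}

#' Write a merged reflection table
#'
#' Tab-separated columns h k l d I sigma n with a header line.
#'
#' @param merged a [MergedDataset-class]
#' @param path output path
#' @return path, invisibly
#' @export
writeHklTable <- function(merged, path) {
  data.table::fwrite(reflections(merged)[, c("h", "k", "l", "d", "I",
                                             "sigma", "n")],
                     path, sep = "\t")
  invisible(path)
}

#' Read a merged reflection table
#' @param path file path
#' @return data.frame
#' @export
readHklTable <- function(path) as.data.frame(data.table::fread(path))

#' Write a measurement stream
#' @param measurements measurement data.frame
#' @param path output path
#' @return path, invisibly
#' @export
writeMeasurements <- function(measurements, path) {
  data.table::fwrite(measurements, path, sep = "\t")
  invisible(path)
}

#' Read a measurement stream
#' @param path file path
#' @return data.frame
#' @export
readMeasurements <- function(path) as.data.frame(data.table::fread(path))
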