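## Accessor generics and show methods.

#' Wavelength of a beam
#' @param object a [BeamSpec-class]
#' @return wavelength in Angstrom
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname wavelength
#' @export
setMethod("wavelength", "BeamSpec", function(object)
  energyToWavelength(object@photonEnergy))

#' Cell volume
#' @param object a [UnitCell-class]
#' @return volume in Angstrom^3
#' @export
setGeneric("cellVolume", function(object) standardGeneric("cellVolume"))

#' @rdname cellVolume
#' @export
setMethod("cellVolume", "UnitCell", function(object) {
  ca <- cos(object@alpha * pi / 180)
  cb <- cos(object@beta * pi / 180)
  cg <- cos(object@gamma * pi / 180)
  object@a * object@b * object@c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
})

#' Cell parameters as a named vector
#' @param object a [UnitCell-class]
#' @return named numeric vector (a, b, c, alpha, beta, gamma)
#' @export
setGeneric("cellParameters", function(object)
  standardGeneric("cellParameters"))

#' @rdname cellParameters
#' @export
setMethod("cellParameters", "UnitCell", function(object)
  c(a = object@a, b = object@b, c = object@c, alpha = object@alpha,
    beta = object@beta, gamma = object@gamma))

#' Number of frames in a stack
#' @param object a [FrameStack-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameStack", function(object) length(object@images))

#' Extract one image from a stack
#' @param object a [FrameStack-class]
#' @param i frame index (1-based)
#' @return integer matrix (`nSlow x nFast`)
#' @export
setGeneric("frameImage", function(object, i) standardGeneric("frameImage"))

#' @rdname frameImage
#' @export
setMethod("frameImage", "FrameStack", function(object, i)
  object@images[[i]])

#' Reflection table of a container
#'
#' For a [StructureFactorSet-class] the sampled true amplitudes; for a
#' [MergedDataset-class] the merged unique intensities.
#' @param object the container
#' @return data.frame
#' @export
setGeneric("reflections", function(object) standardGeneric("reflections"))

#' @rdname reflections
#' @export
setMethod("reflections", "StructureFactorSet", function(object)
  object@reflections)

#' @rdname reflections
#' @export
setMethod("reflections", "MergedDataset", function(object)
  object@reflections)

#' Orientation matrix accessor
#' @param object a [CrystalOrientation-class]
#' @return 3x3 rotation matrix
#' @export
setGeneric("orientationMatrix", function(object)
  standardGeneric("orientationMatrix"))

#' @rdname orientationMatrix
#' @export
setMethod("orientationMatrix", "CrystalOrientation", function(object)
  object@rotation)

#' Refined cell accessor
#' @param object a [CrystalOrientation-class]
#' @return a [UnitCell-class]
#' @export
setGeneric("refinedCell", function(object) standardGeneric("refinedCell"))

#' @rdname refinedCell
#' @export
setMethod("refinedCell", "CrystalOrientation", function(object) object@cell)

#' Shell statistics accessor
#' @param object a [QualityReport-class]
#' @return data.frame of per-shell statistics
#' @export
setGeneric("shellTable", function(object) standardGeneric("shellTable"))

#' @rdname shellTable
#' @export
setMethod("shellTable", "QualityReport", function(object) object@shells)

setMethod("show", "BeamSpec", function(object) {
  cat(sprintf("BeamSpec: %.0f eV (%.4f A), %.3g ph/s, %g x %g um, dE/E %.2g, div %.2g rad\n",
              object@photonEnergy, wavelength(object), object@flux,
              object@focusH, object@focusV, object@bandwidth,
              object@divergence))
})

setMethod("show", "DetectorSpec", function(object) {
  cat(sprintf("DetectorSpec: %d x %d px of %.3f mm at %.1f mm, beam center (%.1f, %.1f)\n",
              object@nFast, object@nSlow, object@pixelSize, object@distance,
              object@beamCenterFast, object@beamCenterSlow))
})

setMethod("show", "UnitCell", function(object) {
  p <- cellParameters(object)
  cat(sprintf("UnitCell: a=%.3f b=%.3f c=%.3f A, %.1f/%.1f/%.1f deg (V=%.0f A^3)\n",
              p["a"], p["b"], p["c"], p["alpha"], p["beta"], p["gamma"],
              cellVolume(object)))
})

setMethod("show", "SymmetryInfo", function(object) {
  cat(sprintf("SymmetryInfo: %s (point group %s, Laue %s), %d point ops, %d Laue ops\n",
              object@spaceGroup, object@pointGroup, object@laueGroup,
              length(object@pointOps), length(object@laueOps)))
})

setMethod("show", "StructureFactorSet", function(object) {
  cat(sprintf("StructureFactorSet: %d ASU reflections to %.2f A, Wilson B %.1f A^2\n",
              nrow(object@reflections), object@dMin, object@wilsonB))
})

setMethod("show", "FrameStack", function(object) {
  cat(sprintf("FrameStack: %d frames of %d x %d px%s\n",
              length(object@images), object@detector@nSlow,
              object@detector@nFast,
              if (nrow(object@truthReflections)) " (with ground truth)"
              else ""))
})

setMethod("show", "CrystalOrientation", function(object) {
  cat(sprintf("CrystalOrientation: %d/%d peaks indexed, rms %.2g 1/A, cell a=%.3f c=%.3f A\n",
              object@nIndexed, object@nPeaks, object@rmsResidual,
              object@cell@a, object@cell@c))
})

setMethod("show", "MergedDataset", function(object) {
  cat(sprintf("MergedDataset: %d unique reflections from %d patterns, mean redundancy %.1f\n",
              nrow(object@reflections), object@nPatterns,
              mean(object@reflections$n)))
})

setMethod("show", "QualityReport", function(object) {
  cat(reportQuality(object), sep = "\n")
})
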