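## Spot prediction for indexed frames and disc/annulus integration of
## background-subtracted intensities at the predicted locations --
## including reflections with no detected peak.

#' Predict integration positions for an indexed frame
#'
#' All reflections within the excitation-error acceptance window
#' (bandwidth + divergence + mosaicity) out to `dMin`, at the frame's
#' refined orientation and cell, with systematic absences excluded.
#' Off-panel predictions are flagged, not dropped.
#'
#' @param orientation a [CrystalOrientation-class]
#' @param sym a [SymmetryInfo-class]
#' @param beam a [BeamSpec-class]
#' @param det a [DetectorSpec-class]
#' @param dMin resolution limit, Angstrom; default the detector corner
#' @param mosaicity effective mosaicity, degrees
#' @param nSigma acceptance half-window in rocking widths
#' @return data.frame as [predictReflectionsStill()]
#' @export
predictSpots <- function(orientation, sym, beam, det, dMin = NULL,
                         mosaicity = 0.05, nSigma = 3) {
  if (is.null(dMin)) dMin <- cornerResolution(det, beam)
  predictReflectionsStill(orientation@cell, sym, orientation@rotation,
                          beam, det, mosaicity = mosaicity, dMin = dMin,
                          nSigma = nSigma)
}

#' Integrate one predicted spot
#'
#' Disc/annulus estimator at the nearest integer pixel to the predicted
#' center: I = (disc sum) - n_disc x (annulus per-pixel background);
#' sigma by Poisson propagation sqrt(disc sum + n_disc^2 var(annulus) /
#' n_annulus). Pixel membership is by center-of-pixel distance (a disc of
#' radius 2 contains 13 pixels). Negative intensities are retained. The
#' measurement is flagged invalid when the disc leaves the panel or less
#' than half of the annulus is usable.
#'
#' @param image photon-count matrix (NA = masked)
#' @param fast,slow predicted center, fractional 0-based pixels
#' @param rDisc disc radius, px
#' @param rBgIn,rBgOut annulus radii, px
#' @param bgStat `"median"` (robust to neighbor spots) or `"mean"`
#' @return list with `I`, `sigma`, `discSum`, `background` (per pixel),
#'   `valid`
#' @export
integrateSpot <- function(image, fast, slow, rDisc = 2, rBgIn = 4,
                          rBgOut = 8, bgStat = c("median", "mean")) {
  bgStat <- match.arg(bgStat)
  sc <- round(slow) + 1L; fc <- round(fast) + 1L
  disc <- .discOffsets(rDisc); ann <- .annulusOffsets(rBgIn, rBgOut)
  ns <- nrow(image); nf <- ncol(image)
  ds <- sc + disc[, "ds"]; df <- fc + disc[, "df"]
  if (any(ds < 1L | ds > ns | df < 1L | df > nf))
    return(list(I = NA_real_, sigma = NA_real_, discSum = NA_real_,
                background = NA_real_, valid = FALSE))
  dvals <- image[cbind(ds, df)]
  as <- sc + ann[, "ds"]; af <- fc + ann[, "df"]
  inside <- as >= 1L & as <= ns & af >= 1L & af <= nf
  avals <- rep(NA_real_, nrow(ann))
  avals[inside] <- image[cbind(as[inside], af[inside])]
  usable <- sum(!is.na(avals))
  if (anyNA(dvals) || usable < nrow(ann) / 2)
    return(list(I = NA_real_, sigma = NA_real_, discSum = NA_real_,
                background = NA_real_, valid = FALSE))
  avals <- avals[!is.na(avals)]
  bg <- if (bgStat == "median") median(avals) else mean(avals)
  nd <- nrow(disc)
  discSum <- sum(dvals)
  I <- discSum - nd * bg
  sigma <- sqrt(max(discSum, 0) + nd^2 * var(avals) / length(avals))
  list(I = I, sigma = sigma, discSum = discSum, background = bg,
       valid = TRUE)
}

#' Integrate all predicted spots of a frame
#'
#' One measurement per on-panel predicted spot whose disc is fully on the
#' panel; indices are reported both as indexed and mapped to the ASU.
#'
#' @param image photon-count matrix
#' @param orientation a [CrystalOrientation-class]
#' @param sym a [SymmetryInfo-class]
#' @param beam a [BeamSpec-class]
#' @param det a [DetectorSpec-class]
#' @param config pipeline configuration (integration block)
#' @param dMin resolution limit; default detector corner
#' @return data.frame: h, k, l (ASU), d, I, sigma, fast, slow; attribute
#'   `nOffPanel` counts predictions excluded for geometry
#' @export
integrateFrame <- function(image, orientation, sym, beam, det, config,
                           dMin = NULL) {
  intc <- config$integration
  pred <- predictSpots(orientation, sym, beam, det, dMin = dMin,
                       mosaicity = intc$mosaicity, nSigma = intc$n_sigma)
  off <- sum(!pred$onPanel)
  pred <- pred[pred$onPanel, , drop = FALSE]
  n <- nrow(pred)
  I <- sigma <- rep(NA_real_, n)
  ok <- logical(n)
  for (j in seq_len(n)) {
    m <- integrateSpot(image, pred$fast[j], pred$slow[j], intc$r_disc,
                       intc$r_bg_in, intc$r_bg_out, intc$bg_stat)
    ok[j] <- m$valid
    I[j] <- m$I; sigma[j] <- m$sigma
  }
  asu <- mapToASU(sym, as.matrix(pred[, c("h", "k", "l")]))
  out <- data.frame(h = asu[, 1], k = asu[, 2], l = asu[, 3],
                    d = pred$d, I = I, sigma = sigma,
                    fast = pred$fast, slow = pred$slow)[ok, , drop = FALSE]
  attr(out, "nOffPanel") <- off
  out
}
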