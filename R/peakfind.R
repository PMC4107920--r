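## Bragg-peak detection: gradient search from candidate pixels to local
## maxima, region growing above the local background, and hit / multi-hit
## frame classification.

## pixel-offset discs by center-of-pixel distance, cached
.discOffsets <- function(r) {
  key <- sprintf("disc_%g", r)
  if (!is.null(.ssxCache[[key]])) return(.ssxCache[[key]])
  w <- ceiling(r)
  o <- expand.grid(df = -w:w, ds = -w:w)
  o <- as.matrix(o[o$df^2 + o$ds^2 <= r^2, ])
  .ssxCache[[key]] <- o
  o
}

.annulusOffsets <- function(rIn, rOut) {
  key <- sprintf("ann_%g_%g", rIn, rOut)
  if (!is.null(.ssxCache[[key]])) return(.ssxCache[[key]])
  w <- ceiling(rOut)
  o <- expand.grid(df = -w:w, ds = -w:w)
  d2 <- o$df^2 + o$ds^2
  o <- as.matrix(o[d2 >= rIn^2 & d2 <= rOut^2, ])
  .ssxCache[[key]] <- o
  o
}

#' Find Bragg peaks in a frame
#'
#' Gradient-search peak finder: candidate pixels at or above the count
#' threshold are walked uphill to their local maximum; from each distinct
#' maximum a connected region is grown while counts exceed the local
#' background (median of a surrounding square ring) plus `kSigma` Poisson
#' standard deviations; the centroid is the background-subtracted
#' count-weighted mean over the region. The threshold applies to the
#' background-subtracted maximum count. Peaks touching masked (NA)
#' pixels are dropped.
#'
#' @param image photon-count matrix (`nSlow x nFast`); NA marks masked
#'   pixels
#' @param threshold minimum background-subtracted maximum count
#' @param kSigma region-growing cut in background standard deviations
#' @param maxRadius maximum region radius, px (Chebyshev)
#' @param bgHalfWidth half-width of the square background ring, px
#' @return data.frame with one row per peak: fast, slow (fractional
#'   0-based centroid), intensity (background-subtracted region sum),
#'   maxCount (background-subtracted maximum), npix
#' @export
findPeaks <- function(image, threshold = 25, kSigma = 2, maxRadius = 4,
                      bgHalfWidth = 7) {
  ns <- nrow(image); nf <- ncol(image)
  cand <- which(!is.na(image) & image >= threshold)
  if (!length(cand))
    return(data.frame(fast = numeric(), slow = numeric(),
                      intensity = numeric(), maxCount = numeric(),
                      npix = integer()))
  cand <- cand[order(image[cand], decreasing = TRUE)]
  visited <- matrix(FALSE, ns, nf)
  peaks <- list()
  for (idx in cand) {
    s <- (idx - 1L) %% ns + 1L
    f <- (idx - 1L) %/% ns + 1L
    if (visited[s, f]) next
    ## steepest ascent to the local maximum
    repeat {
      ss <- max(1L, s - 1L):min(ns, s + 1L)
      ff <- max(1L, f - 1L):min(nf, f + 1L)
      nb <- image[ss, ff, drop = FALSE]
      if (anyNA(nb)) { s <- NA_integer_; break }
      m <- arrayInd(which.max(nb), dim(nb))
      s2 <- ss[m[1]]; f2 <- ff[m[2]]
      if (image[s2, f2] <= image[s, f] || (s2 == s && f2 == f)) break
      s <- s2; f <- f2
    }
    if (is.na(s) || visited[s, f]) next
    ## local background from the square ring border
    ring <- .ringValues(image, s, f, bgHalfWidth)
    if (length(ring) < 8 || mean(is.na(ring)) > 0.5) next
    bg <- median(ring, na.rm = TRUE)
    sigBg <- sqrt(max(bg, 0.25))
    if (image[s, f] - bg < threshold) { visited[s, f] <- TRUE; next }
    ## region growing (BFS within Chebyshev radius maxRadius)
    cut <- bg + kSigma * sigBg
    region <- .growRegion(image, s, f, cut, maxRadius)
    if (anyNA(image[region])) next
    visited[region] <- TRUE
    rs <- (region - 1L) %% ns + 1L
    rf <- (region - 1L) %/% ns + 1L
    wgt <- pmax(image[region] - bg, 0)
    if (sum(wgt) <= 0) next
    peaks[[length(peaks) + 1L]] <- data.frame(
      fast = sum((rf - 1L) * wgt) / sum(wgt),
      slow = sum((rs - 1L) * wgt) / sum(wgt),
      intensity = sum(image[region] - bg),
      maxCount = image[s, f] - bg,
      npix = length(region))
  }
  if (!length(peaks))
    return(data.frame(fast = numeric(), slow = numeric(),
                      intensity = numeric(), maxCount = numeric(),
                      npix = integer()))
  do.call(rbind, peaks)
}

.ringValues <- function(image, s, f, hw) {
  ns <- nrow(image); nf <- ncol(image)
  ss <- max(1L, s - hw):min(ns, s + hw)
  ff <- max(1L, f - hw):min(nf, f + hw)
  box <- image[ss, ff, drop = FALSE]
  inner <- abs(ss - s)[row(box)] < hw & abs(ff - f)[col(box)] < hw
  box[!inner]
}

.growRegion <- function(image, s0, f0, cut, maxRadius) {
  ns <- nrow(image)
  queue <- list(c(s0, f0))
  seen <- new.env(hash = TRUE)
  assign(as.character((f0 - 1L) * ns + s0), TRUE, envir = seen)
  out <- integer()
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    out <- c(out, (p[2] - 1L) * ns + p[1])
    for (ds in -1:1) for (df in -1:1) {
      s <- p[1] + ds; f <- p[2] + df
      if (s < 1L || s > ns || f < 1L || f > ncol(image)) next
      if (abs(s - s0) > maxRadius || abs(f - f0) > maxRadius) next
      key <- as.character((f - 1L) * ns + s)
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      v <- image[s, f]
      if (!is.na(v) && v > cut) queue[[length(queue) + 1L]] <- c(s, f)
    }
  }
  out
}

#' Classify a frame from its peak count
#'
#' Strict bounds: `blank` for n <= minPeaks, `hit` for
#' minPeaks < n < maxPeaks (a strong, likely single-crystal pattern),
#' `multi` for n >= maxPeaks (likely multiple-crystal).
#'
#' @param peaks data.frame from [findPeaks()], or a peak count
#' @param minPeaks strong-pattern lower bound (exclusive)
#' @param maxPeaks multi-hit upper bound (exclusive)
#' @return list with `nPeaks` and `label`
#' @export
classifyFrame <- function(peaks, minPeaks = 15, maxPeaks = 200) {
  n <- if (is.data.frame(peaks)) nrow(peaks) else as.integer(peaks)
  label <- if (n <= minPeaks) "blank"
  else if (n < maxPeaks) "hit"
  else "multi"
  list(nPeaks = n, label = label)
}
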