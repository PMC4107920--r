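## Monte Carlo merging and half-set data-quality statistics.

#' Monte Carlo merge of snapshot measurements
#'
#' Unweighted average of all measurements of each unique (ASU)
#' reflection, with no per-frame scaling: stochastic crystal-to-crystal
#' factors (size, transit time, partiality) are averaged out by
#' redundancy. sigma is the standard error of the mean from the scatter
#' of the measurements; single-measurement reflections carry sigma NA.
#'
#' @param measurements data.frame with columns frame, h, k, l (ASU
#'   indices), d, I
#' @param cell a [UnitCell-class]
#' @param sym a [SymmetryInfo-class]
#' @return a [MergedDataset-class]
#' @export
monteCarloMerge <- function(measurements, cell, sym) {
  stopifnot(nrow(measurements) >= 1)
  dt <- data.table::as.data.table(measurements)
  merged <- dt[, list(I = mean(I), sdI = sd(I), n = .N), by = c("h", "k", "l")]
  merged[, "sigma" := ifelse(merged$n >= 2, merged$sdI / sqrt(merged$n),
                             NA_real_)]
  out <- as.data.frame(merged[, c("h", "k", "l", "I", "sigma", "n")])
  out$d <- dSpacing(cell, as.matrix(out[, c("h", "k", "l")]))
  nPat <- length(unique(measurements$frame))
  new("MergedDataset", reflections = out[order(-out$d), ],
      cell = cell, sym = sym, nPatterns = as.integer(nPat))
}

#' Random half-split of a measurement stream
#'
#' Frames (patterns), not individual measurements, are assigned at random
#' to the two halves, so all measurements of one pattern stay together;
#' half sizes differ by at most one frame.
#'
#' @param measurements measurement data.frame (column frame)
#' @param seed RNG seed
#' @return list of two measurement data.frames
#' @export
splitHalf <- function(measurements, seed = 1L) {
  frames <- unique(measurements$frame)
  set.seed(seed)
  perm <- sample(frames)
  h1 <- perm[seq_len(ceiling(length(perm) / 2))]
  list(measurements[measurements$frame %in% h1, , drop = FALSE],
       measurements[!measurements$frame %in% h1, , drop = FALSE])
}

## inner join of two merged reflection tables on hkl
.commonReflections <- function(m1, m2) {
  r1 <- reflections(m1); r2 <- reflections(m2)
  key1 <- .hklKey(as.matrix(r1[, c("h", "k", "l")]))
  key2 <- .hklKey(as.matrix(r2[, c("h", "k", "l")]))
  i <- match(key1, key2)
  sel <- !is.na(i)
  data.frame(h = r1$h[sel], k = r1$k[sel], l = r1$l[sel], d = r1$d[sel],
             I1 = r1$I[sel], I2 = r2$I[i[sel]])
}

#' Half-set R factor
#'
#' R_split = 2^(-1/2) * sum |I1 - I2| / (0.5 * sum (I1 + I2)) over the
#' reflections common to the two half-dataset merges; the 1/sqrt(2)
#' factor extrapolates the half-set disagreement to the full set.
#'
#' @param m1,m2 two [MergedDataset-class] halves
#' @return R_split in percent
#' @export
rSplit <- function(m1, m2) {
  cm <- .commonReflections(m1, m2)
  if (nrow(cm) < 2) return(NA_real_)
  100 / sqrt(2) * sum(abs(cm$I1 - cm$I2)) / (0.5 * sum(cm$I1 + cm$I2))
}

#' Half-set correlation CC1/2 and CC*
#'
#' Pearson correlation of the two half-dataset intensities, and its
#' transform CC* = sqrt(2 CC / (1 + CC)) estimating the correlation of
#' the full dataset to the converged truth. CC* is undefined (NA) for
#' CC <= -1/3.
#'
#' @param m1,m2 two [MergedDataset-class] halves
#' @return list with `ccHalf`, `ccStar`, `n`
#' @export
ccHalfStar <- function(m1, m2) {
  cm <- .commonReflections(m1, m2)
  if (nrow(cm) < 3)
    return(list(ccHalf = NA_real_, ccStar = NA_real_, n = nrow(cm)))
  cc <- cor(cm$I1, cm$I2)
  list(ccHalf = cc, ccStar = ccStar(cc), n = nrow(cm))
}

#' CC* transform
#'
#' CC* = sqrt(2 CC / (1 + CC)) for non-negative half-set correlations;
#' for CC in (-1/3, 0) the signed extension
#' -sqrt(-2 CC / (1 + CC)) is used so the transform stays monotone with
#' fixed points 0 and 1 (a negative CC* flags an inconsistent shell).
#' Undefined (NA) at or below -1/3.
#'
#' @param ccHalf half-set Pearson correlation
#' @return CC* (NA where ccHalf <= -1/3)
#' @export
ccStar <- function(ccHalf) {
  out <- rep(NA_real_, length(ccHalf))
  ok <- !is.na(ccHalf) & ccHalf > -1 / 3
  x <- 2 * ccHalf[ok] / (1 + ccHalf[ok])
  out[ok] <- sign(x) * sqrt(abs(x))
  out
}

## equal-volume shell boundaries in q^3 between dMax and dMin
.shellEdges <- function(dMin, dMax, nShells) {
  q3 <- seq((1 / dMax)^3, (1 / dMin)^3, length.out = nShells + 1)
  1 / q3^(1 / 3)          # descending d edges
}

.shellIndex <- function(d, edges) {
  ## edges descending; shell i covers (edges[i+1], edges[i]]
  findInterval(-d, -edges, rightmost.closed = TRUE)
}

#' Per-shell data-quality statistics
#'
#' Ten (by default) equal-reciprocal-volume resolution shells with
#' unique-reflection count, completeness against the theoretical
#' non-absent ASU count, redundancy, mean I/sigma, R_split, CC1/2 and
#' CC*.
#'
#' @param measurements measurement stream (frame, h, k, l, d, I)
#' @param cell a [UnitCell-class]
#' @param sym a [SymmetryInfo-class]
#' @param dMin high-resolution cutoff, Angstrom
#' @param dMax low-resolution cutoff; default the largest observed d
#' @param nShells number of shells
#' @param seed seed for the half split
#' @return list with `shells` and `overall` data.frames
#' @export
shellStatistics <- function(measurements, cell, sym, dMin = NULL,
                            dMax = NULL, nShells = 10, seed = 1L) {
  measurements <- measurements[!is.na(measurements$I), , drop = FALSE]
  if (is.null(dMin)) dMin <- min(measurements$d)
  if (is.null(dMax)) dMax <- max(measurements$d)
  measurements <- measurements[measurements$d >= dMin &
                                 measurements$d <= dMax, , drop = FALSE]
  merged <- monteCarloMerge(measurements, cell, sym)
  halves <- splitHalf(measurements, seed)
  mh1 <- monteCarloMerge(halves[[1]], cell, sym)
  mh2 <- monteCarloMerge(halves[[2]], cell, sym)
  theo <- uniqueReflections(cell, sym, dMin, dMax)
  edges <- .shellEdges(dMin, dMax, nShells)
  mref <- reflections(merged)
  shellOf <- .shellIndex(mref$d, edges)
  theoShell <- .shellIndex(theo$d, edges)
  cm <- .commonReflections(mh1, mh2)
  cmShell <- .shellIndex(cm$d, edges)
  one <- function(sel, selTheo, selCm, dlo, dhi) {
    sub <- mref[sel, , drop = FALSE]
    nu <- nrow(sub)
    isig <- sub$I / sub$sigma
    cmS <- cm[selCm, , drop = FALSE]
    rs <- if (nrow(cmS) >= 2)
      100 / sqrt(2) * sum(abs(cmS$I1 - cmS$I2)) /
        (0.5 * sum(cmS$I1 + cmS$I2)) else NA_real_
    cc <- if (nrow(cmS) >= 3) cor(cmS$I1, cmS$I2) else NA_real_
    data.frame(dMax = dhi, dMin = dlo, nUnique = nu,
               completeness = 100 * nu / max(1L, sum(selTheo)),
               redundancy = if (nu) sum(sub$n) / nu else NA_real_,
               meanIsigma = mean(isig[is.finite(isig)]),
               rSplit = rs, ccHalf = cc, ccStar = ccStar(cc))
  }
  shells <- do.call(rbind, lapply(seq_len(nShells), function(i)
    one(shellOf == i, theoShell == i, cmShell == i,
        edges[i + 1], edges[i])))
  overall <- one(rep(TRUE, nrow(mref)), rep(TRUE, nrow(theo)),
                 rep(TRUE, nrow(cm)), dMin, dMax)
  list(shells = shells, overall = overall, merged = merged)
}

#' Wilson plot fit
#'
#' Straight-line fit of log shell-mean intensity against s^2/2 (s = 1/d)
#' over the configured resolution range; the negative slope is the
#' Wilson B factor. Shells with non-positive mean intensity are excluded
#' from the fit.
#'
#' @param merged a [MergedDataset-class]
#' @param fitRange c(dLow, dHigh) resolution range, Angstrom; default
#'   8 Angstrom to the data limit
#' @param nShells number of fit shells
#' @return list with `B` (Angstrom^2), `scale`, `nShellsUsed`, `shells`
#' @export
wilsonFit <- function(merged, fitRange = NULL, nShells = 15) {
  r <- reflections(merged)
  if (is.null(fitRange)) fitRange <- c(8, min(r$d))
  dLow <- max(fitRange); dHigh <- min(fitRange)
  r <- r[r$d <= dLow & r$d >= dHigh, , drop = FALSE]
  if (!nrow(r)) stop("no reflections in the Wilson fit range")
  edges <- .shellEdges(dHigh, dLow, nShells)
  idx <- .shellIndex(r$d, edges)
  s2h <- tapply(1 / r$d^2, idx, mean) / 2
  mI <- tapply(r$I, idx, mean)
  ok <- is.finite(mI) & mI > 0
  if (sum(ok) < 2) stop("fewer than two usable Wilson shells")
  fit <- lm(log(mI[ok]) ~ s2h[ok])
  list(B = -unname(coef(fit)[2]), scale = exp(unname(coef(fit)[1])),
       nShellsUsed = sum(ok),
       shells = data.frame(s2half = as.numeric(s2h), meanI = as.numeric(mI)))
}

#' Convergence of merging statistics with pattern count
#'
#' Draws random pattern subsets of increasing size and recomputes the
#' half-set metrics for each, reproducing the R_split and CC* versus
#' pattern-number behaviour of Monte Carlo merging (R_split shrinks like
#' 1/sqrt(n)).
#'
#' @param measurements measurement stream
#' @param nGrid vector of pattern counts
#' @param cell a [UnitCell-class]
#' @param sym a [SymmetryInfo-class]
#' @param seed RNG seed
#' @return data.frame: n, rSplit (%), ccHalf, ccStar, meanIsigma
#' @export
convergenceAnalysis <- function(measurements, nGrid, cell, sym, seed = 1L) {
  frames <- unique(measurements$frame)
  nGrid <- nGrid[nGrid <= length(frames)]
  set.seed(seed)
  out <- lapply(nGrid, function(n) {
    sub <- measurements[measurements$frame %in% sample(frames, n), ,
                        drop = FALSE]
    halves <- splitHalf(sub, seed = seed + n)
    m1 <- monteCarloMerge(halves[[1]], cell, sym)
    m2 <- monteCarloMerge(halves[[2]], cell, sym)
    cc <- ccHalfStar(m1, m2)
    merged <- monteCarloMerge(sub, cell, sym)
    isig <- reflections(merged)$I / reflections(merged)$sigma
    data.frame(n = n, rSplit = rSplit(m1, m2), ccHalf = cc$ccHalf,
               ccStar = cc$ccStar,
               meanIsigma = mean(isig[is.finite(isig)]))
  })
  do.call(rbind, out)
}

#' Assemble a quality report
#'
#' @param measurements measurement stream
#' @param cell a [UnitCell-class]
#' @param sym a [SymmetryInfo-class]
#' @param dMin,dMax resolution range (defaults: observed)
#' @param nShells number of shells
#' @param seed half-split seed
#' @return a [QualityReport-class]
#' @export
qualityReport <- function(measurements, cell, sym, dMin = NULL,
                          dMax = NULL, nShells = 10, seed = 1L) {
  st <- shellStatistics(measurements, cell, sym, dMin, dMax, nShells, seed)
  wb <- tryCatch(wilsonFit(st$merged)$B, error = function(e) NA_real_)
  new("QualityReport", shells = st$shells, overall = st$overall,
      wilsonB = wb, nPatterns = st$merged@nPatterns)
}

#' Format a quality report
#'
#' Table-style data-collection block with outer-shell values in
#' parentheses.
#'
#' @param quality a [QualityReport-class]
#' @return character vector of report lines
#' @export
reportQuality <- function(quality) {
  ov <- quality@overall
  outer <- quality@shells[nrow(quality@shells), ]
  fmt <- function(a, b, digits = 2)
    sprintf(paste0("%.", digits, "f (%.", digits, "f)"), a, b)
  c("Data statistics",
    sprintf("  Resolution range (A)   %.2f-%.2f", ov$dMax, ov$dMin),
    sprintf("  No. unique reflections %d", ov$nUnique),
    sprintf("  Completeness (%%)       %s", fmt(ov$completeness,
                                                outer$completeness, 1)),
    sprintf("  R_split (%%)            %s", fmt(ov$rSplit, outer$rSplit)),
    sprintf("  I/sigma(I)             %s", fmt(ov$meanIsigma,
                                               outer$meanIsigma, 1)),
    sprintf("  CC1/2                  %s", fmt(ov$ccHalf, outer$ccHalf, 4)),
    sprintf("  CC*                    %s", fmt(ov$ccStar, outer$ccStar, 4)),
    sprintf("  Redundancy             %s", fmt(ov$redundancy,
                                               outer$redundancy, 1)),
    sprintf("  Wilson B factor (A^2)  %.1f", quality@wilsonB),
    sprintf("  Patterns merged        %d", quality@nPatterns))
}
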