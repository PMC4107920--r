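## Known-cell still indexing: map detected peaks to scattering vectors on
## the Ewald sphere, search a quasi-uniform (symmetry-reduced) rotation
## grid for the orientation that places the most peaks on reciprocal-
## lattice nodes, then refine orientation (Kabsch) and cell (linear least
## squares under the tetragonal constraint).

#' Scattering vectors of detected peaks
#'
#' Exact Ewald-sphere mapping (full curvature, no small-angle
#' approximation) from fractional detector pixels to reciprocal space.
#'
#' @param peaks data.frame from [findPeaks()] (columns fast, slow)
#' @param det a [DetectorSpec-class]
#' @param beam a [BeamSpec-class]
#' @return n x 3 matrix of q vectors, 1/Angstrom
#' @export
peaksToScatteringVectors <- function(peaks, det, beam) {
  q <- .pixelToQ(peaks$fast, peaks$slow, det, wavelength(beam))
  colnames(q) <- c("qx", "qy", "qz")
  q
}

## Symmetry-reduced quasi-uniform orientation grid: super-Fibonacci
## quaternions pruned to one representative per point-group orbit (the
## image with the largest |w|, i.e. smallest rotation angle). Cached.
.orientationGrid <- function(stepDeg, sym) {
  key <- sprintf("origrid_%g_%s", stepDeg, sym@pointGroup)
  if (!is.null(.ssxCache[[key]])) return(.ssxCache[[key]])
  r <- stepDeg / 2 * pi / 180             # quaternion-space covering radius
  nFull <- ceiling(pi^2 / (4 / 3 * pi * r^3))
  qs <- .superFibonacci(nFull)
  symQ <- t(vapply(sym@pointOps, .matToQuat, numeric(4)))
  wmax <- abs(qs[, 1])
  keep <- rep(TRUE, nrow(qs))
  for (i in seq_len(nrow(symQ))[-1]) {
    w <- abs(.quatMulMat(qs, symQ[i, ])[, 1])
    keep <- keep & (wmax >= w - 1e-12)
  }
  qs <- qs[keep, , drop = FALSE]
  ## stack of A_i = Binv-independent part: rotation matrices, row-major
  n <- nrow(qs)
  w <- qs[, 1]; x <- qs[, 2]; y <- qs[, 3]; z <- qs[, 4]
  R <- array(0, c(n, 3, 3))
  R[, 1, 1] <- 1 - 2 * (y^2 + z^2); R[, 1, 2] <- 2 * (x * y - w * z)
  R[, 1, 3] <- 2 * (x * z + w * y); R[, 2, 1] <- 2 * (x * y + w * z)
  R[, 2, 2] <- 1 - 2 * (x^2 + z^2); R[, 2, 3] <- 2 * (y * z - w * x)
  R[, 3, 1] <- 2 * (x * z - w * y); R[, 3, 2] <- 2 * (y * z + w * x)
  R[, 3, 3] <- 1 - 2 * (x^2 + y^2)
  out <- list(quats = qs, rots = R)
  .ssxCache[[key]] <- out
  out
}

## fractional Miller indices of peaks for a block of orientations:
## returns |frac - round(frac)| summed in q units as an n_ori x n_peak
## score matrix (count of peaks within `tol`)
.gridScores <- function(rots, Binv, Bdiag, q, tol) {
  n <- dim(rots)[1]; npk <- nrow(q)
  ## Astack (3n x 3): rows of Binv %*% t(R_i)
  A <- matrix(0, 3 * n, 3)
  for (r in 1:3) for (cc in 1:3) {
    v <- numeric(n)
    for (m in 1:3) v <- v + Binv[r, m] * rots[, cc, m]
    A[seq(r, by = 3, length.out = n), cc] <- v
  }
  Fr <- A %*% t(q)                        # (3n) x npk fractional hkl
  Dev <- abs(Fr - round(Fr))
  ## q-space deviation per component, then Euclidean over components
  i1 <- seq(1, by = 3, length.out = n)
  d2 <- (Dev[i1, , drop = FALSE] * Bdiag[1])^2 +
    (Dev[i1 + 1, , drop = FALSE] * Bdiag[2])^2 +
    (Dev[i1 + 2, , drop = FALSE] * Bdiag[3])^2
  rowSums(d2 < tol^2)
}

## Kabsch: rotation minimizing sum |q_j - R v_j|^2 (v = B h)
.kabsch <- function(V, Q) {
  C <- crossprod(V, Q)                    # 3x3
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

## iterative orientation polish: assign nearest nodes, Kabsch re-fit
.polishOrientation <- function(R0, q, B, tolSeq) {
  Binv <- solve(B)
  R <- R0
  for (tol in tolSeq) {
    frac <- t(Binv %*% crossprod(R, t(q)))
    H <- round(frac)
    V <- H %*% t(B)
    pred <- V %*% t(R)
    dq <- sqrt(rowSums((q - pred)^2))
    sel <- dq < tol & rowSums(abs(H)) > 0
    if (sum(sel) < 3) return(NULL)
    R <- .kabsch(V[sel, , drop = FALSE], q[sel, , drop = FALSE])
  }
  frac <- t(Binv %*% crossprod(R, t(q)))
  H <- round(frac)
  dq <- sqrt(rowSums((q - H %*% t(B) %*% t(R))^2))
  list(R = R, H = H, dq = dq)
}

#' Index a still pattern against a known cell
#'
#' Coarse search over a symmetry-reduced quasi-uniform rotation grid
#' scoring the number of scattering vectors within tolerance of a
#' reciprocal-lattice node, followed by iterative local refinement
#' (nearest-node assignment + least-squares rotation). Success requires
#' at least `minFrac` of the peaks (and at least 6) to index; otherwise
#' `NULL` is returned -- indexing failure is an expected outcome, not an
#' error.
#'
#' @param q n x 3 scattering-vector matrix from
#'   [peaksToScatteringVectors()]
#' @param cell prior [UnitCell-class] (known cell, possibly slightly off)
#' @param sym a [SymmetryInfo-class]
#' @param gridStep coarse-grid angular step, degrees
#' @param tolFrac node-assignment tolerance as a fraction of the minimum
#'   reciprocal half-spacing
#' @param minFrac minimum indexed fraction of peaks for success
#' @param refineCellToo also refine the tetragonal cell lengths
#' @return a [CrystalOrientation-class], or NULL on failure
#' @export
indexKnownCell <- function(q, cell, sym, gridStep = 1.5, tolFrac = 0.8,
                           minFrac = 0.5, refineCellToo = TRUE) {
  npk <- nrow(q)
  if (is.null(npk) || npk < 3) return(NULL)
  B <- reciprocalMatrix(cell)
  Bdiag <- c(B[1, 1], B[2, 2], B[3, 3])
  spacing <- min(Bdiag)
  tolFinal <- tolFrac * spacing / 2
  grid <- .orientationGrid(gridStep, sym)
  Binv <- solve(B)
  ## coarse scoring in manageable blocks
  nOri <- dim(grid$rots)[1]
  tolCoarse <- 0.45 * spacing
  scores <- numeric(nOri)
  bs <- 40000L
  for (start in seq(1L, nOri, by = bs)) {
    idx <- start:min(start + bs - 1L, nOri)
    scores[idx] <- .gridScores(grid$rots[idx, , , drop = FALSE], Binv,
                               Bdiag, q, tolCoarse)
  }
  ord <- order(scores, decreasing = TRUE)
  cand <- ord[seq_len(min(30L, nOri))]
  best <- NULL
  for (ci in cand) {
    R0 <- matrix(grid$rots[ci, , ], 3, 3)
    pol <- .polishOrientation(R0, q, B,
                              tolSeq = c(0.45, 0.35, 0.25) * spacing)
    if (is.null(pol)) next
    nIdx <- sum(pol$dq < tolFinal)
    rms <- sqrt(mean(pol$dq[pol$dq < tolFinal]^2))
    if (is.null(best) || nIdx > best$nIdx ||
        (nIdx == best$nIdx && rms < best$rms)) {
      best <- list(R = pol$R, nIdx = nIdx, rms = rms)
    }
  }
  if (is.null(best) || best$nIdx < max(6, ceiling(minFrac * npk)))
    return(NULL)
  ori <- new("CrystalOrientation", rotation = best$R, cell = cell,
             nIndexed = as.integer(best$nIdx), nPeaks = as.integer(npk),
             rmsResidual = best$rms)
  if (refineCellToo) {
    rc <- refineCell(ori, q)
    ori <- rc$orientation
  }
  ## success: enough peaks on nodes AND residuals much tighter than the
  ## assignment tolerance after refinement (random non-lattice
  ## assignments concentrate near the tolerance radius, rms ~ 0.77 tol;
  ## genuine lattices sit far below)
  if (ori@nIndexed < max(6, ceiling(minFrac * npk)) ||
      !is.finite(ori@rmsResidual) || ori@rmsResidual > 0.5 * tolFinal)
    return(NULL)
  ori
}

#' Refine the unit cell for an indexed frame
#'
#' Linear least squares for the reciprocal cell under the tetragonal
#' constraint (a* = b*, c* free; `constraint = "none"` frees all three
#' axes), alternating with Kabsch re-refinement of the orientation.
#' Peaks are assigned to their nearest nodes at the current model.
#'
#' @param orientation a [CrystalOrientation-class]
#' @param q scattering-vector matrix of the frame's peaks
#' @param constraint `"tetragonal"` or `"none"`
#' @param nIter number of assignment/solve iterations
#' @return list with `orientation` (updated [CrystalOrientation-class]
#'   carrying the refined cell) and `cell`
#' @export
refineCell <- function(orientation, q, constraint = c("tetragonal", "none"),
                       nIter = 4) {
  constraint <- match.arg(constraint)
  cell <- orientation@cell
  R <- orientation@rotation
  spacing <- min(diag(reciprocalMatrix(cell)))
  tol <- 0.4 * spacing
  H <- NULL
  for (it in seq_len(nIter)) {
    B <- reciprocalMatrix(cell)
    frac <- t(solve(B) %*% crossprod(R, t(q)))
    H <- round(frac)
    pred <- H %*% t(B) %*% t(R)
    dq <- sqrt(rowSums((q - pred)^2))
    sel <- dq < tol & rowSums(abs(H)) > 0
    if (sum(sel) < 6) break
    Hs <- H[sel, , drop = FALSE]
    qc <- q[sel, , drop = FALSE] %*% R    # rotate into crystal frame: R^T q
    if (constraint == "tetragonal") {
      ## qc ~ astar * (h, k, 0) + cstar * (0, 0, l): two-parameter LS
      u <- cbind(Hs[, 1], Hs[, 2], 0)
      wv <- cbind(0, 0, Hs[, 3])
      uu <- sum(u * u); ww <- sum(wv * wv); uw <- sum(u * wv)
      bu <- sum(u * qc); bw <- sum(wv * qc)
      sol <- solve(matrix(c(uu, uw, uw, ww), 2), c(bu, bw))
      cell <- tetragonalCell(1 / sol[1], 1 / sol[2])
    } else {
      ast <- vapply(1:3, function(j) {
        num <- sum(Hs[, j] * qc[, j]); den <- sum(Hs[, j]^2)
        if (den > 0) num / den else 1 / cellParameters(cell)[j]
      }, numeric(1))
      cell <- unitCell(1 / ast[1], 1 / ast[2], 1 / ast[3])
    }
    ## re-refine orientation against the updated cell
    B <- reciprocalMatrix(cell)
    V <- Hs %*% t(B)
    R <- .kabsch(V, q[sel, , drop = FALSE])
  }
  B <- reciprocalMatrix(cell)
  frac <- t(solve(B) %*% crossprod(R, t(q)))
  H <- round(frac)
  pred <- H %*% t(B) %*% t(R)
  dq <- sqrt(rowSums((q - pred)^2))
  nIdx <- sum(dq < tol)
  ori <- new("CrystalOrientation", rotation = R, cell = cell,
             nIndexed = as.integer(nIdx),
             nPeaks = orientation@nPeaks,
             rmsResidual = sqrt(mean(dq[dq < tol]^2)))
  list(orientation = ori, cell = cell)
}
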