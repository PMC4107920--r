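## Reciprocal-space and detector geometry.
##
## Conventions (fixed project-wide):
##  - beam along +z; detector plane at z = distance (mm), fast axis -> +x,
##    slow axis -> +y; pixel indices 0-based, positions in mm from the
##    beam center
##  - scattering vectors q = k_out - k_in in 1/Angstrom, |k| = 1/lambda
##  - reciprocal basis B maps integer hkl to crystal-frame q; a crystal
##    orientation R maps crystal frame to laboratory frame: q = R B h

#' Reciprocal-basis matrix of a cell
#'
#' Busing-Levy style upper-triangular matrix B with q_crystal = B %*% h
#' in 1/Angstrom. For orthogonal cells this is
#' diag(1/a, 1/b, 1/c).
#'
#' @param cell a [UnitCell-class]
#' @return 3x3 matrix, 1/Angstrom
#' @export
reciprocalMatrix <- function(cell) {
  p <- cellParameters(cell)
  al <- p["alpha"] * pi / 180; be <- p["beta"] * pi / 180
  ga <- p["gamma"] * pi / 180
  V <- cellVolume(cell)
  astar <- p["b"] * p["c"] * sin(al) / V
  bstar <- p["a"] * p["c"] * sin(be) / V
  cstar <- p["a"] * p["b"] * sin(ga) / V
  # reciprocal angles
  cosalstar <- (cos(be) * cos(ga) - cos(al)) / (sin(be) * sin(ga))
  cosbestar <- (cos(al) * cos(ga) - cos(be)) / (sin(al) * sin(ga))
  cosgastar <- (cos(al) * cos(be) - cos(ga)) / (sin(al) * sin(be))
  singastar <- sqrt(max(0, 1 - cosgastar^2))
  B <- matrix(0, 3, 3)
  B[1, 1] <- astar
  B[1, 2] <- bstar * cosgastar
  B[1, 3] <- cstar * cosbestar
  B[2, 2] <- bstar * singastar
  B[2, 3] <- cstar * (cosalstar - cosbestar * cosgastar) / singastar
  B[3, 3] <- sqrt(max(0, cstar^2 - B[1, 3]^2 - B[2, 3]^2))
  unname(B)
}

#' d-spacing of reflections
#'
#' @param cell a [UnitCell-class]
#' @param hkl integer matrix (n x 3) or vector of length 3
#' @return d, Angstrom
#' @export
dSpacing <- function(cell, hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  B <- reciprocalMatrix(cell)
  q <- hkl %*% t(B)
  1 / sqrt(rowSums(q^2))
}

## --- quaternion helpers (w, x, y, z convention) -------------------------

.quatToMat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.matToQuat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

## Hamilton product, vectorized over rows of an n x 4 matrix `qa` with a
## single quaternion `qb`.
.quatMulMat <- function(qa, qb) {
  w1 <- qa[, 1]; x1 <- qa[, 2]; y1 <- qa[, 3]; z1 <- qa[, 4]
  w2 <- qb[1]; x2 <- qb[2]; y2 <- qb[3]; z2 <- qb[4]
  cbind(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
        w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
        w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
        w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' Uniform random rotations
#'
#' Quaternions drawn uniformly on SO(3) (Shoemake construction).
#'
#' @param n number of rotations
#' @return n x 4 matrix of unit quaternions (w, x, y, z)
#' @export
randomRotations <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  ## any fixed assignment of the four uniform S^3 coordinates to
  ## (w, x, y, z) preserves uniformity on SO(3)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}

#' Quaternion to rotation matrix
#' @param q unit quaternion (w, x, y, z)
#' @return 3x3 rotation matrix
#' @export
quaternionToMatrix <- function(q) .quatToMat(q / sqrt(sum(q^2)))

## Deterministic quasi-uniform quaternion set (super-Fibonacci spiral).
.superFibonacci <- function(n) {
  s <- (seq_len(n) - 0.5)
  t <- s / n
  d <- 2 * pi * s
  r <- sqrt(t); R <- sqrt(1 - t)
  alpha <- d / sqrt(2)
  beta <- d / 1.533751168755204
  cbind(r * sin(alpha), r * cos(alpha), R * sin(beta), R * cos(beta))
}

## rotation angle (deg) between two rotation matrices, minimized over the
## proper point-group operations of `sym` (orientation degeneracy)
.misorientation <- function(R1, R2, sym = NULL) {
  ops <- if (is.null(sym)) list(diag(3)) else sym@pointOps
  best <- 180
  for (S in ops) {
    M <- crossprod(R1, R2 %*% S)   # R1^T R2 S
    cosang <- (sum(diag(M)) - 1) / 2
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    best <- min(best, ang)
  }
  best
}

## --- detector <-> reciprocal space --------------------------------------

## pixel (fractional, 0-based) -> q (n x 3), 1/Angstrom
.pixelToQ <- function(fast, slow, det, wl) {
  x <- (fast - det@beamCenterFast) * det@pixelSize
  y <- (slow - det@beamCenterSlow) * det@pixelSize
  z <- det@distance
  nrm <- sqrt(x^2 + y^2 + z^2)
  cbind(x / nrm, y / nrm, z / nrm - 1) / wl
}

## q (n x 3) -> list(fast, slow, valid); projection along the diffracted
## beam direction k_out = q + k_in
.qToPixel <- function(q, det, wl) {
  kx <- q[, 1]; ky <- q[, 2]; kz <- q[, 3] + 1 / wl
  valid <- kz > 0
  x <- kx / kz * det@distance
  y <- ky / kz * det@distance
  fast <- x / det@pixelSize + det@beamCenterFast
  slow <- y / det@pixelSize + det@beamCenterSlow
  onPanel <- valid & fast >= 0 & fast <= det@nFast - 1 &
    slow >= 0 & slow <= det@nSlow - 1
  list(fast = fast, slow = slow, valid = valid, onPanel = onPanel)
}

## per-pixel |q| map (nSlow x nFast), cached
.pixelQMap <- function(det, wl) {
  key <- sprintf("qmap_%d_%d_%g_%g_%g_%g_%g", det@nFast, det@nSlow,
                 det@pixelSize, det@distance, det@beamCenterFast,
                 det@beamCenterSlow, wl)
  if (!is.null(.ssxCache[[key]])) return(.ssxCache[[key]])
  fast <- matrix(rep(0:(det@nFast - 1), each = det@nSlow),
                 det@nSlow, det@nFast)
  slow <- matrix(rep(0:(det@nSlow - 1), times = det@nFast),
                 det@nSlow, det@nFast)
  q <- .pixelToQ(as.vector(fast), as.vector(slow), det, wl)
  m <- matrix(sqrt(rowSums(q^2)), det@nSlow, det@nFast)
  .ssxCache[[key]] <- m
  m
}
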