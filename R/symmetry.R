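## Space-group machinery for P4(3)2(1)2: point group 422, Laue group
## 4/mmm, screw-axis systematic absences and reciprocal-space ASU mapping.

.rot422 <- function() {
  m <- function(...) matrix(c(...), 3, 3, byrow = TRUE)
  list(
    m(1, 0, 0, 0, 1, 0, 0, 0, 1),        # identity
    m(-1, 0, 0, 0, -1, 0, 0, 0, 1),      # 2-fold z
    m(0, -1, 0, 1, 0, 0, 0, 0, 1),       # 4+ z
    m(0, 1, 0, -1, 0, 0, 0, 0, 1),       # 4- z
    m(0, 1, 0, 1, 0, 0, 0, 0, -1),       # 2-fold [110]
    m(0, -1, 0, -1, 0, 0, 0, 0, -1),     # 2-fold [1-10]
    m(1, 0, 0, 0, -1, 0, 0, 0, -1),      # 2-fold x
    m(-1, 0, 0, 0, 1, 0, 0, 0, -1))      # 2-fold y
}

#' Symmetry information for space group P4(3)2(1)2
#'
#' Point group 422 (8 proper rotations), Laue group 4/mmm (16 operations
#' including Friedel inversion), systematic absences from the 4(3) screw
#' axis ((0,0,l) present only for l = 4n) and the 2(1) axes ((h,0,0) only
#' h even, (0,k,0) only k even).
#'
#' @return a [SymmetryInfo-class]
#' @examples
#' sym <- symmetryP43212()
#' isAbsent(sym, c(0, 0, 2))   # TRUE: 4(3) screw axis
#' @export
symmetryP43212 <- function() {
  rots <- .rot422()
  laue <- c(rots, lapply(rots, function(m) -m))
  new("SymmetryInfo", spaceGroup = "P43212", pointGroup = "422",
      laueGroup = "4/mmm", pointOps = rots, laueOps = laue)
}

#' Systematic-absence test
#'
#' @param sym a [SymmetryInfo-class]
#' @param hkl integer matrix (n x 3) or length-3 vector
#' @return logical vector, TRUE where the reflection is systematically
#'   absent
#' @export
isAbsent <- function(sym, hkl) {
  stopifnot(is(sym, "SymmetryInfo"))
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  h <- hkl[, 1]; k <- hkl[, 2]; l <- hkl[, 3]
  (h == 0 & k == 0 & l %% 4 != 0) |
    (k == 0 & l == 0 & h %% 2 != 0) |
    (h == 0 & l == 0 & k %% 2 != 0)
}

#' Map reflections to the reciprocal-space asymmetric unit
#'
#' Applies every Laue-group operation (Friedel mates included) and keeps
#' the lexicographically largest image (ordered by h, then k, then l).
#' Under 4/mmm the representatives satisfy h >= k >= 0, l >= 0. The map
#' is idempotent.
#'
#' @param sym a [SymmetryInfo-class]
#' @param hkl integer matrix (n x 3) or length-3 vector
#' @return integer matrix (n x 3) of ASU representatives
#' @export
mapToASU <- function(sym, hkl) {
  stopifnot(is(sym, "SymmetryInfo"))
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  storage.mode(hkl) <- "integer"
  best <- hkl %*% t(sym@laueOps[[1]])
  bestKey <- .hklKey(best)
  for (op in sym@laueOps[-1]) {
    cand <- hkl %*% t(op)
    key <- .hklKey(cand)
    takeover <- key > bestKey
    if (any(takeover)) {
      best[takeover, ] <- cand[takeover, , drop = FALSE]
      bestKey[takeover] <- key[takeover]
    }
  }
  colnames(best) <- c("h", "k", "l")
  best
}

## lexicographic ordering key; indices are bounded well below 5000
.hklKey <- function(hkl) {
  (hkl[, 1] * 1e4 + hkl[, 2]) * 1e4 + hkl[, 3]
}

#' Enumerate unique (ASU) reflections in a resolution range
#'
#' All non-absent asymmetric-unit reflections with dMin <= d <= dMax,
#' used as the completeness denominator and by the structure-factor
#' sampler. ASU convention as in [mapToASU()] (h >= k >= 0, l >= 0 for
#' 4/mmm).
#'
#' @param cell a [UnitCell-class]
#' @param sym a [SymmetryInfo-class]
#' @param dMin high-resolution limit, Angstrom
#' @param dMax low-resolution limit, Angstrom (default Inf)
#' @return data.frame with columns h, k, l, d
#' @export
uniqueReflections <- function(cell, sym, dMin, dMax = Inf) {
  stopifnot(dMin > 0)
  p <- cellParameters(cell)
  hmax <- floor(p["a"] / dMin); lmax <- floor(p["c"] / dMin)
  grid <- expand.grid(h = 0:hmax, k = 0:hmax, l = 0:lmax)
  grid <- grid[grid$k <= grid$h & !(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  hkl <- as.matrix(grid)
  d <- dSpacing(cell, hkl)
  keep <- d >= dMin & d <= dMax & !isAbsent(sym, hkl)
  out <- data.frame(h = as.integer(hkl[keep, 1]),
                    k = as.integer(hkl[keep, 2]),
                    l = as.integer(hkl[keep, 3]), d = d[keep])
  out[order(-out$d), ]
}
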