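## Shared fixtures, built lazily and cached for the session so several
## test files can reuse the same simulated data.

.fixtures <- new.env(parent = emptyenv())

## default configuration forced to one crystal per frame (known truth)
singleCrystalConfig <- function() {
  cfg <- defaultConfig()
  cfg$simulator$crystals_per_frame <- 1L
  cfg
}

## small simulated stack with ground truth
fixtureStack <- function(n = 10, seed = 21) {
  key <- sprintf("stack_%d_%d", n, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulateDataset(singleCrystalConfig(), n,
                                        seed = seed)
  .fixtures[[key]]
}

## measurement stream for merging statistics
fixtureStream <- function(n = 600, seed = 3) {
  key <- sprintf("stream_%d_%d", n, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulateMeasurementStream(defaultConfig(), n,
                                                  seed = seed)
  .fixtures[[key]]
}

## match lookup key for integer hkl triples
hklKey <- function(m) (m[, 1] * 1e4 + m[, 2]) * 1e4 + m[, 3]

## truth rotation matrix of frame i in a single-crystal fixture stack
truthRotation <- function(stack, i) {
  ev <- stack@truthEvents
  quaternionToMatrix(as.numeric(ev[ev$frame == i,
                                   c("q1", "q2", "q3", "q4")]))
}

## misorientation (deg) between two rotations modulo point-group ops
misorientation <- function(R1, R2, sym) {
  best <- 180
  for (S in sym@pointOps) {
    M <- crossprod(R1, R2 %*% S)
    ang <- acos(min(1, max(-1, (sum(diag(M)) - 1) / 2))) * 180 / pi
    best <- min(best, ang)
  }
  best
}
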