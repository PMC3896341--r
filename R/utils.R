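# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Uniform integer in [lo, hi] (single draw).
sampleInt <- function(bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  as.integer(floor(runif(1, lo, hi + 1)))
}

deg2rad <- function(d) d * pi / 180

# Smallest absolute angular difference between two angles (radians).
angDiff <- function(a, b) {
  d <- a - b
  abs(atan2(sin(d), cos(d)))
}

# Wrap angle to (-pi, pi].
wrapAngle <- function(a) atan2(sin(a), cos(a))

# Linear pixel index (column-major, 1-based) -> 0-based (x, y).
idxToXY <- function(idx, nr) {
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  cbind(x = as.numeric(c), y = as.numeric(r))
}

# 0-based integer (x, y) -> linear pixel index.
xyToIdx <- function(x, y, nr) {
  as.integer(y + 1L + x * nr)
}
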