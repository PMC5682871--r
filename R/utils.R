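# Angular helpers. Repo-wide convention: degrees, counterclockwise about the
# LV centre; sectors of a K-profile are half-open [k*360/K, (k+1)*360/K).

normDeg <- function(a) ((a %% 360) + 360) %% 360

# smallest absolute circular distance between two angles, in [0, 180]
circDistDeg <- function(a, b) {
  d <- abs(normDeg(a) - normDeg(b)) %% 360
  pmin(d, 360 - d)
}

# TRUE where angle theta lies in the wedge centred at `center` with full
# angular width `width` (half-open at the trailing edge)
inWedgeDeg <- function(theta, center, width) {
  if (width >= 360) return(rep(TRUE, length(theta)))
  d <- normDeg(theta - (center - width / 2))
  d < width
}

# 1-based index of the sector containing each angle, for K equal sectors
sectorIndexDeg <- function(theta, K) {
  idx <- floor(normDeg(theta) / (360 / K)) + 1L
  # guard against floating angles that normalise to exactly 360
  idx[idx > K] <- 1L
  as.integer(idx)
}

# overlap (degrees) of two circular arcs [a1,b1) and [a2,b2), widths <= 360
circOverlapDeg <- function(a1, b1, a2, b2) {
  w1 <- b1 - a1
  w2 <- b2 - a2
  a1 <- normDeg(a1); a2 <- normDeg(a2)
  # unroll arc 2 to the two candidate copies nearest arc 1
  tot <- 0
  for (shift in c(-360, 0, 360)) {
    lo <- max(a1, a2 + shift)
    hi <- min(a1 + w1, a2 + shift + w2)
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with the offending field named, for spec-style validation messages
failField <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
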