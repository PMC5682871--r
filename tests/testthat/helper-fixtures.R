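# Shared fixture builders; everything is generated in code at test time.

# circular annulus geometry (optionally two frames for ES analyses)
circleGeometry <- function(endo = 20, epi = 30, endoEs = NULL, epiEs = NULL,
                           stepDeg = 0.5, center = c(0, 0)) {
  th <- seq(0, 360 - stepDeg, by = stepDeg)
  n <- length(th)
  if (is.null(endoEs)) {
    SliceGeometry(center, th, rep(endo, n), rep(epi, n))
  } else {
    SliceGeometry(center, th,
                  rbind(rep(endo, n), rep(endoEs, n)),
                  rbind(rep(epi, n), rep(epiEs, n)),
                  edFrame = 1L, esFrame = 2L)
  }
}

# a quiet noiseless phantom spec used across modules
noiselessSpec <- function(...) PhantomSpec(noiseSd = 0, ...)

# independent per-pixel tally of %TM, deliberately written as an explicit
# double loop so it shares no code with transmuralityProfile()
bruteForceTM <- function(mask, centerXyMm, K = 360) {
  sp <- mask@pixelSpacingMm
  myoC <- scarC <- numeric(K)
  for (r in seq_len(nrow(mask@scar))) {
    for (cc in seq_len(ncol(mask@scar))) {
      if (mask@myoMask[r, cc]) {
        th <- atan2((r - 0.5) * sp - centerXyMm[2],
                    (cc - 0.5) * sp - centerXyMm[1]) * 180 / pi
        th <- ((th %% 360) + 360) %% 360
        k <- floor(th / (360 / K)) + 1
        if (k > K) k <- 1
        myoC[k] <- myoC[k] + 1
        if (mask@scar[r, cc]) scarC[k] <- scarC[k] + 1
      }
    }
  }
  ifelse(myoC > 0, 100 * scarC / myoC, NA_real_)
}

# random-but-seeded phantom specs for property-style loops
randomSpecs <- function(n, seed = 202, noiseSd = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    PhantomSpec(noiseSd = noiseSd,
                scarCenterDeg = runif(1, 0, 360),
                scarWidthDeg = runif(1, 40, 140),
                scarTransmuralityFrac = runif(1, 0.2, 1),
                endoRadiusMm = runif(1, 17, 22),
                epiRadiusMm = runif(1, 27, 33),
                seed = sample.int(1e6, 1))
  })
}
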