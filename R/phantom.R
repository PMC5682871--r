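# Synthetic short-axis LV phantom: annular myocardium, anteroseptal scar
# wedge growing from the endocardium outward, LGE signal linear in local
# fibrosis plus Gaussian noise, and cine motion with suppressed thickening
# in scar.

# pixel-centre coordinates (mm) and polar coordinates about the LV centre
pixelPolar <- function(sizePx, spacingMm, centerXyMm) {
  rows <- sizePx[1]; cols <- sizePx[2]
  x <- (seq_len(cols) - 0.5) * spacingMm
  y <- (seq_len(rows) - 0.5) * spacingMm
  X <- matrix(x, rows, cols, byrow = TRUE)
  Y <- matrix(y, rows, cols)
  dx <- X - centerXyMm[1]
  dy <- Y - centerXyMm[2]
  list(r = sqrt(dx^2 + dy^2),
       theta = normDeg(atan2(dy, dx) * 180 / pi))
}

#' Generate a synthetic LGE slice with known fibrosis ground truth
#'
#' Rasterises the phantom described by a [PhantomSpec-class]: the myocardium
#' is the annulus between the endo- and epicardial contours; the fibrosis
#' field equals `scarFibrosisFrac` inside the scar wedge (angular span
#' `scarWidthDeg` centred on `scarCenterDeg`, radial span covering the
#' innermost `scarTransmuralityFrac` of the wall, measured from the
#' endocardium) and `remoteFibrosisFrac` elsewhere in the myocardium. The LGE
#' image maps the fibrosis field linearly onto
#' `[lgeRemoteIntensity, lgeScarIntensity]` and adds zero-mean Gaussian noise
#' of SD `noiseSd`, clipped at 0. Identical specs (including `seed`) produce
#' bit-identical output.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `geometry` (single-frame
#'   [SliceGeometry-class] at end-diastole), `lge` and `fibrosis`
#'   ([IntensityImage-class]; the fibrosis field is the ground-truth fraction
#'   in `[0, 1]` per pixel).
#' @examples
#' ph <- generatePhantomSlice(PhantomSpec(noiseSd = 0))
#' ph$lge
#' @export
generatePhantomSlice <- function(spec) {
  validObject(spec)
  pol <- pixelPolar(spec@imageSizePx, spec@pixelSpacingMm, spec@centerXyMm)
  myo <- pol$r >= spec@endoRadiusMm & pol$r <= spec@epiRadiusMm
  scarOuter <- spec@endoRadiusMm +
    spec@scarTransmuralityFrac * (spec@epiRadiusMm - spec@endoRadiusMm)
  wedge <- myo & inWedgeDeg(pol$theta, spec@scarCenterDeg, spec@scarWidthDeg) &
    pol$r <= scarOuter

  fib <- matrix(0, spec@imageSizePx[1], spec@imageSizePx[2])
  fib[myo] <- spec@remoteFibrosisFrac
  fib[wedge] <- spec@scarFibrosisFrac

  # linear fibrosis -> intensity map; degenerate when scar and remote
  # fibrosis coincide (flat field at the remote intensity)
  span <- spec@scarFibrosisFrac - spec@remoteFibrosisFrac
  lge <- matrix(0, spec@imageSizePx[1], spec@imageSizePx[2])
  if (span > 0) {
    lge[myo] <- spec@lgeRemoteIntensity +
      (fib[myo] - spec@remoteFibrosisFrac) / span *
        (spec@lgeScarIntensity - spec@lgeRemoteIntensity)
  } else {
    lge[myo] <- spec@lgeRemoteIntensity
  }
  if (spec@noiseSd > 0) {
    lge <- withSeed(spec@seed,
                    lge + matrix(stats::rnorm(length(lge), 0, spec@noiseSd),
                                 nrow(lge), ncol(lge)))
    lge[lge < 0] <- 0
  }

  theta <- seq(0, 360 - 0.5, by = 0.5)
  geom <- SliceGeometry(centerXyMm = spec@centerXyMm, thetaDeg = theta,
                        endoMm = rep(spec@endoRadiusMm, length(theta)),
                        epiMm = rep(spec@epiRadiusMm, length(theta)))
  list(geometry = geom,
       lge = IntensityImage(lge, spec@pixelSpacingMm, myo),
       fibrosis = IntensityImage(fib, spec@pixelSpacingMm, myo))
}

#' Simulate a cine contour series for the phantom
#'
#' Produces `nFrames` contour frames from end-diastole (frame 1) to
#' end-systole (last frame). Wall thickness at angle theta grows linearly
#' over frames by `thickeningScarMm` inside the scar wedge and
#' `thickeningHealthyMm` outside, with a smooth cosine ramp over
#' `borderDeg` degrees at the wedge edges. The endocardium moves inward to
#' realise the thickening while the epicardium stays fixed; an optional
#' whole-ring inward drift `globalInwardMm` (applied to both contours, so
#' wall thickness is unchanged) emulates global systolic contraction, which
#' dominates circumferential shortening in real hearts.
#'
#' @param spec a [PhantomSpec-class].
#' @param borderDeg angular width of the smooth scar-border blending (deg).
#' @param globalInwardMm end-systolic inward drift of both contours, mm
#'   (default 0: epicardium fixed).
#' @return A [SliceGeometry-class] with `nFrames` frames, `edFrame = 1`,
#'   `esFrame = nFrames`.
#' @examples
#' geom <- simulateCine(PhantomSpec(nFrames = 5))
#' geom
#' @export
simulateCine <- function(spec, borderDeg = 15, globalInwardMm = 0) {
  validObject(spec)
  theta <- seq(0, 360 - 0.5, by = 0.5)
  # blending weight: 0 inside the wedge, 1 beyond the border, cosine ramp
  d <- pmax(0, circDistDeg(theta, spec@scarCenterDeg) - spec@scarWidthDeg / 2)
  w <- ifelse(d >= borderDeg, 1, 0.5 * (1 - cos(pi * d / borderDeg)))
  if (borderDeg <= 0) w <- as.numeric(d > 0)
  delta <- spec@thickeningScarMm +
    (spec@thickeningHealthyMm - spec@thickeningScarMm) * w

  maxIn <- max(delta) + globalInwardMm
  if (maxIn >= spec@endoRadiusMm)
    stop("cavity collapse: thickening plus inward drift (", maxIn,
         " mm) reaches the endocardial radius", call. = FALSE)

  n <- spec@nFrames
  fr <- (seq_len(n) - 1) / (n - 1)
  endo <- outer(fr, delta + globalInwardMm,
                function(f, dd) spec@endoRadiusMm - f * dd)
  epi <- matrix(spec@epiRadiusMm, n, length(theta)) -
    outer(fr, rep(globalInwardMm, length(theta)))
  SliceGeometry(centerXyMm = spec@centerXyMm, thetaDeg = theta,
                endoMm = endo, epiMm = epi,
                edFrame = 1L, esFrame = as.integer(n))
}

#' Emulate feature-tracking contour propagation error
#'
#' Feature-tracking software traces the contours in the end-diastolic frame
#' only and propagates them to the other frames by tracking grey-value
#' features, which accumulates spatially smooth tracking error; per-frame
#' semi-automatic segmentation (used for the wall-thickening export) does
#' not share this error. This operation returns a copy of the geometry with
#' zero-mean, angularly correlated radius jitter added to the endo- and
#' epicardial contours of every frame except the (manually traced)
#' end-diastolic reference, with amplitude growing linearly away from it.
#'
#' @param geom a [SliceGeometry-class].
#' @param sdMm tracking-error SD at end-systole, mm (default 1.5, about
#'   three quarters of the 2 mm cine pixel).
#' @param corrDeg angular correlation length of the error field (degrees).
#' @param seed integer RNG seed.
#' @return A [SliceGeometry-class] with jittered contours.
#' @examples
#' geom <- simulateCine(PhantomSpec(nFrames = 5))
#' tracked <- trackContours(geom, sdMm = 0.5, seed = 2)
#' @export
trackContours <- function(geom, sdMm = 1.5, corrDeg = 30, seed = 1L) {
  validObject(geom)
  if (sdMm < 0) failField("sdMm", "must be >= 0")
  if (sdMm == 0) return(geom)
  th <- geom@thetaDeg
  nKnots <- max(4L, as.integer(round(360 / corrDeg)))
  knotAt <- (seq_len(nKnots) - 1) * 360 / nKnots

  # periodic linear interpolation of Gaussian knots onto the angular grid
  smoothField <- function(knots) {
    pos <- th / (360 / nKnots)
    i0 <- floor(pos)
    f <- pos - i0
    lo <- (i0 %% nKnots) + 1
    hi <- ((i0 + 1) %% nKnots) + 1
    (1 - f) * knots[lo] + f * knots[hi]
  }

  n <- geometryFrames(geom)
  ed <- geom@edFrame
  withSeed(seed, {
    eEndo <- smoothField(stats::rnorm(nKnots, 0, sdMm))
    eEpi <- smoothField(stats::rnorm(nKnots, 0, sdMm))
    endo <- geom@endoMm
    epi <- geom@epiMm
    for (f in seq_len(n)) {
      a <- abs(f - ed) / max(1, n - ed)  # 0 at ED, 1 at the far frame
      endo[f, ] <- pmax(0, endo[f, ] + a * eEndo)
      epi[f, ] <- epi[f, ] + a * eEpi
      # keep the wall admissible where jitter would cross the contours
      bad <- epi[f, ] <= endo[f, ]
      if (any(bad)) epi[f, bad] <- endo[f, bad] + 0.1
    }
    SliceGeometry(geom@centerXyMm, th, endo, epi,
                  edFrame = geom@edFrame, esFrame = geom@esFrame)
  })
}
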