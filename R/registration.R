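# Rotational registration between the CMR and histology angular frames via
# the mid-lateral landmark (the point opposite both RV hinge points).

#' Mid-lateral landmark angle from the RV hinge points
#'
#' The mid-lateral reference is the point on the LV wall opposite both
#' right-ventricular hinge points: the circular midpoint of the major arc
#' between the two hinge angles (equivalently, the minor-arc midpoint plus
#' 180 degrees).
#'
#' @param hingeAngleADeg,hingeAngleBDeg the two RV hinge-point angles
#'   (degrees; distinct, and not diametrically opposite).
#' @return The landmark angle, normalised to `[0, 360)`.
#' @examples
#' midlateralAngle(150, 210)  # hinges flanking the septum at 180 -> 0
#' @export
midlateralAngle <- function(hingeAngleADeg, hingeAngleBDeg) {
  a <- normDeg(hingeAngleADeg)
  b <- normDeg(hingeAngleBDeg)
  if (isTRUE(all.equal(a, b)))
    stop("hinge angles coincide; landmark undefined", call. = FALSE)
  d <- normDeg(b - a)
  if (isTRUE(all.equal(d, 180)))
    stop("hinge angles are diametrically opposite; the two arcs are equal ",
         "and the landmark is ambiguous", call. = FALSE)
  minorMid <- if (d < 180) normDeg(a + d / 2) else normDeg(b + (360 - d) / 2)
  normDeg(minorMid + 180)
}

# fractional circular shift of a sampled profile. `shift` in sector units:
# out[k] = in[k + shift].
circularShift <- function(v, shift, method = c("fourier", "linear", "nearest")) {
  method <- match.arg(method)
  K <- length(v)
  shift <- shift %% K
  if (abs(shift - round(shift)) < 1e-12) {  # integer shift: exact relabelling
    s <- as.integer(round(shift)) %% K
    if (s == 0) return(v)
    return(v[c((s + 1):K, seq_len(s))])
  }
  if (method == "nearest")
    return(circularShift(v, round(shift), "linear"))
  if (method == "linear") {
    i0 <- floor(shift)
    f <- shift - i0
    lo <- ((seq_len(K) - 1 + i0) %% K) + 1
    hi <- ((seq_len(K) + i0) %% K) + 1
    return((1 - f) * v[lo] + f * v[hi])
  }
  # spectral shift: exact rotation of the trigonometric interpolant, so
  # band-limited profiles round-trip to machine precision
  V <- stats::fft(v)
  j <- seq_len(K) - 1
  freq <- ifelse(j <= K / 2, j, j - K)
  mult <- exp(2i * pi * freq * shift / K)
  if (K %% 2 == 0) mult[K / 2 + 1] <- cos(2 * pi * (K / 2) * shift / K)
  Re(stats::fft(V * mult, inverse = TRUE)) / K
}

#' Rotate a sector profile between landmark frames
#'
#' Circularly shifts the profile so that angles measured from the source
#' frame's landmark map onto the same offsets from the target frame's
#' landmark -- the profile-level equivalent of rotating the CMR dataset about
#' the LV centre until the mid-lateral reference points align. Non-integer
#' sector shifts are resampled; the default spectral interpolation is exact
#' for band-limited profiles (and reduces to exact relabelling for integer
#' shifts), with `"linear"` (circular linear interpolation) and
#' `"nearest"` available.
#'
#' @param profile a [SectorProfile-class].
#' @param from,to [LandmarkFrame-class] of the source and target frames.
#' @param method interpolation for fractional sector shifts.
#' @return The rotated [SectorProfile-class], tagged with the target frame.
#' @examples
#' p <- SectorProfile(sin(2 * pi * (0:35) / 36), frameTag = "cmr")
#' cmr <- LandmarkFrame(referenceAngleDeg = 40, sourceTag = "cmr")
#' hist <- LandmarkFrame(referenceAngleDeg = 0, sourceTag = "histology")
#' rotateProfile(p, cmr, hist)
#' @export
rotateProfile <- function(profile, from, to,
                          method = c("fourier", "linear", "nearest")) {
  validObject(profile)
  method <- match.arg(method)
  K <- nSectors(profile)
  deltaDeg <- from@referenceAngleDeg - to@referenceAngleDeg
  shift <- deltaDeg / (360 / K)
  SectorProfile(circularShift(profileValues(profile), shift, method),
                quantity = profile@quantity, units = profile@units,
                frameTag = to@sourceTag)
}
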