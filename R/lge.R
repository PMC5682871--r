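# LGE scar delineation and polar export: full-width-at-half-maximum and
# n-SD-from-remote thresholding, manual-correction subtraction, and
# per-sector fraction of transmurality (%TM) and myocardial signal
# intensity (MSI).

asRegion <- function(region, img, what) {
  if (is.character(region) && identical(region, "auto")) return(img@myoMask)
  if (!is.matrix(region) || !all(dim(region) == dim(img@pixels)))
    failField(what, "must be 'auto' or a logical matrix matching the image")
  if (any(region & !img@myoMask))
    failField(what, "must lie inside the myocardial mask")
  region
}

#' Full-width-at-half-maximum scar delineation
#'
#' Threshold at half the maximal signal intensity within the scar seed
#' region; every myocardial pixel at or above the threshold is scar. With
#' `seedRegion = "auto"` the whole myocardium seeds the maximum.
#'
#' @param img an [IntensityImage-class].
#' @param seedRegion logical matrix inside the myocardium, or `"auto"`.
#' @return A [ScarMask-class] tagged `FWHM` with the threshold recorded.
#' @examples
#' ph <- generatePhantomSlice(PhantomSpec(noiseSd = 0))
#' fwhmMask(ph$lge)
#' @export
fwhmMask <- function(img, seedRegion = "auto") {
  validObject(img)
  seed <- asRegion(seedRegion, img, "seedRegion")
  if (!any(seed)) stop("seed region is empty", call. = FALSE)
  thr <- 0.5 * max(img@pixels[seed])
  new("ScarMask", scar = img@myoMask & img@pixels >= thr,
      myoMask = img@myoMask, pixelSpacingMm = img@pixelSpacingMm,
      methodTag = "FWHM", thresholdUsed = thr)
}

#' n-SD-from-remote scar delineation
#'
#' Threshold at the remote-region mean plus `nSd` standard deviations;
#' myocardial pixels strictly above the threshold are scar. The study used
#' 2, 3 and 5 SD with the remote region placed in the healthy lateral wall.
#'
#' @param img an [IntensityImage-class].
#' @param remoteRegion logical matrix of remote (healthy) myocardium, at
#'   least 2 pixels.
#' @param nSd number of standard deviations (2, 3 or 5 in study mode).
#' @param sdType `"population"` (divisor N, default) or `"sample"`
#'   (divisor N-1).
#' @return A [ScarMask-class] tagged `SD<n>`.
#' @export
sdRemoteMask <- function(img, remoteRegion, nSd,
                         sdType = c("population", "sample")) {
  validObject(img)
  sdType <- match.arg(sdType)
  remote <- asRegion(remoteRegion, img, "remoteRegion")
  n <- sum(remote)
  if (n < 2) stop("remote region needs at least 2 pixels", call. = FALSE)
  v <- img@pixels[remote]
  s <- stats::sd(v)
  if (sdType == "population") s <- s * sqrt((n - 1) / n)
  if (is.na(s)) s <- 0
  thr <- mean(v) + nSd * s
  tag <- if (nSd == round(nSd)) sprintf("SD%d", as.integer(nSd))
         else sprintf("SD%.1f", nSd)
  new("ScarMask", scar = img@myoMask & img@pixels > thr,
      myoMask = img@myoMask, pixelSpacingMm = img@pixelSpacingMm,
      methodTag = tag, thresholdUsed = thr)
}

#' Remove a manually identified region from a scar mask
#'
#' Set subtraction of an exclusion region (artefacts, enhancement outside
#' the expected infarct territory) from the delineated scar; the method tag
#' gains an `m` suffix. An empty exclusion is the identity.
#'
#' @param mask a [ScarMask-class].
#' @param exclusionRegion logical matrix of pixels to remove.
#' @return The corrected [ScarMask-class].
#' @export
applyManualCorrection <- function(mask, exclusionRegion) {
  stopifnot(all(dim(exclusionRegion) == dim(mask@scar)))
  tag <- mask@methodTag
  if (!endsWith(tag, "m")) tag <- paste0(tag, "m")
  new("ScarMask", scar = mask@scar & !exclusionRegion,
      myoMask = mask@myoMask, pixelSpacingMm = mask@pixelSpacingMm,
      methodTag = tag, thresholdUsed = mask@thresholdUsed)
}

# per-pixel sector index over a mask's grid, angles about the geometry centre
maskSectorIndex <- function(dims, spacingMm, centerXyMm, K) {
  pol <- pixelPolar(dims, spacingMm, centerXyMm)
  matrix(sectorIndexDeg(pol$theta, K), dims[1], dims[2])
}

#' Fraction of transmurality per sector
#'
#' Area-based transmurality: per equal angular sector (wedge) about the LV
#' centre, 100 times the scar pixel count over the myocardial pixel count
#' within the wedge. Wedges without myocardial pixels are flagged missing
#' (`NA`).
#'
#' @param mask a [ScarMask-class].
#' @param geom a [SliceGeometry-class] sharing the image's spatial frame
#'   (supplies the LV centre).
#' @param K number of sectors (study export: 360).
#' @return A [SectorProfile-class] of \%TM values in `[0, 100]`.
#' @examples
#' ph <- generatePhantomSlice(PhantomSpec(noiseSd = 0))
#' tm <- transmuralityProfile(fwhmMask(ph$lge), ph$geometry)
#' range(profileValues(tm))
#' @export
transmuralityProfile <- function(mask, geom, K = 360L) {
  validObject(geom)
  idx <- maskSectorIndex(dim(mask@scar), mask@pixelSpacingMm,
                         geom@centerXyMm, K)
  myoCount <- tabulate(idx[mask@myoMask], nbins = K)
  scarCount <- tabulate(idx[mask@scar], nbins = K)
  vals <- ifelse(myoCount > 0, 100 * scarCount / myoCount, NA_real_)
  SectorProfile(vals, quantity = sprintf("%%TM (%s)", mask@methodTag),
                units = "%")
}

#' Myocardial signal intensity per sector
#'
#' Mean LGE intensity over the myocardial pixels of each angular wedge,
#' arbitrary units. Empty wedges are flagged missing (`NA`).
#'
#' @param img an [IntensityImage-class].
#' @param geom a [SliceGeometry-class] supplying the LV centre.
#' @param K number of sectors (study export: 360).
#' @return A [SectorProfile-class] of MSI values.
#' @export
msiProfile <- function(img, geom, K = 360L) {
  validObject(img); validObject(geom)
  idx <- maskSectorIndex(dim(img@pixels), img@pixelSpacingMm,
                         geom@centerXyMm, K)
  myoIdx <- factor(idx[img@myoMask], levels = seq_len(K))
  sums <- tapply(img@pixels[img@myoMask], myoIdx, sum)
  counts <- tabulate(idx[img@myoMask], nbins = K)
  vals <- ifelse(counts > 0, as.numeric(sums) / counts, NA_real_)
  vals[is.nan(vals)] <- NA_real_
  SectorProfile(vals, quantity = "MSI", units = "AU")
}

#' Angular region of the myocardium
#'
#' Builds a logical pixel region from an angular span about the LV centre,
#' intersected with the myocardial mask. Used to place the remote
#' (lateral-wall) region for the SD-from-remote methods and manual-correction
#' territories.
#'
#' @param img an [IntensityImage-class].
#' @param centerXyMm LV centre (mm).
#' @param spanDeg length-2 numeric, `c(start, end)` of the half-open angular
#'   span (may wrap through 0).
#' @return A logical matrix.
#' @export
angularRegion <- function(img, centerXyMm, spanDeg) {
  pol <- pixelPolar(dim(img@pixels), img@pixelSpacingMm, centerXyMm)
  width <- normDeg(spanDeg[2] - spanDeg[1])
  if (width == 0) width <- 360
  d <- normDeg(pol$theta - spanDeg[1])
  img@myoMask & (d < width)
}
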