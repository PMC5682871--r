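#' @import methods
NULL

# ---------------------------------------------------------------------------
# PhantomSpec
# ---------------------------------------------------------------------------

#' Specification of a synthetic short-axis LV phantom
#'
#' A `PhantomSpec` fixes every parameter of the synthetic left-ventricular
#' short-axis slice: an annular myocardium between circular endo- and
#' epicardial contours, an anteroseptal scar wedge of given angular width and
#' transmural depth (growing from the endocardium outward, as in
#' ischemia-reperfusion infarcts), piecewise-constant fibrosis fractions, LGE
#' intensity levels for scar and remote tissue with additive Gaussian noise,
#' and cine motion parameters (wall thickening in mm for healthy and scarred
#' myocardium). All angles are degrees, counterclockwise about the LV centre.
#'
#' @slot imageSizePx integer pair, image size in pixels (rows, cols).
#' @slot pixelSpacingMm positive pixel spacing in mm.
#' @slot centerXyMm LV centre in mm (x, y).
#' @slot endoRadiusMm,epiRadiusMm end-diastolic contour radii in mm
#'   (`epiRadiusMm > endoRadiusMm > 0`).
#' @slot scarCenterDeg,scarWidthDeg scar wedge centre and full angular width.
#' @slot scarTransmuralityFrac transmural extent of the scar in `[0, 1]`,
#'   measured from the endocardium.
#' @slot scarFibrosisFrac,remoteFibrosisFrac fibrosis area fractions in scar
#'   and remote myocardium.
#' @slot lgeScarIntensity,lgeRemoteIntensity LGE signal levels (arbitrary
#'   units), scar strictly brighter than remote.
#' @slot noiseSd SD of additive zero-mean Gaussian image noise.
#' @slot nFrames number of cine frames (>= 2).
#' @slot thickeningHealthyMm,thickeningScarMm systolic wall-thickness increase
#'   in healthy and scarred sectors, mm.
#' @slot rvHingeAnglesDeg the two RV hinge-point angles.
#' @slot seed integer RNG seed; generation is a pure function of the spec.
#' @export
setClass("PhantomSpec", representation(
  imageSizePx = "integer",
  pixelSpacingMm = "numeric",
  centerXyMm = "numeric",
  endoRadiusMm = "numeric",
  epiRadiusMm = "numeric",
  scarCenterDeg = "numeric",
  scarWidthDeg = "numeric",
  scarTransmuralityFrac = "numeric",
  scarFibrosisFrac = "numeric",
  remoteFibrosisFrac = "numeric",
  lgeScarIntensity = "numeric",
  lgeRemoteIntensity = "numeric",
  noiseSd = "numeric",
  nFrames = "integer",
  thickeningHealthyMm = "numeric",
  thickeningScarMm = "numeric",
  rvHingeAnglesDeg = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  chk <- function(cond, field, msg) if (!cond) sprintf("invalid `%s`: %s", field, msg) else NULL
  errs <- c(
    chk(length(object@imageSizePx) == 2 && all(object@imageSizePx >= 8),
        "imageSizePx", "must be two integers >= 8"),
    chk(object@pixelSpacingMm > 0, "pixelSpacingMm", "must be > 0"),
    chk(object@endoRadiusMm > 0, "endoRadiusMm", "must be > 0"),
    chk(object@epiRadiusMm > object@endoRadiusMm,
        "epiRadiusMm", "must exceed endoRadiusMm"),
    chk(object@scarWidthDeg > 0 && object@scarWidthDeg <= 360,
        "scarWidthDeg", "must lie in (0, 360]"),
    chk(object@scarTransmuralityFrac >= 0 && object@scarTransmuralityFrac <= 1,
        "scarTransmuralityFrac", "must lie in [0, 1]"),
    chk(object@scarFibrosisFrac >= 0 && object@scarFibrosisFrac <= 1,
        "scarFibrosisFrac", "must lie in [0, 1]"),
    chk(object@remoteFibrosisFrac >= 0 && object@remoteFibrosisFrac <= 1,
        "remoteFibrosisFrac", "must lie in [0, 1]"),
    chk(object@lgeScarIntensity > object@lgeRemoteIntensity,
        "lgeScarIntensity", "must exceed lgeRemoteIntensity"),
    chk(object@noiseSd >= 0, "noiseSd", "must be >= 0"),
    chk(object@nFrames >= 2, "nFrames", "must be >= 2"),
    chk(length(object@rvHingeAnglesDeg) == 2,
        "rvHingeAnglesDeg", "must be an angle pair")
  )
  if (length(errs)) errs else TRUE
})

#' Construct a phantom specification
#'
#' Defaults describe the study conditions emulated throughout the package: a
#' 128 x 128 grid at 1.5 mm spacing, a 20/30 mm annulus, a 90 degree
#' anteroseptal scar wedge, scar fibrosis near the observed maximum of ~50
#' percent over a 3 percent remote background, a five-fold LGE contrast, and a
#' 30-frame cine with 4 mm healthy thickening and an akinetic scar.
#'
#' @param imageSizePx,pixelSpacingMm,centerXyMm image geometry.
#' @param endoRadiusMm,epiRadiusMm end-diastolic contour radii (mm).
#' @param scarCenterDeg,scarWidthDeg,scarTransmuralityFrac scar wedge.
#' @param scarFibrosisFrac,remoteFibrosisFrac fibrosis fractions.
#' @param lgeScarIntensity,lgeRemoteIntensity,noiseSd LGE signal model.
#' @param nFrames,thickeningHealthyMm,thickeningScarMm cine motion.
#' @param rvHingeAnglesDeg RV hinge-point angles (degrees).
#' @param seed integer RNG seed.
#' @return A validated [PhantomSpec-class] object.
#' @examples
#' spec <- PhantomSpec(noiseSd = 0)
#' spec
#' @export
PhantomSpec <- function(imageSizePx = c(128L, 128L),
                        pixelSpacingMm = 1.5,
                        centerXyMm = NULL,
                        endoRadiusMm = 20,
                        epiRadiusMm = 30,
                        scarCenterDeg = 150,
                        scarWidthDeg = 90,
                        scarTransmuralityFrac = 0.6,
                        scarFibrosisFrac = 0.5,
                        remoteFibrosisFrac = 0.03,
                        lgeScarIntensity = 100,
                        lgeRemoteIntensity = 20,
                        noiseSd = 5,
                        nFrames = 30L,
                        thickeningHealthyMm = 4,
                        thickeningScarMm = 0,
                        rvHingeAnglesDeg = c(120, 240),
                        seed = 1L) {
  if (is.null(centerXyMm))
    centerXyMm <- rev(imageSizePx) * pixelSpacingMm / 2
  new("PhantomSpec",
      imageSizePx = as.integer(imageSizePx),
      pixelSpacingMm = pixelSpacingMm,
      centerXyMm = as.numeric(centerXyMm),
      endoRadiusMm = endoRadiusMm,
      epiRadiusMm = epiRadiusMm,
      scarCenterDeg = normDeg(scarCenterDeg),
      scarWidthDeg = scarWidthDeg,
      scarTransmuralityFrac = scarTransmuralityFrac,
      scarFibrosisFrac = scarFibrosisFrac,
      remoteFibrosisFrac = remoteFibrosisFrac,
      lgeScarIntensity = lgeScarIntensity,
      lgeRemoteIntensity = lgeRemoteIntensity,
      noiseSd = noiseSd,
      nFrames = as.integer(nFrames),
      thickeningHealthyMm = thickeningHealthyMm,
      thickeningScarMm = thickeningScarMm,
      rvHingeAnglesDeg = normDeg(rvHingeAnglesDeg),
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:",
      sprintf("%dx%d px @ %.2f mm,", object@imageSizePx[1],
              object@imageSizePx[2], object@pixelSpacingMm),
      sprintf("annulus %.1f-%.1f mm,", object@endoRadiusMm, object@epiRadiusMm),
      sprintf("scar %.0f deg @ %.0f deg, transmurality %.2f",
              object@scarWidthDeg, object@scarCenterDeg,
              object@scarTransmuralityFrac), "\n")
})

# ---------------------------------------------------------------------------
# CohortSpec
# ---------------------------------------------------------------------------

#' Specification of a simulated multi-animal section cohort
#'
#' Describes a two-level design on the log-fibrosis scale: per animal a random
#' intercept `u_i ~ N(0, tau00)`, per section a covariate draw and a residual
#' `e_ij ~ N(0, sigma2)`, giving `log(fibrosis) = beta0 + beta1 * x + u_i +
#' e_ij`. `sigma2` is the within-animal (residual) variance and `tau00` the
#' between-animal (intercept) variance.
#'
#' @slot nAnimals,sectionsPerAnimal design size (both >= 2).
#' @slot beta0,beta1 fixed intercept and slope on the log-fibrosis scale.
#' @slot sigma2,tau00 residual and random-intercept variances (>= 0).
#' @slot covariateGenerator list with element `dist` ("normal" or "uniform")
#'   and its parameters (`mean`/`sd` or `min`/`max`).
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec", representation(
  nAnimals = "integer",
  sectionsPerAnimal = "integer",
  beta0 = "numeric",
  beta1 = "numeric",
  sigma2 = "numeric",
  tau00 = "numeric",
  covariateGenerator = "list",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  errs <- character()
  if (object@nAnimals < 2) errs <- c(errs, "invalid `nAnimals`: must be >= 2")
  if (object@sectionsPerAnimal < 2)
    errs <- c(errs, "invalid `sectionsPerAnimal`: must be >= 2")
  if (object@sigma2 < 0) errs <- c(errs, "invalid `sigma2`: must be >= 0")
  if (object@tau00 < 0) errs <- c(errs, "invalid `tau00`: must be >= 0")
  if (!is.character(object@covariateGenerator$dist) ||
      !object@covariateGenerator$dist %in% c("normal", "uniform"))
    errs <- c(errs, "invalid `covariateGenerator`: dist must be 'normal' or 'uniform'")
  if (length(errs)) errs else TRUE
})

#' Construct a cohort specification
#'
#' Defaults mirror the scale of the emulated study: 15 animals with 8 wedge
#' sections each, residual variance 1.0 and between-animal intercept variance
#' 0.25 on the log-fibrosis scale, and a standard-normal covariate.
#'
#' @param nAnimals,sectionsPerAnimal design size.
#' @param beta0,beta1 fixed effects on log-fibrosis.
#' @param sigma2,tau00 residual and random-intercept variances.
#' @param covariateGenerator named list, e.g.
#'   `list(dist = "normal", mean = 0, sd = 1)` or
#'   `list(dist = "uniform", min = 0, max = 1)`.
#' @param seed integer RNG seed.
#' @return A validated [CohortSpec-class] object.
#' @export
CohortSpec <- function(nAnimals = 15L, sectionsPerAnimal = 8L,
                       beta0 = 1.5, beta1 = 0.5,
                       sigma2 = 1.0, tau00 = 0.25,
                       covariateGenerator = list(dist = "normal", mean = 0, sd = 1),
                       seed = 1L) {
  new("CohortSpec", nAnimals = as.integer(nAnimals),
      sectionsPerAnimal = as.integer(sectionsPerAnimal),
      beta0 = beta0, beta1 = beta1, sigma2 = sigma2, tau00 = tau00,
      covariateGenerator = covariateGenerator, seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d animals x %d sections, beta=(%.2f, %.2f), sigma2=%.2f, tau00=%.2f\n",
    object@nAnimals, object@sectionsPerAnimal, object@beta0, object@beta1,
    object@sigma2, object@tau00))
})

# ---------------------------------------------------------------------------
# SliceGeometry
# ---------------------------------------------------------------------------

#' Polar contour geometry of a short-axis LV slice
#'
#' Endo- and epicardial contours for each cine frame, stored as polar radius
#' functions sampled on a fixed angular grid about the LV centre. This is the
#' substrate for wall thickness, strain, and polar sampling of images.
#'
#' @slot centerXyMm LV centre (x, y) in mm.
#' @slot thetaDeg ascending angular grid in `[0, 360)`, >= 360 samples.
#' @slot endoMm,epiMm matrices `[nFrames x nTheta]` of radii in mm with
#'   `epi(theta) > endo(theta) >= 0` everywhere.
#' @slot edFrame,esFrame 1-based end-diastolic / end-systolic frame indices
#'   (`esFrame` may be `NA`, in which case end-systole is located as the frame
#'   of minimal cavity area).
#' @export
setClass("SliceGeometry", representation(
  centerXyMm = "numeric",
  thetaDeg = "numeric",
  endoMm = "matrix",
  epiMm = "matrix",
  edFrame = "integer",
  esFrame = "integer"
))

setValidity("SliceGeometry", function(object) {
  errs <- character()
  nt <- length(object@thetaDeg)
  if (nt < 360) errs <- c(errs, "thetaDeg must have >= 360 samples")
  if (is.unsorted(object@thetaDeg, strictly = TRUE) ||
      any(object@thetaDeg < 0) || any(object@thetaDeg >= 360))
    errs <- c(errs, "thetaDeg must be strictly ascending in [0, 360)")
  if (ncol(object@endoMm) != nt || ncol(object@epiMm) != nt ||
      nrow(object@endoMm) != nrow(object@epiMm))
    errs <- c(errs, "endoMm/epiMm dimensions inconsistent with thetaDeg")
  if (any(object@endoMm < 0)) errs <- c(errs, "endo radii must be >= 0")
  if (any(object@epiMm <= object@endoMm))
    errs <- c(errs, "epi radius must exceed endo radius at every angle")
  nf <- nrow(object@endoMm)
  if (object@edFrame < 1 || object@edFrame > nf)
    errs <- c(errs, "edFrame out of range")
  if (!is.na(object@esFrame) && (object@esFrame < 1 || object@esFrame > nf))
    errs <- c(errs, "esFrame out of range")
  if (length(errs)) errs else TRUE
})

#' Construct a SliceGeometry
#'
#' @param centerXyMm LV centre (x, y), mm.
#' @param thetaDeg angular grid (degrees, ascending, in `[0, 360)`).
#' @param endoMm,epiMm radius matrices `[nFrames x nTheta]` (a vector is
#'   treated as a single frame), mm.
#' @param edFrame end-diastolic frame index (default 1).
#' @param esFrame end-systolic frame index, or `NA` to auto-detect.
#' @return A [SliceGeometry-class] object.
#' @export
SliceGeometry <- function(centerXyMm, thetaDeg, endoMm, epiMm,
                          edFrame = 1L, esFrame = NA_integer_) {
  if (is.vector(endoMm)) endoMm <- matrix(endoMm, nrow = 1)
  if (is.vector(epiMm)) epiMm <- matrix(epiMm, nrow = 1)
  new("SliceGeometry", centerXyMm = as.numeric(centerXyMm),
      thetaDeg = as.numeric(thetaDeg), endoMm = endoMm, epiMm = epiMm,
      edFrame = as.integer(edFrame), esFrame = as.integer(esFrame))
}

#' @describeIn SliceGeometry-class number of cine frames
#' @param geom a `SliceGeometry`
#' @export
geometryFrames <- function(geom) nrow(geom@endoMm)

#' Endocardial cavity area of one frame
#'
#' Polar area `0.5 * integral(endo(theta)^2 dtheta)` evaluated on the stored
#' angular grid, in mm^2.
#'
#' @param geom a [SliceGeometry-class].
#' @param frame 1-based frame index.
#' @return Cavity area in mm^2.
#' @export
cavityAreaMm2 <- function(geom, frame) {
  stopifnot(frame >= 1, frame <= geometryFrames(geom))
  r <- geom@endoMm[frame, ]
  th <- c(geom@thetaDeg, geom@thetaDeg[1] + 360) * pi / 180
  dth <- diff(th)
  sum(0.5 * r^2 * dth)
}

setMethod("show", "SliceGeometry", function(object) {
  cat(sprintf(
    "SliceGeometry: %d frame(s), %d angular samples, centre (%.1f, %.1f) mm\n",
    geometryFrames(object), length(object@thetaDeg),
    object@centerXyMm[1], object@centerXyMm[2]))
  wt <- object@epiMm[object@edFrame, ] - object@endoMm[object@edFrame, ]
  cat(sprintf("  ED wall thickness %.2f-%.2f mm\n", min(wt), max(wt)))
})

# ---------------------------------------------------------------------------
# SectorProfile
# ---------------------------------------------------------------------------

#' A value per equal angular sector
#'
#' The universal exchange format between the CMR stages and registration: `K`
#' values, one per half-open sector `[k*360/K, (k+1)*360/K)` in the frame
#' named by `frameTag`. Study-mode sector counts are 60 (wall thickening), 48
#' (feature-tracking strain) and 360 (transmurality / signal intensity); any
#' `K >= 1` is accepted in library use.
#'
#' @slot values numeric vector of length `K` (`NA` marks sectors flagged
#'   missing, e.g. wedges with no myocardial pixels).
#' @slot quantity short label of the measured quantity.
#' @slot units measurement units.
#' @slot frameTag angular frame the profile lives in (e.g. "cmr",
#'   "histology").
#' @export
setClass("SectorProfile", representation(
  values = "numeric",
  quantity = "character",
  units = "character",
  frameTag = "character"
))

setValidity("SectorProfile", function(object) {
  if (length(object@values) < 1) "profile must hold at least one sector" else TRUE
})

#' Construct a SectorProfile
#'
#' @param values numeric vector, one value per sector.
#' @param quantity,units,frameTag metadata tags.
#' @return A [SectorProfile-class] object.
#' @export
SectorProfile <- function(values, quantity = "value", units = "",
                          frameTag = "cmr") {
  new("SectorProfile", values = as.numeric(values), quantity = quantity,
      units = units, frameTag = frameTag)
}

#' @describeIn SectorProfile-class number of sectors
#' @param x a `SectorProfile`
#' @export
nSectors <- function(x) length(x@values)

#' @describeIn SectorProfile-class the per-sector values
#' @export
profileValues <- function(x) x@values

setMethod("show", "SectorProfile", function(object) {
  v <- object@values
  cat(sprintf("SectorProfile: %s [%s], K=%d, frame '%s'\n",
              object@quantity, object@units, length(v), object@frameTag))
  cat(sprintf("  range %.3g..%.3g (%d missing)\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

# ---------------------------------------------------------------------------
# IntensityImage / ScarMask
# ---------------------------------------------------------------------------

#' A 2-D intensity image with a myocardial mask
#'
#' @slot pixels nonnegative numeric matrix (row = image y, col = image x).
#' @slot pixelSpacingMm positive isotropic pixel spacing, mm.
#' @slot myoMask logical matrix of the same dimension marking myocardium.
#' @export
setClass("IntensityImage", representation(
  pixels = "matrix",
  pixelSpacingMm = "numeric",
  myoMask = "matrix"
))

setValidity("IntensityImage", function(object) {
  errs <- character()
  if (!all(dim(object@pixels) == dim(object@myoMask)))
    errs <- c(errs, "myoMask dimensions differ from pixels")
  if (object@pixelSpacingMm <= 0)
    errs <- c(errs, "pixelSpacingMm must be > 0")
  if (!any(object@myoMask)) errs <- c(errs, "myocardial mask is empty")
  if (any(object@pixels < 0)) errs <- c(errs, "pixels must be nonnegative")
  if (length(errs)) errs else TRUE
})

#' Construct an IntensityImage
#'
#' @param pixels numeric matrix of nonnegative intensities.
#' @param pixelSpacingMm pixel spacing in mm.
#' @param myoMask logical matrix marking myocardial pixels.
#' @return An [IntensityImage-class] object.
#' @export
IntensityImage <- function(pixels, pixelSpacingMm, myoMask) {
  new("IntensityImage", pixels = pixels, pixelSpacingMm = pixelSpacingMm,
      myoMask = myoMask)
}

setMethod("show", "IntensityImage", function(object) {
  cat(sprintf("IntensityImage: %dx%d px @ %.2f mm, %d myocardial pixels\n",
              nrow(object@pixels), ncol(object@pixels),
              object@pixelSpacingMm, sum(object@myoMask)))
})

#' A scar delineation result
#'
#' Per-pixel scar labelling of the myocardium together with the delineation
#' method that produced it and the threshold it used, so the threshold is
#' recomputable from the recorded inputs.
#'
#' @slot scar logical matrix, a subset of `myoMask`.
#' @slot myoMask logical matrix of the myocardium the mask lives in.
#' @slot pixelSpacingMm pixel spacing, mm.
#' @slot methodTag one of `FWHM`, `SD2`, `SD3`, `SD5` or their
#'   manually-corrected variants `FWHMm`, `SD2m`, `SD3m`, `SD5m`.
#' @slot thresholdUsed intensity threshold applied.
#' @export
setClass("ScarMask", representation(
  scar = "matrix",
  myoMask = "matrix",
  pixelSpacingMm = "numeric",
  methodTag = "character",
  thresholdUsed = "numeric"
))

setValidity("ScarMask", function(object) {
  errs <- character()
  if (!all(dim(object@scar) == dim(object@myoMask)))
    errs <- c(errs, "scar and myoMask dimensions differ")
  if (any(object@scar & !object@myoMask))
    errs <- c(errs, "scar pixels must all lie inside the myocardial mask")
  if (length(errs)) errs else TRUE
})

setMethod("show", "ScarMask", function(object) {
  cat(sprintf("ScarMask [%s]: %d / %d myocardial pixels, threshold %.3f\n",
              object@methodTag, sum(object@scar), sum(object@myoMask),
              object@thresholdUsed))
})

#' @describeIn ScarMask-class the delineation method tag
#' @param mask a `ScarMask`
#' @export
scarMethod <- function(mask) mask@methodTag

#' @describeIn ScarMask-class the threshold the method applied
#' @export
scarThreshold <- function(mask) mask@thresholdUsed

# ---------------------------------------------------------------------------
# HistoSectionImage / TissueFractions / SectionPartition
# ---------------------------------------------------------------------------

#' A trichrome-style RGB histology section image
#'
#' @slot rgb numeric array `[rows x cols x 3]` with channels in `[0, 1]`.
#' @slot tissueMask logical matrix; epicardium and background are excluded
#'   (`FALSE`). At least one tissue pixel is required.
#' @slot sectionLabel identifier of the section.
#' @slot groundTruth list; for generator output, the true class label matrix
#'   and realized class fractions (empty for real data).
#' @export
setClass("HistoSectionImage", representation(
  rgb = "array",
  tissueMask = "matrix",
  sectionLabel = "character",
  groundTruth = "list"
))

setValidity("HistoSectionImage", function(object) {
  errs <- character()
  d <- dim(object@rgb)
  if (length(d) != 3 || d[3] != 3)
    errs <- c(errs, "rgb must be a [rows x cols x 3] array")
  else if (!all(d[1:2] == dim(object@tissueMask)))
    errs <- c(errs, "tissueMask dimensions differ from rgb")
  if (!any(object@tissueMask))
    errs <- c(errs, "tissueMask must contain at least one tissue pixel")
  if (length(errs)) errs else TRUE
})

#' Construct a HistoSectionImage
#'
#' @param rgb `[rows x cols x 3]` array, channels in `[0, 1]`.
#' @param tissueMask logical matrix (default: all pixels are tissue).
#' @param sectionLabel identifier.
#' @param groundTruth optional generator ground truth.
#' @return A [HistoSectionImage-class] object.
#' @export
HistoSectionImage <- function(rgb, tissueMask = NULL, sectionLabel = "S1",
                              groundTruth = list()) {
  if (is.null(tissueMask))
    tissueMask <- matrix(TRUE, dim(rgb)[1], dim(rgb)[2])
  new("HistoSectionImage", rgb = rgb, tissueMask = tissueMask,
      sectionLabel = sectionLabel, groundTruth = groundTruth)
}

setMethod("show", "HistoSectionImage", function(object) {
  cat(sprintf("HistoSectionImage '%s': %dx%d px, %d tissue pixels\n",
              object@sectionLabel, dim(object@rgb)[1], dim(object@rgb)[2],
              sum(object@tissueMask)))
})

#' Tissue-class area fractions of a histology section
#'
#' Percentages of connective tissue (trichrome blue), cardiomyocytes (red)
#' and adipose tissue (non-stained cytoplasm, pseudo-green) over the tissue
#' mask. The three always sum to 100.
#'
#' @slot connectivePct,myocytePct,adiposePct percentages in `[0, 100]`
#'   summing to 100 (tolerance 1e-6).
#' @export
setClass("TissueFractions", representation(
  connectivePct = "numeric",
  myocytePct = "numeric",
  adiposePct = "numeric"
))

setValidity("TissueFractions", function(object) {
  s <- object@connectivePct + object@myocytePct + object@adiposePct
  vals <- c(object@connectivePct, object@myocytePct, object@adiposePct)
  errs <- character()
  if (any(vals < 0 | vals > 100)) errs <- c(errs, "fractions must lie in [0, 100]")
  if (abs(s - 100) > 1e-6) errs <- c(errs, "fractions must sum to 100")
  if (length(errs)) errs else TRUE
})

#' Construct TissueFractions
#' @param connectivePct,myocytePct,adiposePct class percentages summing to 100.
#' @return A [TissueFractions-class] object.
#' @export
TissueFractions <- function(connectivePct, myocytePct, adiposePct) {
  new("TissueFractions", connectivePct = connectivePct,
      myocytePct = myocytePct, adiposePct = adiposePct)
}

setMethod("show", "TissueFractions", function(object) {
  cat(sprintf("TissueFractions: connective %.2f%%, myocyte %.2f%%, adipose %.2f%%\n",
              object@connectivePct, object@myocytePct, object@adiposePct))
})

#' Angular partition of the LV into histology sections
#'
#' Ordered wedge spans, one per cut histology section, that are disjoint and
#' cover `[0, 360)` exactly in the registered (histology) frame. Ordering
#' follows the cutting order, which starts at the mid-lateral landmark.
#'
#' @slot labels section identifiers in cutting order.
#' @slot startDeg,endDeg half-open spans `[start, end)`; `endDeg` may exceed
#'   360 for the wrapping span.
#' @slot landmarkAngleDeg mid-lateral reference angle of this frame.
#' @export
setClass("SectionPartition", representation(
  labels = "character",
  startDeg = "numeric",
  endDeg = "numeric",
  landmarkAngleDeg = "numeric"
))

setValidity("SectionPartition", function(object) {
  n <- length(object@labels)
  errs <- character()
  if (length(object@startDeg) != n || length(object@endDeg) != n)
    errs <- c(errs, "labels/startDeg/endDeg lengths differ")
  if (anyDuplicated(object@labels))
    errs <- c(errs, "section labels must be unique")
  w <- object@endDeg - object@startDeg
  if (any(w <= 0)) errs <- c(errs, "each span must have positive width")
  if (abs(sum(w) - 360) > 1e-9)
    errs <- c(errs, "spans must cover [0, 360) exactly (widths sum to 360)")
  # contiguity in cutting order (circular)
  if (n > 1) {
    nxt <- c(object@startDeg[-1], object@startDeg[1])
    if (any(circDistDeg(object@endDeg, nxt) > 1e-9))
      errs <- c(errs, "spans must be contiguous: each end must meet the next start")
  }
  if (length(errs)) errs else TRUE
})

#' Construct a SectionPartition
#'
#' @param labels section identifiers in cutting order.
#' @param startDeg,endDeg span boundaries in degrees (half-open).
#' @param landmarkAngleDeg mid-lateral reference angle (default 0).
#' @return A [SectionPartition-class] object.
#' @export
SectionPartition <- function(labels, startDeg, endDeg, landmarkAngleDeg = 0) {
  new("SectionPartition", labels = as.character(labels),
      startDeg = as.numeric(startDeg), endDeg = as.numeric(endDeg),
      landmarkAngleDeg = normDeg(landmarkAngleDeg))
}

#' Equal-width section partition starting at the landmark
#'
#' @param nSections number of sections (the study cut typically 7 or 8 wedges
#'   per heart slice).
#' @param labels optional labels (default `S1..Sn`).
#' @param landmarkAngleDeg mid-lateral reference angle.
#' @return A [SectionPartition-class] with equal wedges.
#' @export
equalPartition <- function(nSections, labels = NULL, landmarkAngleDeg = 0) {
  if (is.null(labels)) labels <- paste0("S", seq_len(nSections))
  w <- 360 / nSections
  SectionPartition(labels, startDeg = (seq_len(nSections) - 1) * w,
                   endDeg = seq_len(nSections) * w,
                   landmarkAngleDeg = landmarkAngleDeg)
}

setMethod("show", "SectionPartition", function(object) {
  cat(sprintf("SectionPartition: %d sections, landmark at %.1f deg\n",
              length(object@labels), object@landmarkAngleDeg))
  for (i in seq_along(object@labels))
    cat(sprintf("  %s: [%.1f, %.1f)\n", object@labels[i],
                object@startDeg[i], object@endDeg[i]))
})

# ---------------------------------------------------------------------------
# LandmarkFrame
# ---------------------------------------------------------------------------

#' An angular frame anchored at the mid-lateral landmark
#'
#' @slot centerXyMm rotation centre (LV centre), mm.
#' @slot referenceAngleDeg angle of the mid-lateral landmark in the native
#'   frame, normalised to `[0, 360)`.
#' @slot sourceTag `"cmr"` or `"histology"`.
#' @export
setClass("LandmarkFrame", representation(
  centerXyMm = "numeric",
  referenceAngleDeg = "numeric",
  sourceTag = "character"
))

setValidity("LandmarkFrame", function(object) {
  if (object@referenceAngleDeg < 0 || object@referenceAngleDeg >= 360)
    "referenceAngleDeg must be normalised to [0, 360)" else TRUE
})

#' Construct a LandmarkFrame
#' @param centerXyMm rotation centre (mm).
#' @param referenceAngleDeg landmark angle in the native frame.
#' @param sourceTag `"cmr"` or `"histology"`.
#' @return A [LandmarkFrame-class] object.
#' @export
LandmarkFrame <- function(centerXyMm = c(0, 0), referenceAngleDeg = 0,
                          sourceTag = "cmr") {
  new("LandmarkFrame", centerXyMm = as.numeric(centerXyMm),
      referenceAngleDeg = normDeg(referenceAngleDeg), sourceTag = sourceTag)
}

setMethod("show", "LandmarkFrame", function(object) {
  cat(sprintf("LandmarkFrame [%s]: reference %.2f deg, centre (%.1f, %.1f) mm\n",
              object@sourceTag, object@referenceAngleDeg,
              object@centerXyMm[1], object@centerXyMm[2]))
})

# ---------------------------------------------------------------------------
# VarianceComponents / MixedModelFit
# ---------------------------------------------------------------------------

#' Variance components of a random-intercept model
#'
#' Residual (within-animal) variance `sigma2` and random-intercept
#' (between-animal) variance `tau00`. When a fit degenerates (the intercept
#' variance hits the zero boundary, so the joint information matrix is not
#' positive definite), the two are pooled: `pooled = TRUE`, `sigma2` holds
#' the pooled total and `tau00` is 0.
#'
#' @slot sigma2,tau00 nonnegative variances.
#' @slot pooled logical; `TRUE` implies `tau00 == 0`.
#' @export
setClass("VarianceComponents", representation(
  sigma2 = "numeric", tau00 = "numeric", pooled = "logical"
))

setValidity("VarianceComponents", function(object) {
  errs <- character()
  if (object@sigma2 < 0) errs <- c(errs, "sigma2 must be >= 0")
  if (object@tau00 < 0) errs <- c(errs, "tau00 must be >= 0")
  if (object@pooled && object@tau00 != 0)
    errs <- c(errs, "pooled components must have tau00 == 0")
  if (length(errs)) errs else TRUE
})

#' Construct VarianceComponents
#' @param sigma2,tau00 nonnegative variances.
#' @param pooled whether `sigma2` holds a pooled total (then `tau00 = 0`).
#' @return A [VarianceComponents-class] object.
#' @export
VarianceComponents <- function(sigma2, tau00 = 0, pooled = FALSE) {
  new("VarianceComponents", sigma2 = sigma2, tau00 = tau00, pooled = pooled)
}

#' @describeIn VarianceComponents-class total variance `sigma2 + tau00`
#' @param vc a `VarianceComponents`
#' @export
totalVariance <- function(vc) {
  if (is(vc, "MixedModelFit")) vc <- vc@components
  vc@sigma2 + vc@tau00
}

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents: sigma2=%.4f, tau00=%.4f%s\n",
              object@sigma2, object@tau00,
              if (object@pooled) " (pooled)" else ""))
})

#' A fitted random-intercept mixed model
#'
#' @slot beta named fixed-effect estimates.
#' @slot components the [VarianceComponents-class].
#' @slot logLik maximised log-likelihood.
#' @slot converged logical; must be `TRUE` before use in explained-variance
#'   computations.
#' @slot boundaryFlag `TRUE` when the random-intercept variance hit the zero
#'   boundary (the pooled representation was used).
#' @slot nObs number of rows used.
#' @slot covariate name of the covariate (`""` for the null model).
#' @export
setClass("MixedModelFit", representation(
  beta = "numeric",
  components = "VarianceComponents",
  logLik = "numeric",
  converged = "logical",
  boundaryFlag = "logical",
  nObs = "integer",
  covariate = "character"
))

setMethod("show", "MixedModelFit", function(object) {
  lab <- if (nzchar(object@covariate)) object@covariate else "(null model)"
  cat(sprintf("MixedModelFit %s: n=%d, logLik=%.2f%s\n", lab, object@nObs,
              object@logLik,
              if (object@boundaryFlag) ", boundary (pooled)" else ""))
  print(round(object@beta, 4))
  show(object@components)
})

#' @describeIn MixedModelFit-class extract the variance components
#' @param fit a `MixedModelFit`
#' @export
varianceComponents <- function(fit) fit@components
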