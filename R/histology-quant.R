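# Trichrome colour-fraction quantification: per-pixel class labelling by a
# fixed hue/saturation partition, section-level tissue fractions, and
# assembly of per-section fibrosis into a 360-sector LV overview.

#' Classify tissue pixels of a trichrome section image
#'
#' Deterministic hue/saturation partition of the tissue pixels: blue-dominant
#' hues are connective tissue, red-dominant hues are cardiomyocytes, and
#' low-saturation or green-dominant pixels (non-stained cytoplasm,
#' pseudo-green) are adipose tissue. Thresholds are exposed as arguments;
#' the defaults separate the generator's stain colours with margin.
#'
#' @param img a [HistoSectionImage-class] with a nonempty tissue mask.
#' @param satMin minimum saturation for a stained (blue/red) call.
#' @param blueHueDeg,redHueDeg hue intervals (degrees on the HSV wheel) for
#'   connective and myocyte calls; `redHueDeg` wraps around 0.
#' @return An integer matrix the size of the image: 1 connective, 2 myocyte,
#'   3 adipose, `NA` outside the tissue mask.
#' @examples
#' img <- generateHistologyImage(0.4, 0.1, c(50, 50), seed = 3)
#' table(classifyPixels(img))
#' @export
classifyPixels <- function(img, satMin = 0.30,
                           blueHueDeg = c(180, 300),
                           redHueDeg = c(315, 45)) {
  validObject(img)
  if (!any(img@tissueMask)) stop("tissue mask is empty", call. = FALSE)
  rgbTis <- rbind(img@rgb[, , 1][img@tissueMask],
                  img@rgb[, , 2][img@tissueMask],
                  img@rgb[, , 3][img@tissueMask])
  hsv <- grDevices::rgb2hsv(rgbTis, maxColorValue = 1)
  hueDeg <- hsv[1, ] * 360
  sat <- hsv[2, ]

  lab <- rep(3L, ncol(hsv))  # default: adipose (low saturation / green)
  stained <- sat >= satMin
  lab[stained & hueDeg >= blueHueDeg[1] & hueDeg < blueHueDeg[2]] <- 1L
  inRed <- hueDeg >= redHueDeg[1] | hueDeg < redHueDeg[2]
  lab[stained & inRed] <- 2L

  out <- matrix(NA_integer_, nrow(img@tissueMask), ncol(img@tissueMask))
  out[img@tissueMask] <- lab
  out
}

#' Tissue-class fractions of one section
#'
#' Class pixel counts over the tissue mask, as percentages that sum to 100
#' exactly. Fractions are scale-invariant, so they do not depend on the
#' resolution the image was loaded at.
#'
#' @param img a [HistoSectionImage-class].
#' @param ... passed to [classifyPixels()].
#' @return A [TissueFractions-class].
#' @examples
#' img <- generateHistologyImage(1, 0, c(20, 20), seed = 1)
#' sectionFibrosis(img)  # all connective
#' @export
sectionFibrosis <- function(img, ...) {
  lab <- classifyPixels(img, ...)
  counts <- tabulate(lab[!is.na(lab)], nbins = 3L)
  n <- sum(counts)
  TissueFractions(connectivePct = 100 * counts[1] / n,
                  myocytePct = 100 * counts[2] / n,
                  adiposePct = 100 * counts[3] / n)
}

#' Assemble per-section fibrosis into a 360-sector LV overview
#'
#' Builds the standardised schematic overview of the slice: each 1-degree
#' sector carries the connective-tissue percentage of the section whose
#' angular span contains it (a piecewise-constant map in the registered
#' histology frame).
#'
#' @param fractions named list of [TissueFractions-class] (or bare fibrosis
#'   percentages), keyed by section label.
#' @param partition a [SectionPartition-class].
#' @param K number of sectors for the overview (default 360).
#' @return A [SectorProfile-class] of fibrosis percentages in the histology
#'   frame.
#' @examples
#' part <- equalPartition(4)
#' prof <- buildOverview(list(S1 = 10, S2 = 20, S3 = 30, S4 = 40), part)
#' profileValues(prof)[c(1, 91, 181, 271)]
#' @export
buildOverview <- function(fractions, partition, K = 360L) {
  validObject(partition)
  missing <- setdiff(partition@labels, names(fractions))
  if (length(missing))
    stop("no fibrosis record for section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  pct <- vapply(partition@labels, function(lb) {
    f <- fractions[[lb]]
    if (is(f, "TissueFractions")) f@connectivePct else as.numeric(f)
  }, numeric(1))

  sectorStart <- (seq_len(K) - 1) * (360 / K)
  vals <- rep(NA_real_, K)
  for (i in seq_along(partition@labels)) {
    d <- normDeg(sectorStart - partition@startDeg[i])
    width <- partition@endDeg[i] - partition@startDeg[i]
    vals[d < width - 1e-9 | d > 360 - 1e-9] <- pct[i]
  }
  SectorProfile(vals, quantity = "fibrosis", units = "%",
                frameTag = "histology")
}
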