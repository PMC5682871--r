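# Synthetic trichrome-style section images: three tissue classes drawn
# i.i.d. per pixel and rendered as distinct stain colours with a small
# seeded jitter, with the true class labels recorded as ground truth.

# nominal stain colours (RGB in [0,1]): collagen blue, cardiomyocyte red,
# adipose/non-stained cytoplasm pseudo-green (deliberately low saturation)
.stainColors <- rbind(
  connective = c(0.25, 0.35, 0.75),
  myocyte    = c(0.78, 0.22, 0.28),
  adipose    = c(0.63, 0.76, 0.62)
)

#' Generate a synthetic trichrome section image with known class fractions
#'
#' Tissue pixels are assigned to the connective (blue), adipose
#' (pseudo-green) and cardiomyocyte (red) classes i.i.d. with probabilities
#' `(fibrosisFrac, adiposeFrac, 1 - fibrosisFrac - adiposeFrac)`, rendered
#' as distinct stain colours with a small seeded per-pixel colour jitter.
#' The realised per-image class fractions are recorded as ground truth.
#'
#' @param fibrosisFrac,adiposeFrac class probabilities in `[0, 1]` with
#'   `fibrosisFrac + adiposeFrac <= 1`.
#' @param sizePx integer pair, image size in pixels.
#' @param seed integer RNG seed.
#' @param tissueMask optional logical matrix; non-tissue pixels are rendered
#'   near-white and excluded from the ground truth.
#' @param sectionLabel identifier stored on the image.
#' @param jitter half-width of the uniform per-channel colour jitter.
#' @return A [HistoSectionImage-class]; `groundTruth` holds `labels`
#'   (integer matrix: 1 connective, 2 myocyte, 3 adipose, NA non-tissue),
#'   `fractions` (realised class fractions) and the requested probabilities.
#' @examples
#' img <- generateHistologyImage(0.3, 0.05, c(60, 60), seed = 7)
#' img
#' @export
generateHistologyImage <- function(fibrosisFrac, adiposeFrac = 0,
                                   sizePx = c(100L, 100L), seed = 1L,
                                   tissueMask = NULL, sectionLabel = "S1",
                                   jitter = 0.04) {
  if (fibrosisFrac < 0 || adiposeFrac < 0 || fibrosisFrac + adiposeFrac > 1)
    failField("fibrosisFrac/adiposeFrac",
              "must be nonnegative and sum to at most 1")
  rows <- sizePx[1]; cols <- sizePx[2]
  if (is.null(tissueMask)) tissueMask <- matrix(TRUE, rows, cols)
  nTis <- sum(tissueMask)
  if (nTis < 1) failField("tissueMask", "must contain at least one pixel")

  withSeed(seed, {
    cls <- sample.int(3L, nTis, replace = TRUE,
                      prob = c(fibrosisFrac, 1 - fibrosisFrac - adiposeFrac,
                               adiposeFrac))
    labels <- matrix(NA_integer_, rows, cols)
    labels[tissueMask] <- cls
    rgb <- array(0.97, dim = c(rows, cols, 3))  # background near-white
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[tissueMask] <- .stainColors[cls, ch] +
        stats::runif(nTis, -jitter, jitter)
      rgb[, , ch] <- pmin(1, pmax(0, plane))
    }
    counts <- tabulate(cls, nbins = 3L)
    HistoSectionImage(
      rgb, tissueMask, sectionLabel,
      groundTruth = list(
        labels = labels,
        fractions = c(connective = counts[1] / nTis,
                      myocyte = counts[2] / nTis,
                      adipose = counts[3] / nTis),
        requested = c(fibrosisFrac = fibrosisFrac, adiposeFrac = adiposeFrac),
        seed = as.integer(seed)))
  })
}
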