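# Plain-format readers/writers: contours as JSON, profiles and section
# tables as CSV, intensity grids as float TIFF (with a JSON sidecar carrying
# the physical scale), histology images as PNG, partitions and landmark
# frames as JSON, run manifests as YAML.

#' Write / read cine contours as JSON
#'
#' Per frame, ordered angle/radius pairs (degrees / mm) for the endo- and
#' epicardial contours, plus the LV centre and ED/ES frame indices.
#'
#' @param geom a [SliceGeometry-class].
#' @param path output file.
#' @return `writeContours` returns `path` invisibly; `readContours` a
#'   [SliceGeometry-class].
#' @export
writeContours <- function(geom, path) {
  validObject(geom)
  obj <- list(center_xy_mm = geom@centerXyMm,
              theta_deg = geom@thetaDeg,
              ed_frame = geom@edFrame, es_frame = geom@esFrame,
              frames = lapply(seq_len(geometryFrames(geom)), function(f) {
                list(endo_mm = geom@endoMm[f, ], epi_mm = geom@epiMm[f, ])
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeContours
#' @export
readContours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  endo <- do.call(rbind, lapply(obj$frames$endo_mm, as.numeric))
  epi <- do.call(rbind, lapply(obj$frames$epi_mm, as.numeric))
  if (is.null(endo)) {  # single-frame layout
    endo <- matrix(as.numeric(obj$frames[[1]]$endo_mm), nrow = 1)
    epi <- matrix(as.numeric(obj$frames[[1]]$epi_mm), nrow = 1)
  }
  SliceGeometry(obj$center_xy_mm, obj$theta_deg, endo, epi,
                edFrame = obj$ed_frame,
                esFrame = if (is.null(obj$es_frame)) NA_integer_ else obj$es_frame)
}

#' Write / read a sector profile as CSV
#'
#' Columns `sector_index,value`; metadata tags travel in a comment-free
#' header pair of pseudo-columns on read arguments instead.
#'
#' @param profile a [SectorProfile-class].
#' @param path file path.
#' @param quantity,units,frameTag metadata applied on read.
#' @return `writeSectorProfile` returns `path` invisibly;
#'   `readSectorProfile` a [SectorProfile-class].
#' @export
writeSectorProfile <- function(profile, path) {
  utils::write.csv(data.frame(sector_index = seq_len(nSectors(profile)),
                              value = profileValues(profile)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSectorProfile
#' @export
readSectorProfile <- function(path, quantity = "value", units = "",
                              frameTag = "cmr") {
  df <- utils::read.csv(path)
  SectorProfile(df$value[order(df$sector_index)], quantity, units, frameTag)
}

#' Write / read an intensity grid as float TIFF
#'
#' TIFF float samples live in `[0, 1]`, so the grid is stored divided by a
#' scale written to a JSON sidecar (`<path>.json`) together with the pixel
#' spacing; reading restores the physical values and mask (mask stored as a
#' second PNG when requested).
#'
#' @param img an [IntensityImage-class].
#' @param path output `.tif` path; the sidecar is `<path>.json` and the
#'   myocardial mask `<path>.mask.png`.
#' @return `writeIntensityImage` returns `path` invisibly;
#'   `readIntensityImage` an [IntensityImage-class].
#' @export
writeIntensityImage <- function(img, path) {
  validObject(img)
  scale <- max(img@pixels, 1e-12)
  tiff::writeTIFF(img@pixels / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale,
                            pixel_spacing_mm = img@pixelSpacingMm),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  png::writePNG(img@myoMask * 1, paste0(path, ".mask.png"))
  invisible(path)
}

#' @rdname writeIntensityImage
#' @export
readIntensityImage <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * meta$scale
  mask <- png::readPNG(paste0(path, ".mask.png")) > 0.5
  IntensityImage(px, meta$pixel_spacing_mm, mask)
}

#' Write / read a histology section image as PNG
#'
#' The tissue mask is stored alongside as `<path>.mask.png`. On read the
#' image can be downscaled (plain subsampling) to a maximum dimension, as
#' whole-slide exports are analysed at reduced resolution (the emulated
#' workflow resized to 10 percent); class fractions are scale-invariant.
#'
#' @param img a [HistoSectionImage-class].
#' @param path output `.png` path.
#' @param maxDim on read, subsample so no dimension exceeds this (default
#'   `Inf`: native resolution).
#' @param sectionLabel label applied on read.
#' @return `writeHistoImage` returns `path` invisibly; `readHistoImage` a
#'   [HistoSectionImage-class].
#' @export
writeHistoImage <- function(img, path) {
  validObject(img)
  png::writePNG(img@rgb, path)
  png::writePNG(img@tissueMask * 1, paste0(path, ".mask.png"))
  invisible(path)
}

#' @rdname writeHistoImage
#' @export
readHistoImage <- function(path, maxDim = Inf, sectionLabel = "S1") {
  rgb <- png::readPNG(path)
  if (length(dim(rgb)) == 3 && dim(rgb)[3] > 3) rgb <- rgb[, , 1:3]
  maskPath <- paste0(path, ".mask.png")
  mask <- if (file.exists(maskPath)) png::readPNG(maskPath) > 0.5 else NULL
  if (is.finite(maxDim) && max(dim(rgb)[1:2]) > maxDim) {
    step <- ceiling(max(dim(rgb)[1:2]) / maxDim)
    ri <- seq(1, dim(rgb)[1], by = step)
    ci <- seq(1, dim(rgb)[2], by = step)
    rgb <- rgb[ri, ci, , drop = FALSE]
    if (!is.null(mask)) mask <- mask[ri, ci, drop = FALSE]
  }
  HistoSectionImage(rgb, mask, sectionLabel = sectionLabel)
}

#' Write / read a section partition as JSON
#'
#' A list of `{label, start_deg, end_deg}` plus the landmark angle.
#'
#' @param partition a [SectionPartition-class].
#' @param path file path.
#' @return `writePartition` returns `path` invisibly; `readPartition` a
#'   [SectionPartition-class].
#' @export
writePartition <- function(partition, path) {
  validObject(partition)
  obj <- list(landmark_angle_deg = partition@landmarkAngleDeg,
              sections = lapply(seq_along(partition@labels), function(i) {
                list(label = partition@labels[i],
                     start_deg = partition@startDeg[i],
                     end_deg = partition@endDeg[i])
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  SectionPartition(obj$sections$label, obj$sections$start_deg,
                   obj$sections$end_deg, obj$landmark_angle_deg)
}

#' Write / read a landmark frame as JSON
#' @param frame a [LandmarkFrame-class].
#' @param path file path.
#' @return `writeLandmarkFrame` returns `path` invisibly;
#'   `readLandmarkFrame` a [LandmarkFrame-class].
#' @export
writeLandmarkFrame <- function(frame, path) {
  jsonlite::write_json(list(center_mm = frame@centerXyMm,
                            reference_angle_deg = frame@referenceAngleDeg,
                            source = frame@sourceTag),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLandmarkFrame
#' @export
readLandmarkFrame <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  LandmarkFrame(obj$center_mm, obj$reference_angle_deg, obj$source)
}

#' Write / read the cohort section table as CSV
#' @param table a section-table `data.frame`.
#' @param path file path.
#' @return `writeSectionTable` returns `path` invisibly;
#'   `readSectionTable` the `data.frame`.
#' @export
writeSectionTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSectionTable
#' @export
readSectionTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
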