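# Wall-thickening and contour-geometric strain from cine contour series.
# Radial quantities are measured along rays from the fixed LV centre;
# circumferential strain uses midwall arc length with end-diastole as the
# reference phase (Lagrangian convention: shortening negative).

#' Sector-averaged wall thickness of one frame
#'
#' Per sector, the mean over the sector's angular samples of
#' `epi(theta) - endo(theta)`, radii measured from the LV centre, in mm.
#'
#' @param geom a [SliceGeometry-class].
#' @param frame 1-based frame index.
#' @param K number of equal sectors (study export: 60).
#' @return A [SectorProfile-class] of wall thickness (mm).
#' @examples
#' geom <- simulateCine(PhantomSpec(nFrames = 3))
#' wallThicknessProfile(geom, 1, K = 6)
#' @export
wallThicknessProfile <- function(geom, frame, K = 60L) {
  validObject(geom)
  if (frame < 1 || frame > geometryFrames(geom))
    stop("frame ", frame, " out of range 1..", geometryFrames(geom),
         call. = FALSE)
  wt <- geom@epiMm[frame, ] - geom@endoMm[frame, ]
  idx <- sectorIndexDeg(geom@thetaDeg, K)
  vals <- as.numeric(tapply(wt, factor(idx, levels = seq_len(K)), mean))
  SectorProfile(vals, quantity = "wall thickness", units = "mm")
}

# frame of minimal endocardial cavity area
locateEndSystole <- function(geom) {
  areas <- vapply(seq_len(geometryFrames(geom)),
                  function(f) cavityAreaMm2(geom, f), numeric(1))
  if (max(areas) - min(areas) < 1e-12) {
    warning("all frames have identical cavity area; using the last frame")
    return(geometryFrames(geom))
  }
  which.min(areas)
}

#' End-systolic wall thickness
#'
#' Wall thickness profile at end-systole. If the geometry does not declare
#' an end-systolic frame, it is located as the frame of minimal endocardial
#' cavity area.
#'
#' @inheritParams wallThicknessProfile
#' @return A [SectorProfile-class] of end-systolic wall thickness (mm).
#' @export
endSystolicWT <- function(geom, K = 60L) {
  validObject(geom)
  if (geometryFrames(geom) < 2)
    stop("end-systolic analysis needs at least 2 frames", call. = FALSE)
  es <- if (!is.na(geom@esFrame)) geom@esFrame else locateEndSystole(geom)
  wallThicknessProfile(geom, es, K)
}

#' Circumferential and radial strain profiles at end-systole
#'
#' Contour-geometric strain with the end-diastolic frame as the reference
#' phase, per sector: circumferential strain
#' `ecc = 100 * (L_es - L_ed) / L_ed` where `L` is the sector's midwall arc
#' length (midwall radius `(endo + epi) / 2`); radial strain
#' `err = 100 * (T_es - T_ed) / T_ed` where `T` is the sector mean wall
#' thickness; and the end-systolic wall thickness itself. Shortening is
#' negative and thickening positive (Lagrangian convention).
#'
#' @param geom a [SliceGeometry-class] with at least 2 frames.
#' @param K number of equal sectors (study export: 48).
#' @return A list of three [SectorProfile-class] objects: `ecc` (%), `err`
#'   (%), `wtFt` (mm).
#' @examples
#' geom <- simulateCine(PhantomSpec(nFrames = 5))
#' st <- strainProfiles(geom, K = 8)
#' profileValues(st$ecc)
#' @export
strainProfiles <- function(geom, K = 48L) {
  validObject(geom)
  if (geometryFrames(geom) < 2)
    stop("strain needs at least 2 frames", call. = FALSE)
  ed <- geom@edFrame
  es <- if (!is.na(geom@esFrame)) geom@esFrame else locateEndSystole(geom)

  th <- geom@thetaDeg
  dthRad <- diff(c(th, th[1] + 360)) * pi / 180
  idx <- factor(sectorIndexDeg(th, K), levels = seq_len(K))

  arcLen <- function(frame) {
    rmid <- (geom@endoMm[frame, ] + geom@epiMm[frame, ]) / 2
    as.numeric(tapply(rmid * dthRad, idx, sum))
  }
  meanWT <- function(frame) {
    as.numeric(tapply(geom@epiMm[frame, ] - geom@endoMm[frame, ], idx, mean))
  }

  Led <- arcLen(ed); Les <- arcLen(es)
  Ted <- meanWT(ed); Tes <- meanWT(es)
  if (any(Led <= 0)) stop("end-diastolic arc length is zero", call. = FALSE)
  if (any(Ted <= 0)) stop("end-diastolic wall thickness is zero", call. = FALSE)

  list(ecc = SectorProfile(100 * (Les - Led) / Led,
                           quantity = "circumferential strain", units = "%"),
       err = SectorProfile(100 * (Tes - Ted) / Ted,
                           quantity = "radial strain", units = "%"),
       wtFt = SectorProfile(Tes, quantity = "wall thickness (FT)",
                            units = "mm"))
}

#' Average a sector profile over histology sections
#'
#' Per section, the angular-overlap-weighted mean of the sector values whose
#' spans intersect the section span; the weights over a section sum to the
#' section's angular width, so the span-weighted mean of the section values
#' equals the profile mean. The profile must already be registered to the
#' partition's angular frame.
#'
#' Sectors flagged missing (`NA`, e.g. wedges without myocardial pixels)
#' are dropped from the weighting; a section whose sectors are all missing
#' yields `NA`.
#'
#' @param profile a [SectorProfile-class] in the partition's frame.
#' @param partition a [SectionPartition-class].
#' @return A named numeric vector, one value per section label.
#' @examples
#' prof <- SectorProfile(1:8, frameTag = "histology")
#' averageToSections(prof, equalPartition(4))
#' @export
averageToSections <- function(profile, partition) {
  validObject(profile); validObject(partition)
  K <- nSectors(profile)
  w <- 360 / K
  sectorStart <- (seq_len(K) - 1) * w
  out <- vapply(seq_along(partition@labels), function(i) {
    ov <- vapply(seq_len(K), function(k) {
      circOverlapDeg(sectorStart[k], sectorStart[k] + w,
                     partition@startDeg[i], partition@endDeg[i])
    }, numeric(1))
    if (sum(ov) <= 0) stop("section ", partition@labels[i],
                           " intersects no sector", call. = FALSE)
    v <- profileValues(profile)
    ok <- !is.na(v)
    if (!any(ok & ov > 0)) return(NA_real_)
    sum(ov[ok] * v[ok]) / sum(ov[ok])
  }, numeric(1))
  names(out) <- partition@labels
  out
}
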