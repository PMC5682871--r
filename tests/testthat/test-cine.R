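# Wall thickening, strain and section averaging on contour geometry.

test_that("circular annulus gives uniform wall thickness in every sector", {
  geom <- circleGeometry(20, 30)
  prof <- wallThicknessProfile(geom, 1, K = 60)
  expect_equal(profileValues(prof), rep(10, 60))
  expect_equal(profileValues(wallThicknessProfile(geom, 1, K = 1)), 10)
  expect_error(wallThicknessProfile(geom, 3), "out of range")
})

test_that("sector wall thickness matches dense-ray sampling on an ellipse", {
  th <- seq(0, 360 - 0.1, by = 0.1)
  a <- 32; b <- 28
  epiF <- function(t) a * b / sqrt((b * cos(t * pi / 180))^2 +
                                     (a * sin(t * pi / 180))^2)
  geom <- SliceGeometry(c(0, 0), th, rep(20, length(th)), epiF(th))
  prof <- profileValues(wallThicknessProfile(geom, 1, K = 60))
  dense <- seq(0, 360 - 0.036, by = 0.036)  # 10^4 rays
  oracle <- as.numeric(tapply(epiF(dense) - 20, floor(dense / 6), mean))
  expect_lt(max(abs(prof - oracle)), 0.01)
})

test_that("end-systole defaults to the minimal cavity-area frame", {
  spec <- PhantomSpec(thickeningHealthyMm = 4, thickeningScarMm = 4,
                      endoRadiusMm = 20, epiRadiusMm = 30, nFrames = 6)
  geom <- simulateCine(spec)
  geomNoEs <- SliceGeometry(geom@centerXyMm, geom@thetaDeg, geom@endoMm,
                            geom@epiMm, edFrame = 1L)  # esFrame unset
  expect_equal(profileValues(endSystolicWT(geomNoEs, K = 10)), rep(14, 10))
  # explicit index wins
  g2 <- circleGeometry(20, 30, endoEs = 18, epiEs = 30)
  expect_equal(profileValues(endSystolicWT(g2, K = 4)), rep(12, 4))
  # degenerate: identical frames -> last frame with a warning
  g3 <- circleGeometry(20, 30, endoEs = 20, epiEs = 30)
  g3 <- SliceGeometry(g3@centerXyMm, g3@thetaDeg, g3@endoMm, g3@epiMm)
  expect_warning(endSystolicWT(g3, K = 4), "identical")
})

test_that("akinetic scar keeps end-systolic WT at its diastolic value", {
  spec <- PhantomSpec(thickeningScarMm = 0, nFrames = 8)
  geom <- simulateCine(spec, borderDeg = 10)
  es <- profileValues(endSystolicWT(geom, K = 360))
  ed <- profileValues(wallThicknessProfile(geom, 1, K = 360))
  centerSector <- fibroCMR:::sectorIndexDeg(spec@scarCenterDeg, 360)
  expect_equal(es[centerSector], ed[centerSector], tolerance = 1e-10)
})

test_that("zero motion yields exactly zero strain", {
  geom <- circleGeometry(20, 30, endoEs = 20, epiEs = 30)
  st <- strainProfiles(geom, K = 12)
  expect_equal(profileValues(st$ecc), rep(0, 12))
  expect_equal(profileValues(st$err), rep(0, 12))
})

test_that("uniform contraction reproduces the closed-form strains", {
  # midwall 25 -> 20 mm, thickness 10 -> 12 mm
  geom <- circleGeometry(20, 30, endoEs = 14, epiEs = 26)
  st <- strainProfiles(geom, K = 8)
  expect_equal(profileValues(st$ecc), rep(-20, 8), tolerance = 1e-10)
  expect_equal(profileValues(st$err), rep(20, 8), tolerance = 1e-10)
  expect_equal(profileValues(st$wtFt), rep(12, 8), tolerance = 1e-10)
})

test_that("akinetic scar shows less radial strain than remote sectors", {
  spec <- PhantomSpec(thickeningScarMm = 0, nFrames = 8)
  geom <- simulateCine(spec, borderDeg = 10)
  st <- strainProfiles(geom, K = 48)
  centers <- ((seq_len(48) - 1) + 0.5) * 7.5
  inScar <- fibroCMR:::circDistDeg(centers, spec@scarCenterDeg) <
    spec@scarWidthDeg / 2 - 7.5
  remote <- fibroCMR:::circDistDeg(centers, spec@scarCenterDeg) >
    spec@scarWidthDeg / 2 + 20
  expect_true(max(abs(profileValues(st$err)[inScar])) <
                min(abs(profileValues(st$err)[remote])))
})

test_that("section averaging preserves constants and global means", {
  part <- equalPartition(4)
  const <- SectorProfile(rep(3.5, 60), frameTag = "histology")
  expect_equal(unname(averageToSections(const, part)), rep(3.5, 4))
  prof <- SectorProfile(sin(1:360 / 20) + 2, frameTag = "histology")
  sec <- averageToSections(prof, part)
  # brute-force block means over each 90-sector block
  oracle <- vapply(1:4, function(i) {
    mean(profileValues(prof)[((i - 1) * 90 + 1):(i * 90)])
  }, numeric(1))
  expect_equal(unname(sec), oracle, tolerance = 1e-12)
  # span-weighted conservation identity
  expect_equal(mean(sec), mean(profileValues(prof)), tolerance = 1e-12)
})

test_that("missing sectors are dropped from section averages", {
  v <- rep(5, 360); v[10:20] <- NA
  sec <- averageToSections(SectorProfile(v, frameTag = "histology"),
                           equalPartition(4))
  expect_equal(unname(sec), rep(5, 4))
})
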