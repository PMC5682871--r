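# Landmark computation and rotational registration of sector profiles.

test_that("mid-lateral landmark is opposite the RV hinge points", {
  expect_equal(midlateralAngle(150, 210), 0)
  expect_equal(midlateralAngle(210, 150), 0)  # order-invariant
  expect_equal(midlateralAngle(120, 240), 0)
  expect_equal(midlateralAngle(30, 90), 240)
  expect_error(midlateralAngle(45, 45), "coincide")
  expect_error(midlateralAngle(90, 270), "ambiguous")
})

test_that("landmark keeps at least 90 degrees from both hinges", {
  set.seed(9)
  for (i in 1:50) {
    a <- runif(1, 0, 360)
    sep <- runif(1, 10, 170)   # minor arc < 180
    b <- fibroCMR:::normDeg(a + sep)
    lm <- midlateralAngle(a, b)
    expect_gte(fibroCMR:::circDistDeg(lm, a), 90)
    expect_gte(fibroCMR:::circDistDeg(lm, b), 90)
  }
})

test_that("zero and full-turn rotations are the identity", {
  p <- SectorProfile(runif(48), frameTag = "cmr")
  f0 <- LandmarkFrame(referenceAngleDeg = 10)
  expect_equal(profileValues(rotateProfile(p, f0, f0)), profileValues(p))
  f360 <- LandmarkFrame(referenceAngleDeg = 10 + 360)
  expect_equal(profileValues(rotateProfile(p, f0, f360)), profileValues(p))
})

test_that("integer-sector shifts relabel exactly and compose additively", {
  v <- runif(60)
  p <- SectorProfile(v)
  fA <- LandmarkFrame(referenceAngleDeg = 0)
  fB <- LandmarkFrame(referenceAngleDeg = 36)   # 6 sectors of 60
  fC <- LandmarkFrame(referenceAngleDeg = 90)   # 15 sectors
  ab <- rotateProfile(p, fA, fB)
  expect_equal(profileValues(ab), v[c(55:60, 1:54)])
  composed <- rotateProfile(ab, fB, fC)
  direct <- rotateProfile(p, fA, fC)
  expect_equal(profileValues(composed), profileValues(direct))
  expect_equal(mean(profileValues(direct)), mean(v))
})

test_that("fractional shifts round-trip to 1e-9 on band-limited profiles", {
  th <- 2 * pi * (0:359) / 360
  v <- 3 + sin(th) + 0.5 * cos(7 * th) + 0.2 * sin(23 * th)
  p <- SectorProfile(v)
  fA <- LandmarkFrame(referenceAngleDeg = 0)
  fB <- LandmarkFrame(referenceAngleDeg = 37.5)  # 37.5 sectors
  there <- rotateProfile(p, fA, fB)
  back <- rotateProfile(there, fB, fA)
  expect_lt(max(abs(profileValues(back) - v)), 1e-9)
  expect_equal(mean(profileValues(there)), mean(v), tolerance = 1e-12)
})

test_that("a known rotation lands the scar at its histology angle", {
  # scar centred 73 degrees past the landmark must appear at 73 in the
  # registered frame regardless of the acquisition rotation
  for (rot in c(0, 38.2, 211)) {
    spec <- noiselessSpec(scarCenterDeg = 73 + rot,
                          rvHingeAnglesDeg = c(120, 240) + rot,
                          scarTransmuralityFrac = 1)
    ph <- generatePhantomSlice(spec)
    lm <- midlateralAngle(spec@rvHingeAnglesDeg[1], spec@rvHingeAnglesDeg[2])
    expect_equal(lm, fibroCMR:::normDeg(rot))
    tm <- transmuralityProfile(fwhmMask(ph$lge), ph$geometry, 360)
    reg <- rotateProfile(tm, LandmarkFrame(spec@centerXyMm, lm, "cmr"),
                         LandmarkFrame(spec@centerXyMm, 0, "histology"),
                         method = "linear")
    v <- profileValues(reg)
    scarSectors <- which(!is.na(v) & v > 50)
    centers <- scarSectors - 0.5
    # circular mean of the recovered scar sectors
    cm <- fibroCMR:::normDeg(atan2(mean(sin(centers * pi / 180)),
                                   mean(cos(centers * pi / 180))) * 180 / pi)
    expect_lt(fibroCMR:::circDistDeg(cm, 73), 3)
  }
})

test_that("linear and nearest interpolation stay within the profile range", {
  v <- c(rep(0, 20), rep(100, 10), rep(0, 6))
  p <- SectorProfile(v)
  fA <- LandmarkFrame(referenceAngleDeg = 0)
  fB <- LandmarkFrame(referenceAngleDeg = 4.7)
  for (m in c("linear", "nearest")) {
    r <- profileValues(rotateProfile(p, fA, fB, method = m))
    expect_true(all(r >= 0 & r <= 100))
  }
})
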