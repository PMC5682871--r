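# LGE scar delineation, transmurality and signal-intensity exports.

test_that("FWHM threshold is half the seed-region maximum", {
  ph <- generatePhantomSlice(noiselessSpec())
  m <- fwhmMask(ph$lge)
  expect_equal(scarThreshold(m), 0.5 * max(ph$lge@pixels[ph$lge@myoMask]))
  expect_equal(scarMethod(m), "FWHM")
  # recovered scar equals the generated wedge (noiseless, 2x threshold gap)
  truthWedge <- ph$fibrosis@pixels > noiselessSpec()@remoteFibrosisFrac
  expect_identical(unname(m@scar), unname(truthWedge))
})

test_that("uniform myocardium makes the whole wall FWHM-positive", {
  px <- matrix(10, 32, 32)
  myo <- matrix(FALSE, 32, 32); myo[10:20, 10:20] <- TRUE
  img <- IntensityImage(px, 1, myo)
  m <- fwhmMask(img)
  expect_equal(scarThreshold(m), 5)
  expect_identical(m@scar, myo)   # >= rule includes the boundary
})

test_that("scar intensity exactly twice remote is included by the >= rule", {
  spec <- noiselessSpec(lgeScarIntensity = 40, lgeRemoteIntensity = 20,
                        scarTransmuralityFrac = 1)
  ph <- generatePhantomSlice(spec)
  m <- fwhmMask(ph$lge)
  expect_equal(scarThreshold(m), 20)
  expect_identical(m@scar, ph$lge@myoMask)  # remote sits at the threshold
})

test_that("SD-from-remote threshold is mean plus n population SDs", {
  px <- matrix(0, 20, 20)
  myo <- matrix(TRUE, 20, 20)
  remote <- matrix(FALSE, 20, 20); remote[1, 1:4] <- TRUE
  px[1, 1:4] <- c(8, 12, 8, 12)  # mean 10, population SD 2
  img <- IntensityImage(px, 1, myo)
  m <- sdRemoteMask(img, remote, 5)
  expect_equal(scarThreshold(m), 20)
  expect_equal(scarMethod(m), "SD5")
  # zero-variance remote is valid: threshold collapses to the mean
  px[1, 1:4] <- 7
  m0 <- sdRemoteMask(IntensityImage(px, 1, myo), remote, 3)
  expect_equal(scarThreshold(m0), 7)
  expect_error(sdRemoteMask(img, matrix(FALSE, 20, 20), 2), "2 pixels")
})

test_that("2SD mask covers the scar and false positives follow the Gaussian tail", {
  spec <- PhantomSpec(noiseSd = 2, lgeRemoteIntensity = 20,
                      lgeScarIntensity = 100, seed = 5)
  ph <- generatePhantomSlice(spec)
  pol <- fibroCMR:::pixelPolar(spec@imageSizePx, spec@pixelSpacingMm,
                               spec@centerXyMm)
  remoteBand <- ph$lge@myoMask &
    fibroCMR:::circDistDeg(pol$theta, spec@scarCenterDeg) > 120
  m <- sdRemoteMask(ph$lge, remoteBand, 2)
  trueScar <- ph$fibrosis@pixels > spec@remoteFibrosisFrac
  expect_gte(sum(m@scar), sum(trueScar))
  # false-positive rate over remote myocardium outside the wedge
  remoteAll <- ph$lge@myoMask & !trueScar
  fp <- mean(m@scar[remoteAll])
  p <- pnorm(2, lower.tail = FALSE)
  expect_lt(abs(fp - p), 3 * sqrt(p * (1 - p) / sum(remoteAll)) + 0.01)
})

test_that("SD masks nest with increasing stringency on noisy phantoms", {
  for (spec in randomSpecs(6, seed = 55)) {
    ph <- generatePhantomSlice(spec)
    pol <- fibroCMR:::pixelPolar(spec@imageSizePx, spec@pixelSpacingMm,
                                 spec@centerXyMm)
    remote <- ph$lge@myoMask &
      fibroCMR:::circDistDeg(pol$theta, spec@scarCenterDeg) > 120
    m2 <- sdRemoteMask(ph$lge, remote, 2)
    m3 <- sdRemoteMask(ph$lge, remote, 3)
    m5 <- sdRemoteMask(ph$lge, remote, 5)
    expect_true(all(m5@scar <= m3@scar))
    expect_true(all(m3@scar <= m2@scar))
  }
})

test_that("manual correction subtracts regions and tags the method", {
  ph <- generatePhantomSlice(PhantomSpec(noiseSd = 3, seed = 8))
  m <- fwhmMask(ph$lge)
  none <- applyManualCorrection(m, matrix(FALSE, 128, 128))
  expect_identical(none@scar, m@scar)
  expect_equal(scarMethod(none), "FWHMm")
  all <- applyManualCorrection(m, matrix(TRUE, 128, 128))
  expect_equal(sum(all@scar), 0)
  # excluding everything outside the true wedge leaves a subset of truth
  truth <- ph$fibrosis@pixels > PhantomSpec()@remoteFibrosisFrac
  corr <- applyManualCorrection(m, !truth)
  expect_true(all(corr@scar <= truth))
})

test_that("%TM equals the brute-force per-pixel tally exactly", {
  for (spec in randomSpecs(3, seed = 77)) {
    ph <- generatePhantomSlice(spec)
    m <- fwhmMask(ph$lge)
    tm <- profileValues(transmuralityProfile(m, ph$geometry, 360))
    expect_equal(tm, bruteForceTM(m, spec@centerXyMm, 360))
  }
})

test_that("%TM hits 100 in fully scarred wedges and 0 with empty masks", {
  spec <- noiselessSpec(scarTransmuralityFrac = 1)
  ph <- generatePhantomSlice(spec)
  m <- fwhmMask(ph$lge)
  tm <- profileValues(transmuralityProfile(m, ph$geometry, 36))
  centerSector <- fibroCMR:::sectorIndexDeg(spec@scarCenterDeg, 36)
  expect_equal(tm[centerSector], 100)
  empty <- applyManualCorrection(m, matrix(TRUE, 128, 128))
  tm0 <- profileValues(transmuralityProfile(empty, ph$geometry, 36))
  expect_true(all(tm0[!is.na(tm0)] == 0))
  expect_true(all(tm[!is.na(tm)] >= 0 & tm[!is.na(tm)] <= 100))
})

test_that("MSI reproduces uniform and two-level intensity patterns", {
  px <- matrix(7, 64, 64)
  pol <- fibroCMR:::pixelPolar(c(64, 64), 1.5, c(48, 48))
  myo <- pol$r >= 20 & pol$r <= 30
  img <- IntensityImage(px, 1.5, myo)
  geom <- circleGeometry(20, 30, center = c(48, 48))
  msi <- profileValues(msiProfile(img, geom, 36))
  expect_true(all(msi[!is.na(msi)] == 7))
  # two-level phantom: scar-centre and far-remote sectors read their levels
  spec <- noiselessSpec(scarTransmuralityFrac = 1)
  ph <- generatePhantomSlice(spec)
  msi2 <- profileValues(msiProfile(ph$lge, ph$geometry, 36))
  centerSector <- fibroCMR:::sectorIndexDeg(spec@scarCenterDeg, 36)
  oppSector <- fibroCMR:::sectorIndexDeg(spec@scarCenterDeg + 180, 36)
  expect_equal(msi2[oppSector], spec@lgeRemoteIntensity)
  expect_equal(msi2[centerSector], spec@lgeScarIntensity)
})
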