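# Synthetic phantom: rasterisation, fibrosis/LGE fields, cine motion.

test_that("phantom spec validation names the violated field", {
  expect_error(PhantomSpec(endoRadiusMm = -1), "endoRadiusMm")
  expect_error(PhantomSpec(endoRadiusMm = 30, epiRadiusMm = 20),
               "epiRadiusMm")
  expect_error(PhantomSpec(scarWidthDeg = 0), "scarWidthDeg")
  expect_error(PhantomSpec(lgeScarIntensity = 10, lgeRemoteIntensity = 20),
               "lgeScarIntensity")
  expect_error(PhantomSpec(nFrames = 1), "nFrames")
})

test_that("noiseless fully transmural scar renders at the scar intensity", {
  spec <- noiselessSpec(scarTransmuralityFrac = 1, scarFibrosisFrac = 1)
  ph <- generatePhantomSlice(spec)
  pol <- fibroCMR:::pixelPolar(spec@imageSizePx, spec@pixelSpacingMm,
                               spec@centerXyMm)
  wedge <- ph$lge@myoMask &
    fibroCMR:::inWedgeDeg(pol$theta, spec@scarCenterDeg, spec@scarWidthDeg)
  expect_true(all(ph$lge@pixels[wedge] == spec@lgeScarIntensity))
  expect_true(all(ph$lge@pixels[ph$lge@myoMask & !wedge] ==
                    spec@lgeRemoteIntensity))
})

test_that("scar pixel count matches the analytic wedge-annulus area", {
  spec <- noiselessSpec(scarWidthDeg = 90, scarTransmuralityFrac = 0.5)
  ph <- generatePhantomSlice(spec)
  nScar <- sum(ph$fibrosis@pixels > spec@remoteFibrosisFrac)
  rOut <- spec@endoRadiusMm +
    0.5 * (spec@epiRadiusMm - spec@endoRadiusMm)
  areaMm2 <- (90 / 360) * pi * (rOut^2 - spec@endoRadiusMm^2)
  expected <- areaMm2 / spec@pixelSpacingMm^2
  # rasterisation tolerance: boundary pixels scale with the wedge perimeter
  perimPx <- (2 * (rOut - spec@endoRadiusMm) + 2 * (pi / 2) * rOut) /
    spec@pixelSpacingMm
  expect_lt(abs(nScar - expected), perimPx)
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- PhantomSpec(noiseSd = 4, seed = 99L)
  a <- generatePhantomSlice(spec)
  b <- generatePhantomSlice(spec)
  expect_identical(a$lge@pixels, b$lge@pixels)
  expect_identical(a$fibrosis@pixels, b$fibrosis@pixels)
})

test_that("zero thickening leaves all cine frames identical", {
  spec <- PhantomSpec(thickeningHealthyMm = 0, thickeningScarMm = 0,
                      nFrames = 5)
  geom <- simulateCine(spec)
  for (f in 2:5) expect_equal(geom@endoMm[f, ], geom@endoMm[1, ])
  expect_equal(geom@epiMm[5, ], geom@epiMm[1, ])
})

test_that("uniform thickening adds exactly the configured millimetres", {
  spec <- PhantomSpec(thickeningHealthyMm = 4, thickeningScarMm = 4,
                      endoRadiusMm = 20, epiRadiusMm = 30)
  geom <- simulateCine(spec)
  es <- geometryFrames(geom)
  wt <- geom@epiMm[es, ] - geom@endoMm[es, ]
  expect_equal(wt, rep(14, length(wt)), tolerance = 1e-12)
})

test_that("akinetic scar depresses end-systolic wall thickness in the wedge", {
  spec <- PhantomSpec(thickeningScarMm = 0, nFrames = 10)
  geom <- simulateCine(spec)
  es <- geometryFrames(geom)
  wt <- geom@epiMm[es, ] - geom@endoMm[es, ]
  inScar <- fibroCMR:::inWedgeDeg(geom@thetaDeg, spec@scarCenterDeg,
                                  spec@scarWidthDeg)
  farRemote <- fibroCMR:::circDistDeg(geom@thetaDeg, spec@scarCenterDeg) >
    spec@scarWidthDeg / 2 + 30
  expect_true(max(wt[inScar]) < min(wt[farRemote]))
})

test_that("cavity area strictly decreases when both walls thicken", {
  geom <- simulateCine(PhantomSpec(thickeningScarMm = 2, nFrames = 8))
  areas <- vapply(1:8, function(f) cavityAreaMm2(geom, f), numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("excessive thickening triggers the cavity-collapse error", {
  expect_error(simulateCine(PhantomSpec(thickeningHealthyMm = 25)),
               "cavity collapse")
})

test_that("epi exceeds endo at every angle and frame across random phantoms", {
  for (spec in randomSpecs(5, seed = 31)) {
    geom <- simulateCine(spec, globalInwardMm = 1.5)
    expect_true(all(geom@epiMm > geom@endoMm))
  }
})

test_that("tracked contours keep the ED frame exact and stay seeded", {
  geom <- simulateCine(PhantomSpec(nFrames = 6))
  t1 <- trackContours(geom, sdMm = 1, seed = 5)
  t2 <- trackContours(geom, sdMm = 1, seed = 5)
  expect_identical(t1@endoMm, t2@endoMm)
  expect_equal(t1@endoMm[1, ], geom@endoMm[1, ])   # ED manually traced
  expect_false(isTRUE(all.equal(t1@endoMm[6, ], geom@endoMm[6, ])))
  expect_identical(trackContours(geom, sdMm = 0), geom)
})
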