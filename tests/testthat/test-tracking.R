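# Sub-pixel localization, axial calibration, and 3D reconstruction.

test_that("a noiseless Gaussian spot is localized exactly and equivariantly", {
  opt <- OpticsParams(psfSigma = 1.3 * 98)
  fr <- makeSpotFrame(10.30, 7.75)
  sp <- localizeSpots(fr, opt, maxSpots = 1L)
  expect_equal(sp$x_px, 10.30, tolerance = 0.01)
  expect_equal(sp$y_px, 7.75, tolerance = 0.01)
  # translation equivariance
  sp2 <- localizeSpots(makeSpotFrame(13.30, 12.75), opt, maxSpots = 1L)
  expect_equal(sp2$x_px - sp$x_px, 3, tolerance = 0.01)
  expect_equal(sp2$y_px - sp$y_px, 5, tolerance = 0.01)
  # nothing above threshold: empty result
  expect_equal(nrow(localizeSpots(matrix(0, 20, 20), opt)), 0)
})

test_that("localization precision approaches the photon-limited bound", {
  opt <- OpticsParams(psfSigma = 1.3 * 98)
  set.seed(33)
  n <- 300
  xs <- numeric(n)
  for (i in seq_len(n)) {
    fr <- matrix(rpois(20 * 24, makeSpotFrame(11.4, 9.2)), 20, 24)
    xs[i] <- localizeSpots(fr, opt, maxSpots = 1L)$x_px
  }
  expect_equal(mean(xs), 11.4, tolerance = 0.01)
  expect_lt(sd(xs), 2 * 1.3 / sqrt(1e4))
})

test_that("axial calibration recovers the encoding gain", {
  opt <- OpticsParams(axialGain = 0.5)
  st <- renderCalibrationStack(seq(-300, 300, 100), opt, shotNoise = FALSE)
  cal <- calibrateAxial(st)
  # the window-edge background estimate leaves a sub-nm systematic floor
  expect_equal(cal@slope, 0.5, tolerance = 5e-3)
  expect_equal(cal@intercept, 1470, tolerance = 1e-3)
  expect_lt(cal@residualRms, 1)
  # fewer than 3 distinct z values is rank-deficient for our purposes
  st2 <- renderCalibrationStack(c(-100, 100), opt, shotNoise = FALSE)
  expect_error(calibrateAxial(st2), "3 distinct")
  # with shot and read noise, the slope stays within 2%
  slopes <- vapply(1:8, function(s) {
    stn <- renderCalibrationStack(seq(-300, 300, 100),
                                  OpticsParams(axialGain = 0.5, readNoise = 5),
                                  framesPerZ = 3, shotNoise = TRUE, seed = s)
    calibrateAxial(stn)@slope
  }, numeric(1))
  expect_true(all(abs(slopes - 0.5) / 0.5 < 0.02))
})

test_that("reconstruction inverts the renderer up to the noise floor", {
  opt <- OpticsParams(photonsPerSpot = 1e4, fieldWidth = 40L, fieldHeight = 24L)
  cal <- calibrateAxial(renderCalibrationStack(seq(-300, 300, 100), opt,
                                               shotNoise = FALSE))
  # constant-z orbit reconstructs at constant z
  flat <- makeCircleTraj(n = 120, R = 200, rate = 20, center = c(0, 0, 150))
  stF <- renderDualImageStack(flat, opt, seed = 3)
  rF <- reconstruct3D(stF, cal)
  okF <- frameFlags(rF) == "ok"
  expect_equal(mean(positions(rF)[okF, 3]), 150, tolerance = 0.05)
  expect_lt(sd(positions(rF)[okF, 3]), 10)
  # separation equal to the intercept decodes to z = 0
  z0 <- renderCalibrationStack(0, opt, shotNoise = FALSE)
  r0 <- reconstruct3D(z0, cal)
  expect_equal(unname(positions(r0)[1, 3]), 0, tolerance = 1)
  # tilted-orbit round trip (short version; the full 2000-frame benchmark
  # lives in the acceptance suite)
  tr <- makeCircleTraj(n = 300, R = 250, thetaDeg = 35, phiDeg = 120,
                       center = c(0, 0, 200), rate = 21.8)
  st <- renderDualImageStack(tr, opt, seed = 4)
  rec <- reconstruct3D(st, cal)
  ok <- frameFlags(rec) == "ok"
  err <- positions(rec)[ok, ] - positions(tr)[ok, ]
  expect_lt(sqrt(mean(rowSums(err^2))), 10)
})

test_that("flag decisions are monotone in signal strength", {
  opt <- OpticsParams(psfSigma = 1.3 * 98)
  fr <- makeSpotFrame(11, 9, photons = 3000)
  thr <- 100
  # a frame whose peak falls below the detection threshold yields no spot,
  # and degrading the signal can never recover one
  expect_gt(nrow(localizeSpots(fr, opt, threshold = thr)), 0)
  expect_equal(nrow(localizeSpots(fr * 0.2, opt, threshold = thr)), 0)
  expect_equal(nrow(localizeSpots(fr * 0.1, opt, threshold = thr)), 0)
})
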