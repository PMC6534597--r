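# Forward optical model: dual-spot rendering with linear axial encoding.

test_that("spot separation encodes z linearly from the baseline", {
  opt <- OpticsParams(baselineSeparation = 1470, axialGain = 0.5)
  sepOf <- function(z) {
    st <- renderCalibrationStack(z, opt, shotNoise = FALSE)
    sp <- localizeSpots(st@frames[, , 1], opt)
    abs(diff(sp$x_px)) * opt@pixelSize
  }
  # z at the reference height: separation equals the baseline exactly
  expect_equal(sepOf(0), 1470, tolerance = 1e-3)
  # +100 nm at gain 0.5: separation grows by 50 nm (about half a pixel)
  expect_equal(sepOf(100) - sepOf(0), 50, tolerance = 1e-2)
  expect_equal(sepOf(-200) - sepOf(0), -100, tolerance = 1e-2)
})

test_that("total photon counts per frame are Poisson with the configured mean", {
  opt <- OpticsParams(photonsPerSpot = 2000, readNoise = 0, background = 0,
                      fieldWidth = 32L, fieldHeight = 24L)
  n <- 400
  tr <- Trajectory3D(seq_len(n) * 5e-4, cbind(0, 0, rep(0, n)))
  expected <- sum(renderDualImageStack(tr, opt, shotNoise = FALSE)@frames[, , 1])
  st <- renderDualImageStack(tr, opt, seed = 21)
  totals <- apply(st@frames, 3, sum)
  expect_equal(mean(totals), expected, tolerance = 0.02)
  # index-of-dispersion chi-squared test at alpha = 0.01
  stat <- (n - 1) * var(totals) / mean(totals)
  p <- pchisq(stat, df = n - 1)
  expect_gt(min(p, 1 - p), 0.005)
})

test_that("rendering is deterministic under a fixed seed and flags overlap", {
  opt <- OpticsParams(photonsPerSpot = 5000)
  tr <- makeCircleTraj(n = 50, R = 150, rate = 20)
  s1 <- renderDualImageStack(tr, opt, seed = 5)
  s2 <- renderDualImageStack(tr, opt, seed = 5)
  expect_identical(s1@frames, s2@frames)
  # a pair closer than 4 PSF sigma is declared unseparable
  optClose <- OpticsParams(baselineSeparation = 300, psfSigma = 130,
                           axialGain = 0.5)
  expect_warning(stC <- renderDualImageStack(tr, optClose, shotNoise = FALSE),
                 "overlap")
  expect_true(length(stC@metadata$overlapFrames) > 0)
  # trajectories outside the field of view are refused
  big <- makeCircleTraj(n = 60, R = 4000, rate = 20)
  expect_error(renderDualImageStack(big, opt), "field of view")
})
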