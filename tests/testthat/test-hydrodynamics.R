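# Closed-form drag coefficients and the near-wall correction.
# Frozen expected values were computed by direct evaluation of the printed
# formulas (eta = 1.35e-3 Pa s = 1.35e-9 pN s/nm^2).

test_that("sphere drag reproduces the two-term formula and its limits", {
  # R = 0: pure spinning term 8 pi eta r^3
  eta <- 1.35e-3
  r <- 105
  expect_equal(dragCoefficient(sphereDrag(r, 0, eta)),
               8 * pi * 1.35e-9 * r^3, tolerance = 1e-12)
  # two-term value at r = 105 nm, R = 250 nm (frozen direct evaluation)
  expect_equal(dragCoefficient(sphereDrag(105, 250, eta)), 0.2062726,
               tolerance = 1e-6)
  # linear in viscosity
  for (R in c(0, 100, 400))
    expect_equal(dragCoefficient(sphereDrag(105, R, 2 * eta)),
                 2 * dragCoefficient(sphereDrag(105, R, eta)))
  expect_error(sphereDrag(-1, 100), "positive")
  expect_error(sphereDrag(100, 100, eta = 0), "viscosity")
})

test_that("wall correction reproduces the bead-size factors and its limits", {
  # printed factors at a 0.5-um gap, two significant figures
  expect_equal(signif(wallCorrection(1000, 500), 2), 1.4)
  expect_equal(signif(wallCorrection(490, 500), 2), 1.2)
  expect_equal(signif(wallCorrection(210, 500), 2), 1.1)
  # free-space limit and monotone approach to the wall
  expect_equal(wallCorrection(1000, 1e9), 1, tolerance = 1e-6)
  gaps <- c(5000, 2000, 1000, 500, 200, 100)
  f <- vapply(gaps, function(g) wallCorrection(500, g), numeric(1))
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 1))
  expect_error(wallCorrection(-10, 100))
})

test_that("tethered-cell rod drag matches direct evaluation and is monotone", {
  expect_equal(dragCoefficient(rodDragTethered(2500, 250)), 53.79161,
               tolerance = 1e-6)
  L <- seq(1500, 4000, by = 500)
  g <- vapply(L, function(x) dragCoefficient(rodDragTethered(x, 250)), numeric(1))
  expect_true(all(diff(g) > 0))
  # aspect ratio too small: the log term goes non-positive
  expect_error(rodDragTethered(250, 250), "ln")
})

test_that("helix drag matches direct evaluation under both length conventions", {
  # archaellar parameters b = 220, p = 2100, L = 4300, r = 7 nm
  expect_equal(dragCoefficient(helixDrag(220, 2100, 4300, 7)), 0.5082329,
               tolerance = 1e-6)
  expect_equal(dragCoefficient(helixDrag(220, 2100, 4300, 7,
                                         lengthConvention = "axial")),
               0.6084544, tolerance = 1e-6)
  # straight-filament limit and linearity in length
  expect_equal(dragCoefficient(helixDrag(0, 2100, 4300, 7)), 0)
  g1 <- dragCoefficient(helixDrag(220, 2100, 2000, 7))
  g2 <- dragCoefficient(helixDrag(220, 2100, 4000, 7))
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
  expect_error(helixDrag(220, 10, 4300, 50), "slenderness")
})

test_that("marker dispatch applies the wall correction to beads only", {
  s <- markerDrag(sphereMarker(210, 250, wallGap = 500))
  expect_equal(s@correctionFactor, wallCorrection(210, 500), tolerance = 1e-12)
  expect_equal(s@gammaCorrected, s@gamma * s@correctionFactor)
  r <- markerDrag(rodMarker(2500, 250))
  expect_equal(r@correctionFactor, 1)
  expect_equal(r@gammaCorrected, r@gamma)
  # disabling the correction reproduces free-space drag
  s0 <- markerDrag(sphereMarker(210, 250, wallGap = 500),
                   applyWallCorrection = FALSE)
  expect_equal(dragCoefficient(s0), s@gamma)
})
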