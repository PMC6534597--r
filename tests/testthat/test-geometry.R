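# Rotation-plane search, circle fitting, rate estimation and trace QC.

test_that("an untilted circle yields theta = 0 with near-zero circularity CV", {
  pf <- findRotationPlane(makeCircleTraj(thetaDeg = 0))
  expect_equal(pf@theta, 0, tolerance = 0.1)
  expect_lt(pf@circularityScore, 1e-6)
})

test_that("plane angles of a noiseless tilted circle are recovered to 0.1 degree", {
  pf <- findRotationPlane(makeCircleTraj(thetaDeg = 35, phiDeg = 120,
                                         center = c(100, -50, 400)))
  expect_equal(pf@theta, 35, tolerance = 0.1)
  expect_equal(pf@phi, 120, tolerance = 0.1)
  expect_equal(as.numeric(pf@center), c(100, -50, 400), tolerance = 1)
  # recovery does not degrade with more points on noiseless data
  e1 <- abs(findRotationPlane(makeCircleTraj(n = 100, thetaDeg = 35,
                                             phiDeg = 120))@theta - 35)
  e2 <- abs(findRotationPlane(makeCircleTraj(n = 400, thetaDeg = 35,
                                             phiDeg = 120))@theta - 35)
  expect_lte(e2, e1 + 0.05)
})

test_that("the fitted normal is equivariant under global rotations", {
  tr <- makeCircleTraj(thetaDeg = 25, phiDeg = 40)
  Rm <- rotationMatrix(c(1, 2, 0.5), 20)
  tr2 <- Trajectory3D(times(tr), positions(tr) %*% t(Rm))
  pf <- findRotationPlane(tr)
  pf2 <- findRotationPlane(tr2)
  toNormal <- function(p) {
    t <- p@theta * pi / 180; ph <- p@phi * pi / 180
    c(sin(t) * cos(ph), sin(t) * sin(ph), cos(t))
  }
  nExp <- as.numeric(Rm %*% toNormal(pf))
  ang <- acos(min(1, abs(sum(nExp * toNormal(pf2))))) * 180 / pi
  expect_lt(ang, 0.2)
})

test_that("circle fitting is exact, unbiased under noise, and arc-robust", {
  tr <- makeCircleTraj(R = 250, thetaDeg = 0)
  cf <- projectAndFitCircle(tr, findRotationPlane(tr))
  expect_equal(cf@radius, 250, tolerance = 1e-6)
  expect_lt(cf@radialRms, 1e-6)
  # isotropic sigma = 10 nm noise, 2000 points: radius unbiased within 1%
  set.seed(55)
  trN <- makeCircleTraj(n = 2000, R = 250, thetaDeg = 0)
  pN <- positions(trN) + matrix(rnorm(6000, sd = 10), ncol = 3)
  trN <- Trajectory3D(times(trN), pN)
  cfN <- projectAndFitCircle(trN, findRotationPlane(trN))
  expect_equal(cfN@radius, 250, tolerance = 0.01)
  # semicircular arc only
  arcTr <- makeCircleTraj(n = 300, R = 250, thetaDeg = 0, arc = pi)
  cfA <- projectAndFitCircle(arcTr, findRotationPlane(arcTr))
  expect_equal(cfA@radius, 250, tolerance = 0.05)
})

test_that("rate estimation is exact for uniform rotation and antisymmetric", {
  tr <- makeCircleTraj(rate = 21.8, n = 1000)
  an <- analyzeTrajectory(tr)
  expect_equal(an$rate@rate, 21.8, tolerance = 1e-6)
  expect_equal(an$rate@direction, "CCW")
  # time reversal: same speed, opposite handedness
  rev <- Trajectory3D(times(tr), positions(tr)[nrow(positions(tr)):1, ])
  anR <- analyzeTrajectory(rev)
  expect_equal(anR$rate@rate, 21.8, tolerance = 1e-6)
  expect_equal(anR$rate@direction, "CW")
  # less than one turn cannot give a rate
  short <- makeCircleTraj(rate = 2, n = 200)  # 0.2 turns
  pf <- findRotationPlane(short)
  expect_error(estimateRate(short, pf, projectAndFitCircle(short, pf)),
               "insufficient")
})

test_that("Langevin traces yield rates consistent with the drag balance", {
  motor <- MotorParams(160, 0.81)
  cases <- list(list(mk = sphereMarker(210, 250), dur = 1, seed = 61),
                list(mk = sphereMarker(1000, 300), dur = 3, seed = 62))
  for (cs in cases) {
    g <- dragCoefficient(markerDrag(cs$mk))
    f0 <- predictedRate(motor, g)
    tr <- simulateRotationTrace(motor, cs$mk, PlaneSpec(30, 60, c(0, 0, 400)),
                                SimParams(cs$dur, seed = cs$seed))
    an <- analyzeTrajectory(tr)
    expect_lt(abs(an$rate@rate - f0), 3 * an$rate@rateSe)
  }
})

test_that("the estimated rate is invariant under rigid motions", {
  tr <- simulateRotationTrace(MotorParams(160, 0.81), sphereMarker(490, 250),
                              PlaneSpec(25, 210, c(0, 0, 300)),
                              SimParams(0.5, seed = 77))
  r1 <- analyzeTrajectory(tr)$rate@rate
  Rm <- rotationMatrix(c(0.3, -1, 2), 15)
  tr2 <- Trajectory3D(times(tr),
                      sweep(positions(tr) %*% t(Rm), 2, c(500, -200, 100), "+"))
  r2 <- analyzeTrajectory(tr2)$rate@rate
  expect_equal(r2, r1, tolerance = 0.005)
})

test_that("collinear input is rejected as having no rotation plane", {
  t <- (1:100) * 5e-4
  line <- Trajectory3D(t, cbind(t * 1000, t * 2000, t * 500))
  expect_error(findRotationPlane(line), "degenerate")
})

test_that("QC accepts constant speed and rejects 60-degree modulation", {
  anC <- analyzeTrajectory(makeCircleTraj(n = 2000))
  expect_lt(anC$qc@modulationDepth60, 0.1)
  expect_true(anC$qc@accepted)
  # full-depth 60-degree-periodic speed modulation is a positive control
  anM <- analyzeTrajectory(makeModulatedTraj())
  expect_gt(anM$qc@modulationDepth60, 0.5)
  expect_false(anM$qc@accepted)
  # the decision is invariant to the phase offset of the modulation
  anM2 <- analyzeTrajectory(makeModulatedTraj(offsetRad = 0.7))
  expect_false(anM2$qc@accepted)
  # long dwells (saw-tooth rotation) break smoothness
  t <- (1:3000) * 5e-4
  ph <- 2 * pi * 10 * t
  ph[1000:3000] <- ph[1000] + (ph[1000:3000] - ph[1000]) * 0.02  # near-stall
  saw <- Trajectory3D(t, cbind(250 * cos(ph), 250 * sin(ph), 0))
  anS <- analyzeTrajectory(saw)
  expect_false(anS$qc@smooth)
  expect_false(anS$qc@accepted)
})
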