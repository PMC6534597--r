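# Generative motor models: Langevin constant-torque rotation (model A) and
# the stepping motor with a rate-limiting chemical transition (model B).

test_that("noiseless model A rotates uniformly at T_a/2pi(gamma+gamma_a)", {
  motor <- MotorParams(torque = 160, internalFriction = 0.81)
  g <- dragCoefficient(markerDrag(sphereMarker(210, 250)))
  a <- simulateAngularTrace(motor, g, SimParams(0.2, kBT = 0, seed = 1))
  f0 <- 160 / (2 * pi * (g + 0.81))
  rates <- diff(a$theta_rad) / diff(a$t_s) / (2 * pi)
  # uniform to machine precision over any window
  expect_equal(rates, rep(f0, length(rates)), tolerance = 1e-10)
  expect_equal(predictedRate(motor, g), f0)
})

test_that("model A thermal phase diffuses with variance 2 k_BT t / gamma", {
  # negligible torque isolates the diffusive part of the dynamics
  motor <- MotorParams(torque = 1e-9, internalFriction = 0)
  gamma <- 2
  sim <- SimParams(duration = 50, kBT = 4.1, seed = 42)  # 1e5 frames
  a <- simulateAngularTrace(motor, gamma, sim)
  D <- 4.1 / gamma
  for (lag in c(1L, 3L, 10L)) {
    dth <- a$theta_rad[-seq_len(lag)] - a$theta_rad[seq_len(nrow(a) - lag)]
    msd <- mean(dth^2)
    expect_equal(msd, 2 * D * lag * sim@dt, tolerance = 0.05)
  }
})

test_that("model B reaches the zero-load rate when the drag vanishes", {
  motor <- MotorParams(160, mode = "model_B", fNoLoad = 30)
  sim <- SimParams(duration = 60, seed = 7)  # ~ 10800 steps
  a <- simulateAngularTrace(motor, 0, sim)
  f <- (a$theta_rad[nrow(a)] - a$theta_rad[1]) / (2 * pi * (a$t_s[nrow(a)] - a$t_s[1]))
  nSteps <- 30 * 6 * 60
  se <- 30 / sqrt(nSteps / 6)  # per-revolution periods are Erlang(6)
  expect_lt(abs(f - 30), 3 * se)
})

test_that("models A and B trace the same mean rate-vs-drag curve", {
  # gamma_a = T_a / (2 pi f_noload) makes the two algebraically identical;
  # quick 3-point Monte-Carlo check (the full 10-point curve is in the
  # acceptance suite)
  fn <- 30
  ga <- 160 / (2 * pi * fn)
  mA <- MotorParams(160, internalFriction = ga)
  mB <- MotorParams(160, mode = "model_B", fNoLoad = fn)
  for (g in c(0.3, 3, 30)) {
    fExp <- predictedRate(mA, g)
    expect_equal(fExp, predictedRate(mB, g), tolerance = 1e-12)
    durB <- 2e4 * (1 / (fn * 6) + g * (pi / 3) / 160)
    simB <- SimParams(durB, dt = durB / 5e4, seed = round(100 * g))
    b <- simulateAngularTrace(mB, g, simB)
    fB <- (b$theta_rad[nrow(b)] - b$theta_rad[1]) / (2 * pi * durB)
    expect_equal(fB, fExp, tolerance = 0.03)
  }
})

test_that("trajectories are reproducible and direction flips the phase", {
  motor <- MotorParams(160, 0.81)
  mk <- sphereMarker(490, 250)
  pl <- PlaneSpec(20, 200, c(0, 0, 300))
  t1 <- simulateRotationTrace(motor, mk, pl, SimParams(0.2, seed = 9))
  t2 <- simulateRotationTrace(motor, mk, pl, SimParams(0.2, seed = 9))
  expect_identical(positions(t1), positions(t2))
  mCW <- MotorParams(160, 0.81, direction = "CW")
  aCCW <- simulateAngularTrace(motor, 1, SimParams(0.2, kBT = 0, seed = 1))
  aCW <- simulateAngularTrace(mCW, 1, SimParams(0.2, kBT = 0, seed = 1))
  expect_equal(aCW$theta_rad, -aCCW$theta_rad)
})

test_that("degenerate parameters are refused", {
  expect_error(MotorParams(-5), "positive")
  expect_error(MotorParams(160, mode = "model_B"), "fNoLoad")
  expect_error(MotorParams(160, stepSize = 50), "divisor")
  expect_error(SimParams(duration = 0.001), "100 camera intervals")
  # rotation faster than half a turn per frame is unresolvable
  expect_error(
    simulateAngularTrace(MotorParams(1e9), 0.1, SimParams(0.1, kBT = 0)),
    "unstable")
  expect_error(
    simulateRotationTrace(MotorParams(160), helixMarker(), PlaneSpec(),
                          SimParams(0.2)),
    "helical")
})
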