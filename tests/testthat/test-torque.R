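# Constant-torque model fitting and the benchmark dataset generator.

test_that("the benchmark dataset reproduces the study design and seed contract", {
  ds <- buildBenchmarkDataset(seed = 11)
  rec <- records(ds)
  expect_equal(sum(rec$kind == "sphere" & rec$diameter_nm == 210), 32)
  expect_equal(sum(rec$kind == "sphere" & rec$diameter_nm == 490), 31)
  expect_equal(sum(rec$kind == "sphere" & rec$diameter_nm == 1000), 26)
  expect_equal(sum(rec$kind == "rod"), 12)
  expect_identical(rec, records(buildBenchmarkDataset(seed = 11)))
  expect_false(identical(rec, records(buildBenchmarkDataset(seed = 12))))
  cfg <- benchmarkConfig()
  cfg$classes <- list()
  expect_error(buildBenchmarkDataset(cfg, seed = 1), "config error")
})

test_that("drag columns follow the per-size wall-correction factors", {
  ds <- markerFriction(buildBenchmarkDataset(seed = 3))
  rec <- records(ds)
  for (d in c(210, 490, 1000)) {
    i <- rec$kind == "sphere" & rec$diameter_nm == d
    expect_equal(rec$gamma_corrected[i] / rec$gamma_raw[i],
                 rep(wallCorrection(d, 500), sum(i)), tolerance = 1e-9)
  }
  i <- rec$kind == "rod"
  expect_equal(rec$gamma_corrected[i], rec$gamma_raw[i])
  # composition against the two closed forms for a bead spinning in place
  one <- MarkerDataset(data.frame(
    marker_id = "x", kind = "sphere", diameter_nm = 1000,
    rotation_radius_nm = 0, cell_length_nm = NA, cell_radius_nm = NA,
    wall_gap_nm = 500, rate_hz = 1, direction = "CCW"))
  r1 <- records(markerFriction(one))
  expect_equal(r1$gamma_raw, 8 * pi * 1.35e-9 * 500^3, tolerance = 1e-9)
  expect_equal(r1$gamma_corrected, r1$gamma_raw * wallCorrection(1000, 500),
               tolerance = 1e-9)
})

test_that("the fit recovers exact model parameters to numerical precision", {
  gamma <- 10^seq(-1, 2, length.out = 8)
  f <- 160 / (2 * pi * (gamma + 0.81))
  ds <- MarkerDataset(data.frame(
    marker_id = paste0("m", 1:8), kind = "sphere", diameter_nm = 210,
    rotation_radius_nm = 250, cell_length_nm = NA, cell_radius_nm = NA,
    wall_gap_nm = 500, rate_hz = f, direction = "CCW",
    gamma_raw = gamma, gamma_corrected = gamma))
  fit <- fitConstantTorque(ds, bootstrap = 50, seed = 1)
  expect_equal(torque(fit), 160, tolerance = 1e-6)
  expect_equal(internalFriction(fit), 0.81, tolerance = 1e-6)
  # nested model: data generated with gamma_a = 0 fit back to ~0
  ds0 <- initialize(ds, records = within(records(ds),
    rate_hz <- 160 / (2 * pi * gamma_raw)))
  fit0 <- fitConstantTorque(ds0, bootstrap = 50, seed = 1)
  expect_lt(internalFriction(fit0), 1e-6)
})

test_that("the fit is scale-consistent and bootstrap-reproducible", {
  ds <- buildBenchmarkDataset(seed = 21)
  f1 <- fitConstantTorque(ds, bootstrap = 300, seed = 5)
  rec <- records(markerFriction(ds))
  c0 <- 3
  rec$rate_hz <- rec$rate_hz / c0
  rec$gamma_raw <- rec$gamma_raw * c0
  rec$gamma_corrected <- rec$gamma_corrected * c0
  f2 <- fitConstantTorque(MarkerDataset(rec), bootstrap = 300, seed = 5)
  expect_equal(torque(f2), torque(f1), tolerance = 1e-6)
  expect_equal(internalFriction(f2), c0 * internalFriction(f1), tolerance = 1e-6)
  # fixed bootstrap seed reproduces the intervals
  f3 <- fitConstantTorque(ds, bootstrap = 300, seed = 5)
  expect_identical(confint(f3), confint(f1))
  # degenerate design
  recE <- records(markerFriction(ds))
  recE$gamma_raw <- recE$gamma_corrected <- 1
  expect_error(fitConstantTorque(MarkerDataset(recE)), "identifiability")
})

test_that("apparent torque is flat after subtracting the internal friction", {
  gamma <- 10^seq(-1, 2, length.out = 12)
  f <- 160 / (2 * pi * (gamma + 0.81))
  ds <- MarkerDataset(data.frame(
    marker_id = paste0("m", seq_along(gamma)), kind = "sphere",
    diameter_nm = 210, rotation_radius_nm = 250, cell_length_nm = NA,
    cell_radius_nm = NA, wall_gap_nm = 500, rate_hz = f, direction = "CCW",
    gamma_raw = gamma, gamma_corrected = gamma))
  fit <- fitConstantTorque(ds, bootstrap = 50, seed = 2)
  tab <- apparentTorqueCurve(ds, fit)
  expect_equal(tab$apparent_torque_total, rep(160, 12), tolerance = 1e-6)
  # the load-only torque declines with rate when gamma_a > 0
  ord <- order(tab$rate_hz)
  expect_true(all(diff(tab$apparent_torque[ord]) < 0))
  # on noisy benchmark data the subtracted torque is flat across loads:
  # no monotone association with the drag coefficient (the measured rate
  # itself carries the same multiplicative noise as the torque, so drag is
  # the noise-free load axis), while the load-only torque declines strongly
  pvals <- vapply(8:12, function(s) {
    dsB <- markerFriction(buildBenchmarkDataset(seed = s))
    fitB <- fitConstantTorque(dsB, bootstrap = 100, seed = s)
    tabB <- apparentTorqueCurve(dsB, fitB)
    g <- records(dsB)$gamma_corrected
    suppressWarnings(c(
      flat = cor.test(tabB$apparent_torque_total, g, method = "spearman")$p.value,
      decl = cor.test(tabB$apparent_torque, tabB$rate_hz,
                      method = "spearman")$p.value))
  }, numeric(2))
  expect_gt(median(pvals["flat", ]), 0.01)
  expect_lt(max(pvals["decl", ]), 1e-6)
})

test_that("the stepping-motor parameterization converts exactly both ways", {
  expect_equal(modelBNoLoadRate(160, 0.81), 31.43801, tolerance = 1e-6)
  for (fn in c(5, 31.4, 200))
    expect_equal(modelBNoLoadRate(160, modelBFriction(160, fn)), fn)
  # vanishing internal friction corresponds to an unbounded zero-load rate
  expect_lt(modelBFriction(160, 1e9), 1e-6)
  expect_error(modelBFriction(160, 0), "fNoLoad")
  # the two parameterizations trace identical rate curves
  g <- 10^seq(-2, 3, length.out = 50)
  fA <- 160 / (2 * pi * (g + 0.81))
  fB <- 1 / (1 / modelBNoLoadRate(160, 0.81) + 2 * pi * g / 160)
  expect_lt(max(abs(fA - fB) / fA), 1e-9)
})

test_that("rate-versus-diameter regression matches the printed line", {
  ds2 <- MarkerDataset(data.frame(
    marker_id = c("a", "b"), kind = "sphere", diameter_nm = c(200, 1000),
    rotation_radius_nm = 250, cell_length_nm = NA, cell_radius_nm = NA,
    wall_gap_nm = 500, rate_hz = c(22.2, 3.0), direction = "CCW"))
  fit2 <- fitRateVsDiameter(ds2)
  expect_equal(fit2$A, -0.024, tolerance = 1e-9)
  expect_equal(fit2$B, 27, tolerance = 1e-9)
  # those constants predict ~22 Hz for a 210-nm bead
  expect_equal(fit2$A * 210 + fit2$B, 21.96, tolerance = 1e-9)
  # benchmark spheres: the intercept approximates the zero-load rate
  dsB <- buildBenchmarkDataset(seed = 14)
  fB <- fitRateVsDiameter(dsB)
  f0 <- modelBNoLoadRate(160, 0.81)
  expect_lt(abs(fB$B - f0) / f0, 0.2)
  one <- MarkerDataset(records(ds2)[1, ])
  expect_error(fitRateVsDiameter(one), "identifiability")
})
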