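# Constructed trajectories with known ground truth, built in code.

# exact circle of radius R in the plane whose normal has polar angles
# (thetaDeg, phiDeg), traversed at a uniform rate (Hz, CCW-positive)
makeCircleTraj <- function(n = 600, R = 250, thetaDeg = 0, phiDeg = 0,
                           center = c(0, 0, 0), rate = 21.8, dt = 5e-4,
                           arc = NULL) {
  t <- seq_len(n) * dt
  ph <- 2 * pi * rate * t
  if (!is.null(arc)) ph <- seq(0, arc, length.out = n)
  th <- thetaDeg * pi / 180
  p <- phiDeg * pi / 180
  nrm <- c(sin(th) * cos(p), sin(th) * sin(p), cos(th))
  u <- if (abs(sin(th)) < 1e-12) c(1, 0, 0) else c(-sin(p), cos(p), 0)
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  pos <- R * (outer(cos(ph), u) + outer(sin(ph), v))
  pos <- sweep(pos, 2, center, "+")
  Trajectory3D(times = t, positions = pos)
}

# rotation matrix about an arbitrary axis (Rodrigues)
rotationMatrix <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# trace whose angular speed is modulated with 60-degree periodicity:
# dtheta/dt = w0 * (1 + depth * cos(6 * (theta + offsetRad)))
makeModulatedTraj <- function(n = 4000, dt = 1e-4, rateHz = 20, depth = 0.95,
                              offsetRad = 0, R = 250) {
  th <- numeric(n)
  w0 <- 2 * pi * rateHz
  for (i in 2:n)
    th[i] <- th[i - 1] + w0 * (1 + depth * cos(6 * (th[i - 1] + offsetRad))) * dt
  Trajectory3D(seq_len(n) * dt, cbind(R * cos(th), R * sin(th), 0))
}

# single pixel-integrated Gaussian spot frame, built independently of the
# package's renderer
makeSpotFrame <- function(x0, y0, h = 20, w = 24, sigma = 1.3, photons = 1e4,
                          bg = 0) {
  gx <- pnorm((0:(w - 1) + 0.5 - x0) / sigma) - pnorm((0:(w - 1) - 0.5 - x0) / sigma)
  gy <- pnorm((0:(h - 1) + 0.5 - y0) / sigma) - pnorm((0:(h - 1) - 0.5 - y0) / sigma)
  bg + photons * (gy %o% gx)
}
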