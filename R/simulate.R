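## Rotational dynamics simulators: an overdamped Langevin motor with
## constant torque (model A) and a tightly coupled stepping motor with a
## rate-limiting chemical transition (model B).

#' Evaluate an expression with a temporarily fixed RNG seed
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Orthonormal basis of a tilted rotation plane
#'
#' The plane normal in polar coordinates is
#' n = (sin t cos p, sin t sin p, cos t); `u` and `v` span the plane with
#' u x v = n, so a phase increasing in the (u, v) frame is counter-clockwise
#' about the normal.
#' @noRd
planeBasis <- function(thetaDeg, phiDeg) {
  t <- thetaDeg * pi / 180
  p <- phiDeg * pi / 180
  n <- c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
  if (abs(sin(t)) < 1e-12) {
    u <- c(1, 0, 0)
  } else {
    u <- c(-sin(p), cos(p), 0)  # perpendicular to the tilt direction
  }
  v <- c(n[2] * u[3] - n[3] * u[2],   # v = n x u, so that u x v = n
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(n = n, u = u, v = v)
}

#' Analytic mean rotation rate of the motor models
#'
#' Model A: \eqn{f = T_a / (2\pi(\gamma + \gamma_a))}.
#' Model B: \eqn{f = (1/f_{noload} + 2\pi\gamma/T_a)^{-1}}.
#' The two coincide when \eqn{\gamma_a = T_a / (2\pi f_{noload})}.
#'
#' @param motor a [MotorParams].
#' @param gammaLoad external (marker) drag (pN nm s); vectorised.
#' @return Mean rotation rate (Hz).
#' @export
predictedRate <- function(motor, gammaLoad) {
  stopifnot(is(motor, "MotorParams"))
  if (motor@mode == "model_A") {
    motor@torque / (2 * pi * (gammaLoad + motor@internalFriction))
  } else {
    1 / (1 / motor@fNoLoad + 2 * pi * gammaLoad / motor@torque)
  }
}

#' Simulate the angular trajectory of a loaded rotary motor
#'
#' Returns the unwrapped rotation angle sampled at camera frames.
#'
#' Model A integrates the overdamped angular Langevin equation
#' \deqn{d\theta = \frac{T_a}{\gamma + \gamma_a}\,dt +
#'   \sqrt{2 k_B T/(\gamma+\gamma_a)}\,dW}
#' by Euler--Maruyama on an internal grid of one tenth of the camera
#' interval, decimated to camera frames.
#'
#' Model B draws exponential chemical dwells at rate
#' `fNoLoad * 360 / stepSize` and follows each by a constant-torque
#' mechanical ramp of one step, of duration \eqn{\gamma\,\delta/T_a}
#' (slew rate \eqn{T_a/\gamma}); thermal fluctuation is added to the
#' observed angle as per-frame Brownian jitter of variance
#' \eqn{2(k_BT/\gamma)\,dt}, leaving the mean rate exactly
#' \eqn{(1/f_{noload} + 2\pi\gamma/T_a)^{-1}}.
#'
#' @param motor a [MotorParams].
#' @param gammaLoad external drag of the attached marker (pN nm s); must be
#'   positive for model A (with `internalFriction`, total drag positive) and
#'   non-negative for model B.
#' @param sim a [SimParams].
#' @return A data.frame with columns `t_s` and `theta_rad` (signed,
#'   CCW-positive about the plane normal).
#' @export
simulateAngularTrace <- function(motor, gammaLoad, sim) {
  stopifnot(is(motor, "MotorParams"), is(sim, "SimParams"))
  nF <- round(sim@duration / sim@dt)
  tt <- seq_len(nF) * sim@dt
  theta <- withSeed(sim@seed, {
    if (motor@mode == "model_A") {
      gtot <- gammaLoad + motor@internalFriction
      if (!is.finite(gtot) || gtot <= 0)
        stop("total drag must be positive for model_A")
      if (motor@torque / gtot * sim@dt > pi)
        stop("unstable sampling: more than half a turn per camera interval; ",
             "reduce 'dt' or increase the load")
      sub <- 10L
      dti <- sim@dt / sub
      drift <- motor@torque / gtot * dti
      sdW <- sqrt(2 * sim@kBT / gtot * dti)
      out <- numeric(nF)
      chunk <- 200000L  # frames per chunk, keeps memory bounded on long runs
      last <- 0
      i <- 1L
      while (i <= nF) {
        j <- min(i + chunk - 1L, nF)
        m <- (j - i + 1L) * sub
        inc <- drift + if (sdW > 0) sdW * stats::rnorm(m) else numeric(m)
        cum <- cumsum(inc)
        out[i:j] <- last + cum[seq.int(sub, m, by = sub)]
        last <- out[j]
        i <- j + 1L
      }
      out
    } else {
      simulateModelB(motor, gammaLoad, sim, tt)
    }
  })
  if (motor@direction == "CW") theta <- -theta
  data.frame(t_s = tt, theta_rad = theta)
}

#' Event-driven model B phase, evaluated at frame times
#' @noRd
simulateModelB <- function(motor, gammaLoad, sim, tt) {
  if (!is.finite(gammaLoad) || gammaLoad < 0)
    stop("'gammaLoad' must be >= 0 for model_B")
  delta <- motor@stepSize * pi / 180
  k <- motor@fNoLoad * (360 / motor@stepSize)   # chemical steps per second
  tau <- gammaLoad * delta / motor@torque        # mechanical ramp duration
  Tend <- tt[length(tt)]
  nGuess <- ceiling(Tend / (1 / k + tau) * 1.25) + 50L
  dwell <- stats::rexp(nGuess, rate = k)
  while (sum(dwell) + length(dwell) * tau < Tend) {
    dwell <- c(dwell, stats::rexp(nGuess, rate = k))
  }
  nStep <- length(dwell)
  rampStart <- cumsum(dwell + tau) - tau
  if (tau == 0) {  # instantaneous steps: count completed steps
    theta <- delta * findInterval(tt, rampStart)
  } else {
    # breakpoints: dwell start, ramp start, alternating; phase piecewise linear
    dwellStart <- rampStart - dwell
    tb <- cummax(as.vector(rbind(dwellStart, rampStart)))
    pb <- rep((seq_len(nStep) - 1) * delta, each = 2)
    slope <- as.vector(rbind(rep(0, nStep), rep(delta / tau, nStep)))
    idx <- findInterval(tt, tb)
    idx[idx < 1L] <- 1L
    theta <- pb[idx] + slope[idx] * (tt - tb[idx])
  }
  if (sim@kBT > 0 && gammaLoad > 0) {
    jitter <- stats::rnorm(length(tt), sd = sqrt(2 * (sim@kBT / gammaLoad) * sim@dt))
    theta <- theta + jitter
  }
  theta
}

#' Simulate a 3D rotation trace of a marker on the motor
#'
#' Simulates the motor angle with [simulateAngularTrace()] under the total
#' drag of the given marker (wall-corrected for beads) and places the marker
#' on its orbit in the specified plane: orbit radius is the bead
#' `rotationRadius` for spheres and the lever arm `cellLength` (pivot at the
#' cell end) for tethered cells.
#'
#' @param motor a [MotorParams].
#' @param marker a [MarkerGeometry] (`sphere` or `rod`).
#' @param plane a [PlaneSpec]; orbit plane orientation and centre.
#' @param sim a [SimParams].
#' @return A [Trajectory3D], sampled at the camera interval.
#' @examples
#' tr <- simulateRotationTrace(
#'   MotorParams(torque = 160, internalFriction = 0.81),
#'   sphereMarker(diameter = 210, rotationRadius = 250),
#'   PlaneSpec(theta = 35, phi = 120, center = c(0, 0, 400)),
#'   SimParams(duration = 0.25, seed = 1))
#' @export
simulateRotationTrace <- function(motor, marker, plane, sim) {
  stopifnot(is(marker, "MarkerGeometry"), is(plane, "PlaneSpec"))
  if (marker@kind == "helix")
    stop("helical filaments are drag terms, not orbiting markers")
  drag <- markerDrag(marker, eta = sim@viscosity, applyWallCorrection = TRUE)
  radius <- switch(marker@kind, sphere = marker@rotationRadius,
                   rod = marker@cellLength)
  ang <- simulateAngularTrace(motor, dragCoefficient(drag), sim)
  basis <- planeBasis(plane@theta, plane@phi)
  pos <- outer(cos(ang$theta_rad), basis$u) + outer(sin(ang$theta_rad), basis$v)
  pos <- pos * radius
  pos <- sweep(pos, 2, plane@center, "+")
  Trajectory3D(times = ang$t_s, positions = pos)
}
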