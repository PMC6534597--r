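## Orbit geometry: find the plane in which the trajectory is circular,
## fit the circle, unwrap phase, estimate the signed rotation rate, and
## apply the smooth-rotation quality-control rules.

#' Kasa algebraic circle fit
#' @noRd
kasaCircle <- function(xy) {
  A <- cbind(xy[, 1], xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  sol <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                  error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  cx <- sol[1] / 2; cy <- sol[2] / 2
  R2 <- sol[3] + cx^2 + cy^2
  if (!is.finite(R2) || R2 <= 0) return(NULL)
  list(center = c(cx, cy), radius = sqrt(R2))
}

#' Coefficient of variation of radial distances in a candidate plane
#' @noRd
planeCircularity <- function(pts, thetaDeg, phiDeg) {
  basis <- planeBasis(thetaDeg, phiDeg)
  uu <- pts %*% basis$u
  vv <- pts %*% basis$v
  k <- kasaCircle(cbind(uu, vv))
  if (is.null(k)) return(Inf)
  r <- sqrt((uu - k$center[1])^2 + (vv - k$center[2])^2)
  m <- mean(r)
  if (m <= 0) return(Inf)
  stats::sd(r) / m
}

#' Find the plane in which an orbit is circular
#'
#' Grid search over the polar angles of the plane normal, minimizing the
#' coefficient of variation of the projected radial distances (a circle has
#' CV zero).  The coarse 1-degree grid is seeded from the SVD plane of the
#' point cloud and refined to 0.1 degree.
#'
#' @param traj a [Trajectory3D]; flagged frames are ignored.
#' @return A `PlaneFit` with the normal angles `theta` (tilt from +z, 0--90
#'   degrees) and `phi` (azimuth), the 3D orbit centre, the circularity
#'   score (CV of radii; lower is better) and the RMS out-of-plane residual.
#' @examples
#' tr <- simulateRotationTrace(MotorParams(160, 0.81),
#'                             sphereMarker(210, 250),
#'                             PlaneSpec(35, 120), SimParams(0.25, seed = 2))
#' findRotationPlane(tr)
#' @export
findRotationPlane <- function(traj) {
  stopifnot(is(traj, "Trajectory3D"))
  ok <- frameFlags(traj) == "ok"
  pts <- positions(traj)[ok, , drop = FALSE]
  if (nrow(pts) < 50L) stop("need at least 50 unflagged points")
  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2, ctr)
  sv <- svd(cpts, nu = 0)
  if (sv$d[2] < 1e-6 * sv$d[1])
    stop("degenerate (collinear) trajectory: no rotation plane")
  n0 <- sv$v[, 3]
  if (n0[3] < 0) n0 <- -n0
  theta0 <- acos(min(max(n0[3], -1), 1)) * 180 / pi
  phi0 <- (atan2(n0[2], n0[1]) * 180 / pi) %% 360
  gridSearch <- function(thetas, phis) {
    best <- list(score = Inf)
    for (th in thetas) for (ph in phis) {
      s <- planeCircularity(cpts, th, ph %% 360)
      if (s < best$score) best <- list(score = s, theta = th, phi = ph %% 360)
    }
    best
  }
  if (theta0 < 2) {
    best <- gridSearch(seq(0, max(3, theta0 + 2), by = 1), seq(0, 355, by = 5))
  } else {
    best <- gridSearch(seq(max(0, theta0 - 8), min(90, theta0 + 8), by = 1),
                       seq(phi0 - 8, phi0 + 8, by = 1))
  }
  best <- gridSearch(seq(max(0, best$theta - 1), min(90, best$theta + 1), by = 0.1),
                     seq(best$phi - 1, best$phi + 1, by = 0.1))
  basis <- planeBasis(best$theta, best$phi)
  k <- kasaCircle(cbind(cpts %*% basis$u, cpts %*% basis$v))
  center3 <- ctr + k$center[1] * basis$u + k$center[2] * basis$v
  w <- cpts %*% basis$n
  new("PlaneFit", theta = best$theta, phi = best$phi, center = center3,
      circularityScore = best$score,
      outOfPlaneRms = sqrt(mean((w - mean(w))^2)))
}

#' Project onto a fitted plane and fit the orbit circle
#'
#' Projects the trajectory into the plane, fits a circle algebraically
#' (Kasa) and refines it by geometric least squares (minimizing the radial
#' residual sum of squares over the centre).
#'
#' @param traj a [Trajectory3D].
#' @param plane a `PlaneFit` from [findRotationPlane()].
#' @return A `CircleFit` with radius, in-plane centre and radial RMS
#'   residual.  Warns when the radius is below 3x the radial residual
#'   (low-signal orbit).
#' @export
projectAndFitCircle <- function(traj, plane) {
  stopifnot(is(traj, "Trajectory3D"), is(plane, "PlaneFit"))
  ok <- frameFlags(traj) == "ok"
  pts <- positions(traj)[ok, , drop = FALSE]
  basis <- planeBasis(plane@theta, plane@phi)
  uv <- cbind(pts %*% basis$u, pts %*% basis$v)
  k <- kasaCircle(uv)
  if (is.null(k)) stop("circle fit failed (degenerate projection)")
  obj <- function(ce) {
    r <- sqrt((uv[, 1] - ce[1])^2 + (uv[, 2] - ce[2])^2)
    sum((r - mean(r))^2)
  }
  opt <- stats::optim(k$center, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12))
  r <- sqrt((uv[, 1] - opt$par[1])^2 + (uv[, 2] - opt$par[2])^2)
  R <- mean(r)
  rms <- sqrt(mean((r - R)^2))
  if (R < 3 * rms)
    warning("orbit radius below 3x radial noise: low-signal trajectory")
  new("CircleFit", radius = R, center = opt$par, radialRms = rms)
}

#' Unwrapped phase of a projected trajectory
#' @noRd
unwrapPhase <- function(traj, plane, circle) {
  ok <- frameFlags(traj) == "ok"
  pts <- positions(traj)[ok, , drop = FALSE]
  basis <- planeBasis(plane@theta, plane@phi)
  uu <- pts %*% basis$u - circle@center[1]
  vv <- pts %*% basis$v - circle@center[2]
  ph <- atan2(vv, uu)
  d <- diff(ph)
  d <- (d + pi) %% (2 * pi) - pi
  list(times = times(traj)[ok], phase = ph[1] + c(0, cumsum(d)))
}

#' Estimate the signed rotation rate
#'
#' Per-frame phase is the `atan2` of the in-plane coordinates about the
#' fitted centre, unwrapped; the rate is the slope of the least-squares line
#' of phase versus time divided by 2 pi.  Rotation is CCW-positive about the
#' plane normal oriented toward +z (i.e. as seen looking along -z, the
#' camera viewpoint of an inverted microscope).  The standard error is taken
#' from the dispersion of slopes over 8 non-overlapping blocks, which stays
#' calibrated when the phase noise is Brownian rather than independent.
#'
#' @param traj a [Trajectory3D].
#' @param plane a `PlaneFit`.
#' @param circle a `CircleFit`.
#' @return A `RateEstimate` (rate in Hz, >= 0, with a `direction` label).
#' @export
estimateRate <- function(traj, plane, circle) {
  up <- unwrapPhase(traj, plane, circle)
  if (abs(up$phase[length(up$phase)] - up$phase[1]) < 2 * pi)
    stop("insufficient rotation: less than one full turn")
  fit <- stats::lm(up$phase ~ up$times)
  slope <- unname(stats::coef(fit)[2])
  nb <- 8L
  n <- length(up$times)
  grp <- cut(seq_len(n), nb, labels = FALSE)
  slopes <- vapply(seq_len(nb), function(b) {
    i <- grp == b
    if (sum(i) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(up$phase[i] ~ up$times[i]))[2])
  }, numeric(1))
  slopes <- slopes[is.finite(slopes)]
  se <- stats::sd(slopes) / sqrt(length(slopes))
  new("RateEstimate", rate = abs(slope) / (2 * pi),
      direction = if (slope >= 0) "CCW" else "CW",
      phase = up$phase, times = up$times, rateSe = se / (2 * pi))
}

#' Quality control of a rotation trace
#'
#' Screens for the two trace pathologies excluded from torque estimation:
#' periodic speed changes with 60-degree periodicity (stepping signatures of
#' the hexameric motor) and long dwells (saw-tooth rotation).  The phase is
#' folded modulo 60 degrees into 12 bins of 5 degrees; the mean angular
#' speed in each bin is estimated from the bin occupancy (time spent per
#' bin, whose inverse is proportional to the local speed), which stays
#' calibrated under Brownian phase noise where per-frame speeds do not;
#' `modulationDepth60` is (max - min)/mean of the 12 bin speeds.  A trace is
#' `smooth` when no 60-degree sector crossing takes longer than
#' `dwellFactor` times the median crossing interval, and `accepted` when it
#' is smooth and the modulation depth is below `depthThreshold`.
#'
#' @param traj a [Trajectory3D].
#' @param plane a `PlaneFit`.
#' @param circle a `CircleFit`.
#' @param depthThreshold maximum accepted modulation depth; default 0.5.
#' @param dwellFactor dwell rejection multiple; default 5.
#' @return A `QCReport`.
#' @export
qcTrace <- function(traj, plane, circle, depthThreshold = 0.5, dwellFactor = 5) {
  up <- unwrapPhase(traj, plane, circle)
  t <- up$times
  ph <- up$phase
  dt <- stats::median(diff(t))
  binPh <- (ph * 180 / pi) %% 60
  bins <- pmin(floor(binPh / 5) + 1L, 12L)
  occ <- pmax(tabulate(bins, 12L), 1L) * dt   # time spent per 5-degree bin
  spd <- 1 / occ                              # proportional to local speed
  depth <- (max(spd) - min(spd)) / mean(spd)
  # 60-degree sector crossing intervals of the monotone phase envelope
  prog <- abs(ph - ph[1])
  prog <- cummax(prog)
  sect <- floor(prog / (pi / 3))
  cross <- t[which(diff(sect) > 0) + 1L]
  smooth <- TRUE
  if (length(cross) >= 6) {
    iv <- diff(cross)
    smooth <- max(iv) < dwellFactor * stats::median(iv)
  }
  accepted <- smooth && depth < depthThreshold
  reason <- if (accepted) "ok" else if (!smooth)
    "dwell longer than 5x median inter-step interval" else
    sprintf("60-degree speed modulation depth %.2f >= %.2f", depth, depthThreshold)
  new("QCReport", modulationDepth60 = unname(depth), smooth = smooth,
      accepted = accepted, reason = reason)
}

#' Full geometric analysis of one trajectory
#'
#' Convenience wrapper running [findRotationPlane()],
#' [projectAndFitCircle()], [estimateRate()] and [qcTrace()].
#'
#' @param traj a [Trajectory3D].
#' @param depthThreshold,dwellFactor passed to [qcTrace()].
#' @return A list with elements `plane`, `circle`, `rate`, `qc`.
#' @export
analyzeTrajectory <- function(traj, depthThreshold = 0.5, dwellFactor = 5) {
  plane <- findRotationPlane(traj)
  circle <- projectAndFitCircle(traj, plane)
  rate <- estimateRate(traj, plane, circle)
  qc <- qcTrace(traj, plane, circle, depthThreshold, dwellFactor)
  list(plane = plane, circle = circle, rate = rate, qc = qc)
}
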