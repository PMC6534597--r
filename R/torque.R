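## Constant-torque inference: assemble (gamma, f) pairs from analyzed
## markers and fit f = T_a / (2 pi (gamma + gamma_a)), raw and
## wall-corrected, with bootstrap uncertainties.

#' Fill drag coefficients of a marker dataset
#'
#' Computes the raw and wall-corrected drag of every marker from its
#' geometry: spheres through [sphereDrag()] (correction per
#' [wallCorrection()]), tethered cells through [rodDragTethered()] (for
#' which no wall correction is applied, so both columns coincide).
#'
#' @param dataset a [MarkerDataset].
#' @param eta viscosity (Pa s).
#' @return The dataset with `gamma_raw` and `gamma_corrected` columns
#'   filled.
#' @export
markerFriction <- function(dataset, eta = 1.35e-3) {
  stopifnot(is(dataset, "MarkerDataset"))
  rec <- records(dataset)
  gr <- gc <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (rec$kind[i] == "sphere") {
      if (!is.finite(rec$diameter_nm[i]) || !is.finite(rec$rotation_radius_nm[i]))
        stop("schema error: sphere marker ", rec$marker_id[i],
             " lacks diameter or rotation radius")
      d <- sphereDrag(r = rec$diameter_nm[i] / 2, R = rec$rotation_radius_nm[i],
                      eta = eta, wallGap = rec$wall_gap_nm[i])
      gr[i] <- d@gamma
      gc[i] <- d@gammaCorrected
    } else if (rec$kind[i] == "rod") {
      if (!is.finite(rec$cell_length_nm[i]) || !is.finite(rec$cell_radius_nm[i]))
        stop("schema error: rod marker ", rec$marker_id[i],
             " lacks cell length or radius")
      d <- rodDragTethered(rec$cell_length_nm[i], rec$cell_radius_nm[i], eta)
      gr[i] <- gc[i] <- d@gamma
    } else {
      stop("schema error: markers must be spheres or rods, got '",
           rec$kind[i], "'")
    }
  }
  rec$gamma_raw <- gr
  rec$gamma_corrected <- gc
  initialize(dataset, records = rec)
}

#' Profiled least-squares fit of the constant-torque model
#'
#' For fixed gamma_a the model is linear in T_a, so the fit reduces to a 1-D
#' optimisation of the profiled residual sum of squares over gamma_a >= 0.
#' @noRd
profileTorqueFit <- function(gamma, f, w = NULL) {
  if (is.null(w)) w <- rep(1, length(f))
  TaOf <- function(ga) {
    x <- 1 / (2 * pi * (gamma + ga))
    sum(w * f * x) / sum(w * x * x)
  }
  ssr <- function(ga) {
    x <- 1 / (2 * pi * (gamma + ga))
    Ta <- sum(w * f * x) / sum(w * x * x)
    sum(w * (f - Ta * x)^2)
  }
  upper <- max(gamma)
  opt <- stats::optimize(ssr, interval = c(0, upper), tol = 1e-10)
  ga <- opt$minimum
  if (ssr(0) <= opt$objective) ga <- 0
  list(torque = TaOf(ga), gammaA = ga, ssr = ssr(ga),
       boundary = ga < 1e-8)
}

#' Fit the constant-torque model to a marker dataset
#'
#' Nonlinear least squares of \eqn{f = T_a/(2\pi(\gamma + \gamma_a))} over
#' the QC-accepted markers, using either the raw or the wall-corrected drag.
#' Points are weighted by `1/rate_se_hz^2` when a `rate_se_hz` column is
#' present, otherwise unweighted.  Since \eqn{T_a} enters linearly, the fit
#' profiles it in closed form and optimises the residual sum of squares
#' over \eqn{\gamma_a \ge 0} alone, which has the same optimum as the usual
#' linearization-initialized Gauss-Newton iteration.  95% confidence
#' intervals come from a seeded case-resampling bootstrap.
#'
#' @param dataset a [MarkerDataset]; `gamma_*` columns are computed with
#'   [markerFriction()] if absent.
#' @param variant `"corrected"` (default) or `"raw"`.
#' @param bootstrap number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param eta viscosity used if drags must be computed (Pa s).
#' @return A [TorqueFit].
#' @examples
#' ds <- buildBenchmarkDataset(seed = 1)
#' fit <- fitConstantTorque(ds, bootstrap = 200, seed = 1)
#' torque(fit); internalFriction(fit); confint(fit)
#' @export
fitConstantTorque <- function(dataset, variant = c("corrected", "raw"),
                              bootstrap = 1000L, seed = NA_integer_,
                              eta = 1.35e-3) {
  variant <- match.arg(variant)
  stopifnot(is(dataset, "MarkerDataset"))
  if (!"gamma_corrected" %in% names(records(dataset)))
    dataset <- markerFriction(dataset, eta = eta)
  rec <- records(dataset)
  if ("qc_accepted" %in% names(rec)) rec <- rec[rec$qc_accepted %in% TRUE, ]
  rec <- rec[is.finite(rec$rate_hz) & rec$rate_hz > 0, ]
  gamma <- if (variant == "corrected") rec$gamma_corrected else rec$gamma_raw
  f <- rec$rate_hz
  if (length(f) < 3L) stop("need at least 3 accepted markers")
  if (length(unique(gamma)) < 2L)
    stop("identifiability error: all drag coefficients equal")
  if (max(gamma) / min(gamma) < 10)
    warning("drag coefficients span less than one decade; ",
            "T_a and gamma_a are weakly identified")
  w <- if ("rate_se_hz" %in% names(rec) && all(is.finite(rec$rate_se_hz)) &&
           all(rec$rate_se_hz > 0)) 1 / rec$rate_se_hz^2 else NULL
  fit <- profileTorqueFit(gamma, f, w)
  if (fit$boundary && fit$gammaA == 0)
    message("gamma_a at the zero boundary; reporting gamma_a = 0")
  n <- length(f)
  # asymptotic covariance from the Jacobian at the optimum
  x <- 1 / (2 * pi * (gamma + fit$gammaA))
  J <- cbind(x, -2 * pi * fit$torque * x^2)
  W <- if (is.null(w)) rep(1, n) else w
  s2 <- fit$ssr / max(n - 2, 1)
  covm <- tryCatch(s2 * solve(crossprod(J * sqrt(W))),
                   error = function(e) matrix(NA_real_, 2, 2))
  dimnames(covm) <- list(c("torque", "internalFriction"),
                         c("torque", "internalFriction"))
  boot <- withSeed(seed, {
    t(vapply(seq_len(bootstrap), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      bf <- profileTorqueFit(gamma[i], f[i], if (is.null(w)) NULL else w[i])
      c(bf$torque, bf$gammaA)
    }, numeric(2)))
  })
  ci <- rbind(torque = stats::quantile(boot[, 1], c(0.025, 0.975), names = FALSE),
              internalFriction = stats::quantile(boot[, 2], c(0.025, 0.975),
                                                 names = FALSE))
  colnames(ci) <- c("2.5%", "97.5%")
  est <- c(fit$torque, fit$gammaA)
  ci[, 1] <- pmin(ci[, 1], est)
  ci[, 2] <- pmax(ci[, 2], est)
  new("TorqueFit", torque = fit$torque, internalFriction = fit$gammaA,
      cov = covm, ci = ci, variant = variant, nMarkers = as.integer(n),
      bootstrap = list(B = as.integer(bootstrap), seed = seed, draws = boot))
}

#' Apparent-torque table
#'
#' For every accepted marker, the apparent torque \eqn{2\pi\gamma f} (load
#' contribution only) and the total \eqn{2\pi(\gamma + \gamma_a) f}.  Under
#' the constant-torque model the latter scatters around \eqn{T_a} with no
#' trend in rate, while the former declines with rate whenever
#' \eqn{\gamma_a > 0}.
#'
#' @param dataset a [MarkerDataset].
#' @param fit a [TorqueFit]; its variant selects raw or corrected drags.
#' @param eta viscosity used if drags must be computed (Pa s).
#' @return A data.frame with columns `marker_id`, `rate_hz`,
#'   `apparent_torque` and `apparent_torque_total` (pN nm).
#' @export
apparentTorqueCurve <- function(dataset, fit, eta = 1.35e-3) {
  stopifnot(is(dataset, "MarkerDataset"), is(fit, "TorqueFit"))
  if (!"gamma_corrected" %in% names(records(dataset)))
    dataset <- markerFriction(dataset, eta = eta)
  rec <- records(dataset)
  if ("qc_accepted" %in% names(rec)) rec <- rec[rec$qc_accepted %in% TRUE, ]
  gamma <- if (fit@variant == "corrected") rec$gamma_corrected else rec$gamma_raw
  data.frame(marker_id = rec$marker_id, rate_hz = rec$rate_hz,
             apparent_torque = 2 * pi * gamma * rec$rate_hz,
             apparent_torque_total = 2 * pi * (gamma + fit@internalFriction) *
               rec$rate_hz)
}

#' Equivalence of the stepping-motor and internal-friction parameterizations
#'
#' A motor with a rate-limiting chemical step,
#' \eqn{f(\gamma) = (1/f_{noload} + 2\pi\gamma/T_a)^{-1}}, traces exactly
#' the curve \eqn{f = T_a/(2\pi(\gamma+\gamma_a))} with
#' \eqn{\gamma_a = T_a/(2\pi f_{noload})}; the two functions convert
#' between the parameterizations.
#'
#' @param torque motor torque (pN nm).
#' @param fNoLoad zero-load rotation rate (Hz).
#' @param internalFriction internal friction constant (pN nm s).
#' @return `modelBFriction()` the equivalent \eqn{\gamma_a};
#'   `modelBNoLoadRate()` the equivalent \eqn{f_{noload}}.
#' @examples
#' modelBNoLoadRate(160, 0.81)          # ~31.4 Hz
#' modelBFriction(160, modelBNoLoadRate(160, 0.81))
#' @export
modelBFriction <- function(torque, fNoLoad) {
  if (any(!is.finite(torque) | torque <= 0)) stop("'torque' must be > 0")
  if (any(!is.finite(fNoLoad) | fNoLoad <= 0)) stop("'fNoLoad' must be > 0")
  torque / (2 * pi * fNoLoad)
}

#' @rdname modelBFriction
#' @export
modelBNoLoadRate <- function(torque, internalFriction) {
  if (any(!is.finite(torque) | torque <= 0)) stop("'torque' must be > 0")
  if (any(!is.finite(internalFriction) | internalFriction <= 0))
    stop("'internalFriction' must be > 0")
  torque / (2 * pi * internalFriction)
}

#' Linear fit of rotation rate versus bead diameter
#'
#' Least squares of \eqn{f = A\,\phi + B} over the sphere markers: `B` is
#' the zero-size (zero-load) intercept and `A` the (negative) slope with
#' diameter.
#'
#' @param dataset a [MarkerDataset]; only sphere records are used.
#' @return A list with `A` (Hz/nm), `B` (Hz), their standard errors `seA`,
#'   `seB`, and the underlying `lm` fit.
#' @export
fitRateVsDiameter <- function(dataset) {
  stopifnot(is(dataset, "MarkerDataset"))
  rec <- records(dataset)
  rec <- rec[rec$kind == "sphere" & is.finite(rec$rate_hz), ]
  if (length(unique(rec$diameter_nm)) < 2L)
    stop("identifiability error: need at least two distinct bead diameters")
  fit <- stats::lm(rate_hz ~ diameter_nm, data = rec)
  sm <- summary(fit)$coefficients
  list(A = unname(stats::coef(fit)[2]), B = unname(stats::coef(fit)[1]),
       seA = if (nrow(rec) > 2) sm[2, 2] else NA_real_,
       seB = if (nrow(rec) > 2) sm[1, 2] else NA_real_,
       fit = fit)
}
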