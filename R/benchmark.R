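## Synthetic benchmark dataset: markers in four size classes with rotation
## rates drawn from the generative motor model plus measurement noise.

#' Default benchmark configuration
#'
#' Study conditions of the reference marker survey: 32 beads of 210 nm, 31
#' of 490 nm, 26 of 1.0 um, and 12 tethered cells, driven by a 160 pN nm
#' constant-torque motor with internal friction 0.81 pN nm s.  Rotation
#' radii and cell lengths vary across markers; measured rates carry 10%
#' multiplicative Gaussian noise.
#'
#' @param torque,internalFriction generator motor parameters.
#' @param rateCV coefficient of variation of the multiplicative measurement
#'   noise on rates.
#' @param eta viscosity (Pa s).
#' @return A configuration list for [buildBenchmarkDataset()].
#' @export
benchmarkConfig <- function(torque = 160, internalFriction = 0.81,
                            rateCV = 0.10, eta = 1.35e-3) {
  list(
    motor = MotorParams(torque = torque, internalFriction = internalFriction),
    rateCV = rateCV,
    eta = eta,
    classes = list(
      list(kind = "sphere", diameter = 210, n = 32,
           rotationRadiusRange = c(150, 350), wallGap = 500),
      list(kind = "sphere", diameter = 490, n = 31,
           rotationRadiusRange = c(150, 350), wallGap = 500),
      list(kind = "sphere", diameter = 1000, n = 26,
           rotationRadiusRange = c(150, 350), wallGap = 500),
      list(kind = "rod", n = 12, cellLengthRange = c(2000, 4000),
           cellRadius = 250)))
}

#' Build a synthetic benchmark marker dataset
#'
#' Draws marker geometries from the configured size classes, computes each
#' marker's true (wall-corrected) drag, assigns the mean rate of the
#' generative motor model at that drag, and applies multiplicative Gaussian
#' measurement noise.  Fully reproducible for a given seed.
#'
#' @param config a configuration list as returned by [benchmarkConfig()].
#' @param seed integer RNG seed.
#' @return A [MarkerDataset] whose `params` record the generator settings.
#' @examples
#' ds <- buildBenchmarkDataset(seed = 1)
#' table(records(ds)$kind)
#' @export
buildBenchmarkDataset <- function(config = benchmarkConfig(), seed = NA_integer_) {
  if (is.null(config$classes) || length(config$classes) == 0L)
    stop("config error: empty size-class list")
  withSeed(seed, {
    rows <- list()
    id <- 0L
    for (cl in config$classes) {
      for (i in seq_len(cl$n)) {
        id <- id + 1L
        if (cl$kind == "sphere") {
          R <- stats::runif(1, cl$rotationRadiusRange[1], cl$rotationRadiusRange[2])
          geom <- sphereMarker(cl$diameter, R, cl$wallGap)
          row <- data.frame(marker_id = sprintf("m%03d", id), kind = "sphere",
                            diameter_nm = cl$diameter, rotation_radius_nm = R,
                            cell_length_nm = NA_real_, cell_radius_nm = NA_real_,
                            wall_gap_nm = cl$wallGap)
        } else if (cl$kind == "rod") {
          L <- stats::runif(1, cl$cellLengthRange[1], cl$cellLengthRange[2])
          geom <- rodMarker(L, cl$cellRadius)
          row <- data.frame(marker_id = sprintf("m%03d", id), kind = "rod",
                            diameter_nm = NA_real_, rotation_radius_nm = NA_real_,
                            cell_length_nm = L, cell_radius_nm = cl$cellRadius,
                            wall_gap_nm = NA_real_)
        } else stop("config error: unknown marker kind '", cl$kind, "'")
        gamma <- dragCoefficient(markerDrag(geom, eta = config$eta))
        f <- predictedRate(config$motor, gamma)
        fObs <- f * (1 + config$rateCV * stats::rnorm(1))
        while (fObs <= 0) fObs <- f * (1 + config$rateCV * stats::rnorm(1))
        row$rate_hz <- fObs
        row$direction <- sample(c("CW", "CCW"), 1)
        rows[[id]] <- row
      }
    }
    MarkerDataset(do.call(rbind, rows),
                  params = list(torque = config$motor@torque,
                                internalFriction = config$motor@internalFriction,
                                mode = config$motor@mode,
                                rateCV = config$rateCV, eta = config$eta,
                                seed = seed))
  })
}
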