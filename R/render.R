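## Forward optical model: render prism-split dual-spot image stacks from a
## 3D trajectory.  Image convention: origin at the top-left pixel centre,
## x rightward along columns, y downward along rows, 0-based pixel indices;
## physical nm coordinates map to pixels through the origin stored in the
## stack metadata (x_px = (x_nm - origin_x) / pixelSize).  z is positive
## away from the coverslip.

#' Pixel-integrated 1D Gaussian profile
#' @noRd
pixGauss <- function(idx, center, sigma) {
  stats::pnorm((idx + 0.5 - center) / sigma) -
    stats::pnorm((idx - 0.5 - center) / sigma)
}

#' Render a dual-spot image stack from a 3D trajectory
#'
#' Each frame contains two pixel-integrated Gaussian spots placed
#' symmetrically about the projected lateral position along the prism axis;
#' their separation encodes the axial position as
#' `baselineSeparation + axialGain * z`.  Poisson shot noise and Gaussian
#' read noise are applied when requested.
#'
#' @param traj a [Trajectory3D] (ground truth).
#' @param optics an [OpticsParams].
#' @param shotNoise logical; apply Poisson shot noise and read noise.
#' @param seed RNG seed for the noise (or `NA`).
#' @return An [ImageStack].  Metadata records the nm origin of the pixel
#'   grid, the frame times, and indices of frames whose spot pair is closer
#'   than the separability threshold (4 PSF sigma), if any, under
#'   `overlapFrames` with a warning flag.
#' @examples
#' tr <- Trajectory3D((0:199) * 5e-4,
#'                    cbind(250 * cos(2 * pi * 20 * (0:199) * 5e-4),
#'                          250 * sin(2 * pi * 20 * (0:199) * 5e-4), 0))
#' st <- renderDualImageStack(tr, OpticsParams(), seed = 1)
#' nFrames(st)
#' @export
renderDualImageStack <- function(traj, optics, shotNoise = TRUE, seed = NA_integer_) {
  stopifnot(is(traj, "Trajectory3D"), is(optics, "OpticsParams"))
  pos <- positions(traj)
  W <- optics@fieldWidth
  H <- optics@fieldHeight
  pix <- optics@pixelSize
  # centre the trajectory (plus its prism-split extent) in the field of view
  origin <- c(mean(range(pos[, 1])) - (W - 1) / 2 * pix,
              mean(range(pos[, 2])) - (H - 1) / 2 * pix)
  sep <- optics@baselineSeparation + optics@axialGain * pos[, 3]
  off <- outer(sep / 2, optics@prismAxis)            # nm offsets of each spot
  s1 <- cbind(pos[, 1] - off[, 1], pos[, 2] - off[, 2])
  s2 <- cbind(pos[, 1] + off[, 1], pos[, 2] + off[, 2])
  px1 <- sweep(s1, 2, origin) / pix
  px2 <- sweep(s2, 2, origin) / pix
  margin <- 3 * optics@psfSigma / pix
  if (any(px1 < margin - 0.5) || any(px2 < margin - 0.5) ||
      any(px1[, 1] > W - 1 - margin) || any(px2[, 1] > W - 1 - margin) ||
      any(px1[, 2] > H - 1 - margin) || any(px2[, 2] > H - 1 - margin))
    stop("trajectory (with prism split) does not fit in the field of view; ",
         "enlarge 'fieldWidth'/'fieldHeight'")
  sigma <- optics@psfSigma / pix
  nF <- nrow(pos)
  frames <- array(0, dim = c(H, W, nF))
  xi <- 0:(W - 1)
  yi <- 0:(H - 1)
  expectFrame <- function(i) {
    e <- optics@background +
      optics@photonsPerSpot * (pixGauss(yi, px1[i, 2], sigma) %o% pixGauss(xi, px1[i, 1], sigma)) +
      optics@photonsPerSpot * (pixGauss(yi, px2[i, 2], sigma) %o% pixGauss(xi, px2[i, 1], sigma))
    e
  }
  withSeed(seed, {
    for (i in seq_len(nF)) {
      e <- expectFrame(i)
      if (shotNoise) {
        f <- stats::rpois(length(e), e)
        if (optics@readNoise > 0)
          f <- f + stats::rnorm(length(f), sd = optics@readNoise)
        frames[, , i] <- pmin(pmax(round(f), 0), 65535)
      } else {
        frames[, , i] <- e
      }
    }
  })
  meta <- list(pixel_nm = pix, dt_s = optics@frameInterval,
               axial_gain = optics@axialGain,
               baseline = optics@baselineSeparation,
               origin_nm = origin, times_s = times(traj))
  overlap <- which(abs(sep) < 4 * optics@psfSigma)
  if (length(overlap)) {
    warning("spot pairs overlap beyond the separability threshold in ",
            length(overlap), " frame(s)")
    meta$overlapFrames <- overlap
  }
  ImageStack(frames = frames, optics = optics, metadata = meta)
}

#' Render a calibration stack at known axial positions
#'
#' Renders one stationary spot pair per z value, recording the true z in the
#' stack metadata; input to [calibrateAxial()].
#'
#' @param z numeric vector of known axial positions (nm).
#' @param optics an [OpticsParams].
#' @param framesPerZ frames rendered at each z.
#' @param shotNoise,seed as in [renderDualImageStack()].
#' @return An [ImageStack] with `metadata$z_nm` of length `nFrames`.
#' @export
renderCalibrationStack <- function(z, optics, framesPerZ = 1L,
                                   shotNoise = FALSE, seed = NA_integer_) {
  zAll <- rep(as.numeric(z), each = framesPerZ)
  n <- length(zAll)
  tr <- Trajectory3D(times = seq_len(n) * optics@frameInterval,
                     positions = cbind(0, 0, zAll))
  st <- renderDualImageStack(tr, optics, shotNoise = shotNoise, seed = seed)
  st@metadata$z_nm <- zAll
  st
}
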