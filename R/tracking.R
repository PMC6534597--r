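## Recover 3D trajectories from prism-split dual-spot stacks: sub-pixel 2D
## localization, axial calibration of the spot-pair separation, and 3D
## reconstruction.

#' Sub-pixel spot localization in a single frame
#'
#' Detects intensity maxima above a threshold and refines each to sub-pixel
#' precision by least-squares fit of a pixel-integrated 2D Gaussian (PSF
#' sigma taken from `optics`) in a window around the maximum.  The window
#' background is fixed at the window-edge median; the amplitude is profiled
#' analytically, leaving a 2-parameter optimisation over the centre.
#'
#' @param frame numeric matrix (height x width) of counts.
#' @param optics an [OpticsParams].
#' @param maxSpots maximum number of spots returned (brightest first).
#' @param threshold detection threshold in counts; default
#'   `median + 8 * mad` of the frame.
#' @param window odd window size in pixels; default 7.
#' @return A data.frame with one row per spot: `x_px`, `y_px` (0-based pixel
#'   coordinates), `intensity` (fitted photons), `residual` (RMS of the fit)
#'   and `flag` (`"ok"`, `"edge"` or `"merged"`).  Zero rows (with the same
#'   columns) when nothing exceeds the threshold.
#' @examples
#' st <- renderCalibrationStack(0, OpticsParams())
#' localizeSpots(st@frames[, , 1], OpticsParams())
#' @export
localizeSpots <- function(frame, optics, maxSpots = 2L, threshold = NULL,
                          window = 7L) {
  stopifnot(is.matrix(frame), is(optics, "OpticsParams"))
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), residual = numeric(0),
                      flag = character(0))
  if (is.null(threshold))
    threshold <- max(stats::median(frame) + 8 * stats::mad(frame),
                     0.1 * max(frame))
  h <- nrow(frame); w <- ncol(frame)
  half <- (window - 1L) %/% 2L
  # local maxima in a 3x3 neighbourhood, above threshold
  cand <- which(frame > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  isMax <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    ii <- max(1, i - 1):min(h, i + 1)
    jj <- max(1, j - 1):min(w, j + 1)
    frame[i, j] >= max(frame[ii, jj])
  }, logical(1))
  cand <- cand[isMax, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  ord <- order(frame[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  # greedy suppression of maxima closer than one window
  keep <- rep(TRUE, nrow(cand))
  merged <- rep(FALSE, nrow(cand))
  for (k in seq_len(nrow(cand))[-1]) {
    d <- abs(cand[seq_len(k - 1), , drop = FALSE] -
             matrix(cand[k, ], k - 1, 2, byrow = TRUE))
    close <- keep[seq_len(k - 1)] & apply(d, 1, max) < window
    if (any(close)) {
      keep[k] <- FALSE
      # flag the survivor only if the suppressed peak is a real rival spot,
      # not a background fluctuation
      rival <- frame[cand[k, 1], cand[k, 2]] >
        0.2 * frame[cand[close, , drop = FALSE][1, 1], cand[close, , drop = FALSE][1, 2]]
      if (rival) merged[close] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  merged <- merged[keep]
  nS <- min(nrow(cand), maxSpots)
  sigma <- optics@psfSigma / optics@pixelSize
  out <- lapply(seq_len(nS), function(k) {
    i0 <- cand[k, 1]; j0 <- cand[k, 2]
    flag <- if (merged[k]) "merged" else "ok"
    ii <- (i0 - half):(i0 + half)
    jj <- (j0 - half):(j0 + half)
    if (any(ii < 1) || any(ii > h) || any(jj < 1) || any(jj > w)) {
      flag <- "edge"
      ii <- ii[ii >= 1 & ii <= h]
      jj <- jj[jj >= 1 & jj <= w]
    }
    win <- frame[ii, jj, drop = FALSE]
    fit <- fitIntegratedGaussian(win, rowIdx = ii - 1, colIdx = jj - 1, sigma = sigma)
    data.frame(x_px = fit$x, y_px = fit$y, intensity = fit$A,
               residual = fit$rms, flag = flag)
  })
  do.call(rbind, out)
}

#' Least-squares integrated-Gaussian fit in a window
#'
#' Background fixed at the window-edge median; amplitude profiled in closed
#' form; Nelder-Mead over the centre.
#' @noRd
fitIntegratedGaussian <- function(win, rowIdx, colIdx, sigma) {
  bg <- stats::median(c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)]))
  d <- win - bg
  tot <- sum(d)
  if (tot <= 0) tot <- 1e-9
  y0 <- sum(rowIdx * rowSums(d)) / tot
  x0 <- sum(colIdx * colSums(d)) / tot
  y0 <- min(max(y0, min(rowIdx)), max(rowIdx))
  x0 <- min(max(x0, min(colIdx)), max(colIdx))
  ssr <- function(par) {
    g <- pixGauss(rowIdx, par[2], sigma) %o% pixGauss(colIdx, par[1], sigma)
    A <- sum(d * g) / max(sum(g * g), 1e-12)
    sum((d - A * g)^2)
  }
  opt <- stats::optim(c(x0, y0), ssr, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 400))
  g <- pixGauss(rowIdx, opt$par[2], sigma) %o% pixGauss(colIdx, opt$par[1], sigma)
  A <- sum(d * g) / max(sum(g * g), 1e-12)
  list(x = opt$par[1], y = opt$par[2], A = A,
       rms = sqrt(opt$value / length(win)))
}

#' Pair the two prism-split spots of one frame
#'
#' Orders candidate spots along the prism axis and accepts the pair whose
#' separation lies within +/-30% of the baseline separation.
#' @noRd
pairSpots <- function(spots, optics) {
  if (nrow(spots) < 2L) return(NULL)
  pix <- optics@pixelSize
  proj <- (spots$x_px * optics@prismAxis[1] + spots$y_px * optics@prismAxis[2]) * pix
  best <- NULL
  for (a in seq_len(nrow(spots) - 1L)) {
    for (b in (a + 1L):nrow(spots)) {
      s <- abs(proj[b] - proj[a])
      if (s > 0.7 * optics@baselineSeparation && s < 1.3 * optics@baselineSeparation) {
        if (is.null(best) || spots$intensity[a] + spots$intensity[b] > best$sumInt)
          best <- list(i = a, j = b, sumInt = spots$intensity[a] + spots$intensity[b])
      }
    }
  }
  best
}

#' Calibrate the axial encoding of the spot-pair separation
#'
#' Localizes the spot pair in each frame of a calibration stack recorded at
#' known axial positions and fits the least-squares line of separation
#' versus z.
#'
#' @param stack an [ImageStack] whose `metadata$z_nm` gives the true z of
#'   each frame (as written by [renderCalibrationStack()]).
#' @param optics an [OpticsParams]; defaults to the stack's own.
#' @return An [AxialCalibration].
#' @examples
#' st <- renderCalibrationStack(c(-200, 0, 200), OpticsParams())
#' calibrateAxial(st)
#' @export
calibrateAxial <- function(stack, optics = stack@optics) {
  stopifnot(is(stack, "ImageStack"))
  z <- stack@metadata$z_nm
  if (is.null(z)) stop("calibration stack must carry metadata$z_nm")
  if (length(unique(z)) < 3L)
    stop("axial calibration needs at least 3 distinct z positions")
  sep <- vapply(seq_len(nFrames(stack)), function(i) {
    sp <- localizeSpots(stack@frames[, , i], optics)
    pr <- pairSpots(sp, optics)
    if (is.null(pr)) return(NA_real_)
    dx <- (sp$x_px[pr$j] - sp$x_px[pr$i]) * optics@pixelSize
    dy <- (sp$y_px[pr$j] - sp$y_px[pr$i]) * optics@pixelSize
    abs(dx * optics@prismAxis[1] + dy * optics@prismAxis[2])
  }, numeric(1))
  ok <- is.finite(sep)
  if (sum(ok) < 3L) stop("too few frames with a localizable spot pair")
  fit <- stats::lm(sep[ok] ~ z[ok])
  AxialCalibration(slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   residualRms = sqrt(mean(stats::residuals(fit)^2)))
}

#' Reconstruct a 3D trajectory from a dual-spot stack
#'
#' Localizes and pairs the two spots in every frame; the lateral position is
#' the midpoint of the pair (the symmetric prism offsets cancel), converted
#' to nm through the pixel origin stored in the stack metadata, and the
#' axial position is decoded from the pair separation through the
#' calibration, `z = (separation - intercept) / slope`.  Frames in which
#' localization or pairing fails are flagged (`"pairing"`), not dropped;
#' if more than 20% of frames fail the stack is rejected.
#'
#' @param stack an [ImageStack].
#' @param calibration an [AxialCalibration].
#' @param optics an [OpticsParams]; defaults to the stack's own.
#' @return A [Trajectory3D].
#' @export
reconstruct3D <- function(stack, calibration, optics = stack@optics) {
  stopifnot(is(stack, "ImageStack"), is(calibration, "AxialCalibration"))
  nF <- nFrames(stack)
  pix <- optics@pixelSize
  origin <- stack@metadata$origin_nm
  if (is.null(origin)) origin <- c(0, 0)
  tt <- stack@metadata$times_s
  if (is.null(tt)) tt <- seq_len(nF) * optics@frameInterval
  pos <- matrix(NA_real_, nF, 3)
  flags <- rep("ok", nF)
  for (i in seq_len(nF)) {
    sp <- localizeSpots(stack@frames[, , i], optics)
    pr <- pairSpots(sp, optics)
    if (is.null(pr)) { flags[i] <- "pairing"; next }
    xm <- (sp$x_px[pr$i] + sp$x_px[pr$j]) / 2 * pix + origin[1]
    ym <- (sp$y_px[pr$i] + sp$y_px[pr$j]) / 2 * pix + origin[2]
    dx <- (sp$x_px[pr$j] - sp$x_px[pr$i]) * pix
    dy <- (sp$y_px[pr$j] - sp$y_px[pr$i]) * pix
    sep <- abs(dx * optics@prismAxis[1] + dy * optics@prismAxis[2])
    pos[i, ] <- c(xm, ym, (sep - calibration@intercept) / calibration@slope)
    if (any(sp$flag[c(pr$i, pr$j)] != "ok")) flags[i] <- sp$flag[pr$i]
  }
  failed <- mean(flags == "pairing")
  if (failed > 0.2)
    stop(sprintf("stack rejected: %.0f%% of frames failed spot pairing", 100 * failed))
  Trajectory3D(times = tt, positions = pos, flags = flags)
}
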