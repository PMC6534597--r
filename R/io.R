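## File formats: trajectory CSV, marker-dataset CSV, 16-bit multi-page TIFF
## with a JSON metadata sidecar, analysis-record JSON, YAML pipeline config.

#' Format numeric columns at full (round-tripping) precision
#' @noRd
fullPrecision <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) {
      s <- sprintf("%.17g", df[[j]])
      s[is.na(df[[j]])] <- "NA"
      df[[j]] <- s
    }
  df
}

#' Read and write trajectory CSV files
#'
#' The trajectory dialect has a header and columns `t_s, x_nm, y_nm, z_nm`
#' (UTF-8, '.' decimal); an optional `flag` column carries per-frame QC
#' flags and round-trips when present.
#'
#' @param traj a [Trajectory3D].
#' @param path file path.
#' @return `readTrajectoryCsv()` a [Trajectory3D]; `writeTrajectoryCsv()`
#'   the path, invisibly.
#' @examples
#' tr <- Trajectory3D((1:100) * 5e-4, cbind(cos(1:100), sin(1:100), 0) * 250)
#' p <- tempfile(fileext = ".csv")
#' writeTrajectoryCsv(tr, p)
#' tr2 <- readTrajectoryCsv(p)
#' @export
writeTrajectoryCsv <- function(traj, path) {
  stopifnot(is(traj, "Trajectory3D"))
  df <- data.frame(t_s = times(traj), x_nm = positions(traj)[, 1],
                   y_nm = positions(traj)[, 2], z_nm = positions(traj)[, 3])
  if (any(frameFlags(traj) != "ok")) df$flag <- frameFlags(traj)
  utils::write.csv(fullPrecision(df), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTrajectoryCsv
#' @export
readTrajectoryCsv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("t_s", "x_nm", "y_nm", "z_nm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory CSV lacks columns: ", paste(miss, collapse = ", "))
  Trajectory3D(times = df$t_s,
               positions = as.matrix(df[, c("x_nm", "y_nm", "z_nm")]),
               flags = if ("flag" %in% names(df)) as.character(df$flag)
                       else rep("ok", nrow(df)))
}

#' Read and write marker-dataset CSV files
#'
#' Dialect: `marker_id, kind, diameter_nm, rotation_radius_nm,
#' cell_length_nm, cell_radius_nm, wall_gap_nm, rate_hz, direction`, plus
#' any additional numeric columns present (drags, QC, rate SEs), which
#' round-trip.
#'
#' @param dataset a [MarkerDataset].
#' @param path file path.
#' @return `readMarkerDatasetCsv()` a [MarkerDataset];
#'   `writeMarkerDatasetCsv()` the path, invisibly.
#' @export
writeMarkerDatasetCsv <- function(dataset, path) {
  stopifnot(is(dataset, "MarkerDataset"))
  utils::write.csv(fullPrecision(records(dataset)), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeMarkerDatasetCsv
#' @export
readMarkerDatasetCsv <- function(path) {
  MarkerDataset(utils::read.csv(path, fileEncoding = "UTF-8",
                                stringsAsFactors = FALSE))
}

#' Write and read dual-spot image stacks
#'
#' Stacks are stored as 16-bit grayscale multi-page TIFF with a JSON
#' metadata sidecar (`<path>.json`) holding the pixel size, frame interval,
#' axial encoding, nm origin of the pixel grid and the optical parameters,
#' so that a stack re-read from disk can be tracked without further inputs.
#'
#' @param stack an [ImageStack].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `readImageStack()` an [ImageStack]; `writeImageStack()` the
#'   path, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  nF <- nFrames(stack)
  pages <- lapply(seq_len(nF), function(i)
    pmin(pmax(stack@frames[, , i], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  o <- stack@optics
  side <- c(stack@metadata,
            list(optics = list(pixelSize = o@pixelSize,
                               frameInterval = o@frameInterval,
                               psfSigma = o@psfSigma, prismAxis = o@prismAxis,
                               baselineSeparation = o@baselineSeparation,
                               axialGain = o@axialGain,
                               photonsPerSpot = o@photonsPerSpot,
                               readNoise = o@readNoise,
                               background = o@background,
                               fieldWidth = o@fieldWidth,
                               fieldHeight = o@fieldHeight)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- round(pages[[i]] * 65535)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("metadata sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ol <- meta$optics
  optics <- OpticsParams(pixelSize = ol$pixelSize, frameInterval = ol$frameInterval,
                         psfSigma = ol$psfSigma, prismAxis = ol$prismAxis,
                         baselineSeparation = ol$baselineSeparation,
                         axialGain = ol$axialGain, photonsPerSpot = ol$photonsPerSpot,
                         readNoise = ol$readNoise, background = ol$background,
                         fieldWidth = ol$fieldWidth, fieldHeight = ol$fieldHeight)
  meta$optics <- NULL
  ImageStack(frames = frames, optics = optics, metadata = meta)
}

#' Serialize one trajectory analysis to JSON
#'
#' @param analysis a list as returned by [analyzeTrajectory()].
#' @param path file path; when `NULL` the JSON-able list is returned
#'   instead.
#' @param extra named list merged into the record (e.g. marker identity,
#'   config hash).
#' @return The record list (invisibly when written).
#' @export
writeAnalysisJson <- function(analysis, path = NULL, extra = list()) {
  rec <- c(extra, list(
    plane = list(theta_deg = analysis$plane@theta, phi_deg = analysis$plane@phi,
                 center_nm = analysis$plane@center,
                 circularity_cv = analysis$plane@circularityScore,
                 out_of_plane_rms_nm = analysis$plane@outOfPlaneRms),
    circle = list(radius_nm = analysis$circle@radius,
                  center_nm = analysis$circle@center,
                  radial_rms_nm = analysis$circle@radialRms),
    rate = list(rate_hz = analysis$rate@rate, direction = analysis$rate@direction,
                rate_se_hz = analysis$rate@rateSe),
    qc = list(modulation_depth_60 = analysis$qc@modulationDepth60,
              smooth = analysis$qc@smooth, accepted = analysis$qc@accepted,
              reason = analysis$qc@reason)))
  if (is.null(path)) return(rec)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(rec)
}
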