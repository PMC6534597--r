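## End-to-end pipeline: simulate -> (render/track) -> analyze -> fit ->
## energetics, with a resolved-config snapshot and per-stage logging in a
## run directory.

pipelineSchema <- list(
  seed = NULL,
  stages = NULL,
  out = NULL,
  motor = c("torque", "internalFriction", "mode", "fNoLoad", "stepSize"),
  sim = c("dt", "kBT", "viscosity"),
  optics = c("pixelSize", "frameInterval", "psfSigma", "prismAxis",
             "baselineSeparation", "axialGain", "photonsPerSpot", "readNoise",
             "background", "fieldWidth", "fieldHeight"),
  markers = c("kind", "n", "diameter", "rotationRadius", "rotationRadiusRange",
              "wallGap", "cellLength", "cellLengthRange", "cellRadius",
              "renderImages", "duration", "revolutions"),
  qc = c("depthThreshold", "dwellFactor"),
  fit = c("variant", "bootstrap"),
  energetics = c("dgAtp", "nMax", "tolerance"))

#' Default pipeline configuration
#'
#' A small end-to-end configuration: three marker classes (210-nm and
#' 1.0-um beads, tethered cells), trajectories long enough for a handful of
#' revolutions each, the analysis and QC stages, the corrected-variant
#' torque fit and the energetics report.
#'
#' @param seed integer master seed; per-marker seeds are derived from it.
#' @return A named configuration list accepted by [runPipeline()].
#' @export
pipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "analyze", "fit", "energetics"),
    motor = list(torque = 160, internalFriction = 0.81, mode = "model_A"),
    sim = list(dt = 5e-4, kBT = 4.1, viscosity = 1.35e-3),
    optics = list(),
    markers = list(
      list(kind = "sphere", n = 3, diameter = 210, rotationRadius = 250,
           wallGap = 500, renderImages = FALSE, revolutions = 12),
      list(kind = "sphere", n = 3, diameter = 1000, rotationRadius = 250,
           wallGap = 500, renderImages = FALSE, revolutions = 12),
      list(kind = "rod", n = 3, cellLength = 2500, cellRadius = 250,
           revolutions = 12)),
    qc = list(depthThreshold = 0.5, dwellFactor = 5),
    fit = list(variant = "corrected", bootstrap = 500),
    energetics = list(dgAtp = 80, nMax = 6, tolerance = 0.10))
}

#' Validate a pipeline configuration against the known schema
#' @noRd
validateConfig <- function(config) {
  unknown <- setdiff(names(config), names(pipelineSchema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in c("motor", "sim", "optics", "qc", "fit", "energetics")) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), pipelineSchema[[sec]])
      if (length(bad))
        stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
    }
  }
  for (mk in config$markers) {
    bad <- setdiff(names(mk), pipelineSchema$markers)
    if (length(bad))
      stop("unknown key(s) in a marker entry: ", paste(bad, collapse = ", "))
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return The validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  validateConfig(yaml::read_yaml(path))
}

markerFromSpec <- function(mk, seedOffset) {
  if (mk$kind == "sphere") {
    R <- if (!is.null(mk$rotationRadius)) mk$rotationRadius else
      stats::runif(1, mk$rotationRadiusRange[1], mk$rotationRadiusRange[2])
    sphereMarker(mk$diameter, R, if (is.null(mk$wallGap)) 500 else mk$wallGap)
  } else {
    L <- if (!is.null(mk$cellLength)) mk$cellLength else
      stats::runif(1, mk$cellLengthRange[1], mk$cellLengthRange[2])
    rodMarker(L, if (is.null(mk$cellRadius)) 250 else mk$cellRadius)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages into a fresh run directory: `simulate`
#' writes per-marker trajectory CSVs (and, when a marker class asks for it,
#' rendered dual-spot TIFF stacks); `track` reconstructs trajectories from
#' any rendered stacks through an internally rendered axial calibration;
#' `analyze` runs the geometric analysis and QC on every trajectory and
#' assembles the marker dataset; `fit` computes drags and the
#' constant-torque fit; `energetics` evaluates the ATP budget of the fitted
#' torque.  The resolved configuration is snapshotted into the run
#' directory and its MD5 hash is stamped into every JSON output; rerunning
#' with the same configuration and seed reproduces the reports.
#'
#' @param config configuration list (see [pipelineConfig()]) or the path of
#'   a YAML file.
#' @param outDir run directory; created if missing.
#' @return Invisibly, a list with the fitted [TorqueFit] (`fit`), the
#'   [EnergeticsReport] (`energetics`), the assembled [MarkerDataset]
#'   (`dataset`), the per-marker analyses, and the config hash.
#' @examples
#' \donttest{
#' res <- runPipeline(pipelineConfig(seed = 1), tempfile("run"))
#' torque(res$fit)
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("rotorque_run")) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config, cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  logPath <- file.path(outDir, "log.txt")
  logLine <- function(...) cat(paste0(..., "\n"), file = logPath, append = TRUE)
  logLine("run config hash: ", cfgHash)
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0L) {
    warning("no stages enabled; nothing to do")
    return(invisible(list(configHash = cfgHash)))
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  simCfg <- config$sim
  motor <- do.call(MotorParams, c(config$motor[setdiff(names(config$motor), "mode")],
                                  list(mode = if (is.null(config$motor$mode))
                                    "model_A" else config$motor$mode)))
  optics <- do.call(OpticsParams, as.list(config$optics))
  trajs <- list()
  geoms <- list()
  renderFlags <- logical(0)
  if ("simulate" %in% stages) {
    logLine("stage simulate")
    idx <- 0L
    for (ci in seq_along(config$markers)) {
      mk <- config$markers[[ci]]
      for (j in seq_len(mk$n)) {
        idx <- idx + 1L
        mseed <- seed + 1000L + idx
        geom <- withSeed(mseed, markerFromSpec(mk, idx))
        drag <- markerDrag(geom, eta = simCfg$viscosity)
        fExp <- predictedRate(motor, dragCoefficient(drag))
        dur <- if (!is.null(mk$duration)) mk$duration else {
          rev <- if (is.null(mk$revolutions)) 4 else mk$revolutions
          max(rev / fExp, 100 * simCfg$dt)
        }
        sim <- SimParams(duration = dur, dt = simCfg$dt, kBT = simCfg$kBT,
                         viscosity = simCfg$viscosity, seed = mseed)
        plane <- withSeed(mseed + 500000L,
                          PlaneSpec(theta = stats::runif(1, 10, 50),
                                    phi = stats::runif(1, 0, 359.9),
                                    center = c(0, 0, 500)))
        tr <- simulateRotationTrace(motor, geom, plane, sim)
        id <- sprintf("m%03d", idx)
        writeTrajectoryCsv(tr, file.path(outDir, paste0(id, "_traj.csv")))
        doRender <- isTRUE(mk$renderImages) && geom@kind == "sphere"
        if (doRender) {
          span <- 2 * (geom@rotationRadius + optics@baselineSeparation / 2) /
            optics@pixelSize + 14
          opt2 <- optics
          opt2@fieldWidth <- as.integer(ceiling(span) + 4)
          opt2@fieldHeight <- as.integer(2 * geom@rotationRadius / optics@pixelSize + 18)
          st <- renderDualImageStack(tr, opt2, seed = mseed + 2000000L)
          writeImageStack(st, file.path(outDir, paste0(id, "_stack.tiff")))
        }
        trajs[[id]] <- tr
        geoms[[id]] <- geom
        renderFlags[id] <- doRender
        logLine("  ", id, " kind=", geom@kind, " gamma=",
                signif(dragCoefficient(drag), 4), " expected_rate=",
                signif(fExp, 4), if (doRender) " +images" else "")
      }
    }
  }
  if ("track" %in% stages && any(renderFlags)) {
    logLine("stage track")
    calib <- calibrateAxial(renderCalibrationStack(
      z = seq(-300, 300, by = 100), optics = optics, shotNoise = FALSE))
    for (id in names(trajs)[renderFlags]) {
      st <- readImageStack(file.path(outDir, paste0(id, "_stack.tiff")))
      trajs[[id]] <- reconstruct3D(st, calib)
      logLine("  ", id, " reconstructed from stack")
    }
  }
  analyses <- list()
  dataset <- NULL
  if ("analyze" %in% stages) {
    logLine("stage analyze")
    qcCfg <- config$qc
    rows <- list()
    for (id in names(trajs)) {
      an <- analyzeTrajectory(trajs[[id]],
                              depthThreshold = qcCfg$depthThreshold,
                              dwellFactor = qcCfg$dwellFactor)
      analyses[[id]] <- an
      writeAnalysisJson(an, file.path(outDir, paste0(id, "_analysis.json")),
                        extra = list(marker_id = id, config_md5 = cfgHash))
      g <- geoms[[id]]
      rows[[id]] <- data.frame(
        marker_id = id, kind = g@kind,
        diameter_nm = g@diameter,
        rotation_radius_nm = if (g@kind == "sphere") an$circle@radius else NA_real_,
        cell_length_nm = if (g@kind == "rod") an$circle@radius else NA_real_,
        cell_radius_nm = g@cellRadius, wall_gap_nm = g@wallGap,
        rate_hz = an$rate@rate, rate_se_hz = an$rate@rateSe,
        direction = an$rate@direction, qc_accepted = an$qc@accepted)
      logLine("  ", id, " rate=", signif(an$rate@rate, 4), " qc=",
              if (an$qc@accepted) "accepted" else paste0("rejected (", an$qc@reason, ")"))
    }
    dataset <- MarkerDataset(do.call(rbind, rows),
                             params = list(config_md5 = cfgHash))
    writeMarkerDatasetCsv(dataset, file.path(outDir, "dataset.csv"))
  }
  fit <- NULL
  if ("fit" %in% stages) {
    logLine("stage fit")
    if (is.null(dataset)) stop("fit stage requires the analyze stage (or a dataset)")
    dataset <- markerFriction(dataset, eta = simCfg$viscosity)
    fit <- fitConstantTorque(dataset, variant = config$fit$variant,
                             bootstrap = config$fit$bootstrap, seed = seed,
                             eta = simCfg$viscosity)
    jsonlite::write_json(list(
      config_md5 = cfgHash, variant = fit@variant,
      torque_pn_nm = fit@torque, internal_friction_pn_nm_s = fit@internalFriction,
      n_markers = fit@nMarkers,
      ci95 = list(torque = as.numeric(fit@ci[1, ]),
                  internal_friction = as.numeric(fit@ci[2, ]))),
      file.path(outDir, "torque_fit.json"), auto_unbox = TRUE, digits = NA)
    curve <- apparentTorqueCurve(dataset, fit, eta = simCfg$viscosity)
    utils::write.table(curve, file.path(outDir, "apparent_torque.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    logLine("  T_a=", signif(fit@torque, 4), " gamma_a=",
            signif(fit@internalFriction, 4))
  }
  energy <- NULL
  if ("energetics" %in% stages) {
    logLine("stage energetics")
    Ta <- if (!is.null(fit)) fit@torque else config$motor$torque
    e <- config$energetics
    energy <- energeticsReport(Ta, dgAtp = e$dgAtp, nMax = e$nMax,
                               tolerance = e$tolerance)
    jsonlite::write_json(list(
      config_md5 = cfgHash, torque_pn_nm = Ta,
      work_per_rotation_pn_nm = energy@workPerRotation,
      dg_atp_pn_nm = energy@dgAtp, feasible_n = energy@feasibleN,
      tolerance = energy@tolerance, table = energy@table),
      file.path(outDir, "energetics.json"), auto_unbox = TRUE, digits = NA)
  }
  logLine("done")
  invisible(list(fit = fit, energetics = energy, dataset = dataset,
                 analyses = analyses, configHash = cfgHash, outDir = outDir))
}
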