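#' @import methods
NULL

## Unit conventions used throughout the package:
##   length nm, time s, torque pN.nm, rotational drag pN.nm.s,
##   energy pN.nm, viscosity stored in Pa.s (1 Pa.s = 1e-6 pN.s.nm^-2).

PA_S_TO_PN_S_NM2 <- 1e-6

#' Motor model parameters
#'
#' Parameters of the generative motor model.  Two generative mechanisms are
#' supported: `"model_A"`, an overdamped constant-torque motor in which the
#' internal friction constant acts as additional viscous drag, and
#' `"model_B"`, a tightly coupled stepping motor with a rate-limiting
#' chemical transition, whose zero-load rate `fNoLoad` plays the role of the
#' internal friction through \eqn{\gamma_a = T_a / (2\pi f_{noload})}.
#'
#' @param torque motor torque \eqn{T_a} (pN nm); must be positive.
#' @param internalFriction internal friction constant \eqn{\gamma_a}
#'   (pN nm s); used by `"model_A"`.
#' @param mode `"model_A"` or `"model_B"`.
#' @param fNoLoad zero-load rotation rate (Hz); required for `"model_B"`.
#' @param stepSize angular step of the stepping motor (degrees); must divide
#'   360.  Default 60, one step per catalytic site of a hexameric ATPase.
#' @param direction `"CW"` or `"CCW"` as seen looking along -z (the camera
#'   viewpoint of an inverted microscope).
#' @return A `MotorParams` object.
#' @examples
#' MotorParams(torque = 160, internalFriction = 0.81)
#' @export
MotorParams <- function(torque, internalFriction = 0, mode = c("model_A", "model_B"),
                        fNoLoad = NA_real_, stepSize = 60, direction = c("CCW", "CW")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  new("MotorParams", torque = as.numeric(torque),
      internalFriction = as.numeric(internalFriction), mode = mode,
      fNoLoad = as.numeric(fNoLoad), stepSize = as.numeric(stepSize),
      direction = direction)
}

setClass("MotorParams",
  representation(torque = "numeric", internalFriction = "numeric",
                 mode = "character", fNoLoad = "numeric",
                 stepSize = "numeric", direction = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@torque) != 1L || !is.finite(object@torque) || object@torque <= 0)
      msg <- c(msg, "'torque' must be a single positive number")
    if (length(object@internalFriction) != 1L || is.na(object@internalFriction) ||
        object@internalFriction < 0)
      msg <- c(msg, "'internalFriction' must be >= 0")
    if (!object@mode %in% c("model_A", "model_B"))
      msg <- c(msg, "'mode' must be 'model_A' or 'model_B'")
    if (object@mode == "model_B" &&
        (!is.finite(object@fNoLoad) || object@fNoLoad <= 0))
      msg <- c(msg, "'fNoLoad' must be positive for model_B")
    if (!is.finite(object@stepSize) || object@stepSize <= 0 ||
        abs(360 / object@stepSize - round(360 / object@stepSize)) > 1e-9)
      msg <- c(msg, "'stepSize' must be a positive divisor of 360 degrees")
    if (!object@direction %in% c("CW", "CCW"))
      msg <- c(msg, "'direction' must be 'CW' or 'CCW'")
    if (length(msg)) msg else TRUE
  })

#' Simulation parameters
#'
#' @param duration simulated duration (s); at least 100 camera intervals.
#' @param dt camera sampling interval (s); default 5e-4 (0.5 ms).
#' @param kBT thermal energy (pN nm); default 4.1, room temperature.
#' @param viscosity solution viscosity (Pa s); default 1.35e-3, the measured
#'   viscosity of high-salt motility buffer.
#' @param seed integer RNG seed, or `NA` to leave the RNG state alone.
#' @return A `SimParams` object.
#' @examples
#' SimParams(duration = 1)
#' @export
SimParams <- function(duration, dt = 5e-4, kBT = 4.1, viscosity = 1.35e-3,
                      seed = NA_integer_) {
  new("SimParams", dt = as.numeric(dt), duration = as.numeric(duration),
      kBT = as.numeric(kBT), viscosity = as.numeric(viscosity),
      seed = as.integer(seed))
}

setClass("SimParams",
  representation(dt = "numeric", duration = "numeric", kBT = "numeric",
                 viscosity = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@dt) || object@dt <= 0) msg <- c(msg, "'dt' must be > 0")
    if (!is.finite(object@duration) || object@duration < 100 * object@dt)
      msg <- c(msg, "'duration' must be at least 100 camera intervals")
    if (!is.finite(object@kBT) || object@kBT < 0) msg <- c(msg, "'kBT' must be >= 0")
    if (!is.finite(object@viscosity) || object@viscosity <= 0)
      msg <- c(msg, "'viscosity' must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Marker geometry
#'
#' Geometry of a viscous-load marker: a polystyrene bead (`sphere`), a
#' tethered cell body (`rod`) pivoting about one end, or a helical filament
#' (`helix`).  Constructors [sphereMarker()], [rodMarker()] and
#' [helixMarker()] fill the fields relevant for each kind; the remaining
#' fields stay `NA`.
#'
#' @slot kind marker kind.
#' @slot diameter,rotationRadius,wallGap sphere fields (nm).
#' @slot cellLength,cellRadius rod fields (nm).
#' @slot helixRadius,pitch,length,filamentRadius helix fields (nm).
#' @name MarkerGeometry-class
#' @aliases MarkerGeometry
#' @exportClass MarkerGeometry
setClass("MarkerGeometry",
  representation(kind = "character", diameter = "numeric",
                 rotationRadius = "numeric", wallGap = "numeric",
                 cellLength = "numeric", cellRadius = "numeric",
                 helixRadius = "numeric", pitch = "numeric",
                 length = "numeric", filamentRadius = "numeric"),
  prototype(diameter = NA_real_, rotationRadius = NA_real_, wallGap = NA_real_,
            cellLength = NA_real_, cellRadius = NA_real_, helixRadius = NA_real_,
            pitch = NA_real_, length = NA_real_, filamentRadius = NA_real_),
  validity = function(object) {
    msg <- character()
    pos <- function(x) is.finite(x) && x > 0
    switch(object@kind,
      sphere = {
        if (!pos(object@diameter)) msg <- c(msg, "sphere: 'diameter' must be > 0")
        if (!is.finite(object@rotationRadius) || object@rotationRadius < 0)
          msg <- c(msg, "sphere: 'rotationRadius' must be >= 0")
        if (!is.finite(object@wallGap) || object@wallGap < 0)
          msg <- c(msg, "sphere: 'wallGap' must be >= 0")
      },
      rod = {
        if (!pos(object@cellLength)) msg <- c(msg, "rod: 'cellLength' must be > 0")
        if (!pos(object@cellRadius)) msg <- c(msg, "rod: 'cellRadius' must be > 0")
        if (pos(object@cellLength) && pos(object@cellRadius) &&
            object@cellLength / (2 * object@cellRadius) * 2 <= exp(0.66))
          msg <- c(msg, "rod: L/(2r) with L = 2*cellLength must exceed exp(0.66)")
      },
      helix = {
        for (f in c("helixRadius", "pitch", "length", "filamentRadius"))
          if (!pos(slot(object, f))) msg <- c(msg, paste0("helix: '", f, "' must be > 0"))
      },
      msg <- c(msg, "'kind' must be sphere, rod or helix"))
    if (length(msg)) msg else TRUE
  })

#' @param diameter bead diameter (nm).
#' @param rotationRadius radius of the bead-centre orbit (nm).
#' @param wallGap surface-to-surface gap between bead and coverslip (nm);
#'   default 500, the width of an immobilised cell.
#' @rdname MarkerGeometry-class
#' @export
sphereMarker <- function(diameter, rotationRadius, wallGap = 500) {
  new("MarkerGeometry", kind = "sphere", diameter = as.numeric(diameter),
      rotationRadius = as.numeric(rotationRadius), wallGap = as.numeric(wallGap))
}

#' @param cellLength cell length, pivot to far end (nm).
#' @param cellRadius radius of the rod cross-section (nm).
#' @rdname MarkerGeometry-class
#' @export
rodMarker <- function(cellLength, cellRadius = 250) {
  new("MarkerGeometry", kind = "rod", cellLength = as.numeric(cellLength),
      cellRadius = as.numeric(cellRadius))
}

#' @param helixRadius helix radius b (nm).
#' @param pitch helix pitch p (nm).
#' @param length filament length L (nm); see [helixDrag()] for the
#'   contour/axial convention.
#' @param filamentRadius filament cross-section radius r (nm).
#' @rdname MarkerGeometry-class
#' @export
helixMarker <- function(helixRadius = 220, pitch = 2100, length = 4300,
                        filamentRadius = 7) {
  new("MarkerGeometry", kind = "helix", helixRadius = as.numeric(helixRadius),
      pitch = as.numeric(pitch), length = as.numeric(length),
      filamentRadius = as.numeric(filamentRadius))
}

#' Rotation-plane specification
#'
#' Orientation of the plane of a circular orbit, given as the polar
#' coordinates of the plane normal: `theta` is the tilt from the optical
#' (+z) axis and `phi` the azimuth of the tilt direction.
#'
#' @param theta polar angle of the plane normal (degrees, 0--90).
#' @param phi azimuth (degrees, 0--360).
#' @param center orbit centre, length-3 numeric (nm).
#' @return A `PlaneSpec` object.
#' @examples
#' PlaneSpec(theta = 35, phi = 120)
#' @export
PlaneSpec <- function(theta = 0, phi = 0, center = c(0, 0, 0)) {
  new("PlaneSpec", theta = as.numeric(theta), phi = as.numeric(phi),
      center = as.numeric(center))
}

setClass("PlaneSpec",
  representation(theta = "numeric", phi = "numeric", center = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@theta) || object@theta < 0 || object@theta > 90)
      msg <- c(msg, "'theta' must be in [0, 90] degrees")
    if (!is.finite(object@phi) || object@phi < 0 || object@phi >= 360)
      msg <- c(msg, "'phi' must be in [0, 360) degrees")
    if (length(object@center) != 3L || any(!is.finite(object@center)))
      msg <- c(msg, "'center' must be a finite length-3 vector")
    if (length(msg)) msg else TRUE
  })

#' Optical model of the wedge-prism dual-spot system
#'
#' Describes the prism-split imaging path: a wedge prism at the equivalent
#' back focal plane splits each point source into two spots whose separation
#' along the prism axis encodes axial position linearly,
#' separation = baseline + axialGain * z.
#'
#' @param pixelSize camera pixel size (nm); default 98.
#' @param frameInterval camera interval (s); default 5e-4.
#' @param psfSigma Gaussian PSF sigma (nm).
#' @param prismAxis unit 2-vector of the prism splitting direction in image
#'   coordinates.
#' @param baselineSeparation spot-pair separation at the reference height
#'   z = 0 (nm).
#' @param axialGain separation change per nm of z (dimensionless); must be
#'   non-zero.  A free calibration parameter of the optical path.
#' @param photonsPerSpot expected photons per spot per frame.
#' @param readNoise Gaussian read noise (counts RMS).
#' @param background expected background (counts per pixel).
#' @param fieldWidth,fieldHeight field of view (pixels).
#' @return An `OpticsParams` object.
#' @examples
#' OpticsParams(photonsPerSpot = 1e4)
#' @export
OpticsParams <- function(pixelSize = 98, frameInterval = 5e-4, psfSigma = 130,
                         prismAxis = c(1, 0), baselineSeparation = 1470,
                         axialGain = 0.5, photonsPerSpot = 1e4, readNoise = 0,
                         background = 0, fieldWidth = 48L, fieldHeight = 32L) {
  prismAxis <- as.numeric(prismAxis)
  nrm <- sqrt(sum(prismAxis^2))
  if (nrm > 0) prismAxis <- prismAxis / nrm
  new("OpticsParams", pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval), psfSigma = as.numeric(psfSigma),
      prismAxis = prismAxis, baselineSeparation = as.numeric(baselineSeparation),
      axialGain = as.numeric(axialGain), photonsPerSpot = as.numeric(photonsPerSpot),
      readNoise = as.numeric(readNoise), background = as.numeric(background),
      fieldWidth = as.integer(fieldWidth), fieldHeight = as.integer(fieldHeight))
}

setClass("OpticsParams",
  representation(pixelSize = "numeric", frameInterval = "numeric",
                 psfSigma = "numeric", prismAxis = "numeric",
                 baselineSeparation = "numeric", axialGain = "numeric",
                 photonsPerSpot = "numeric", readNoise = "numeric",
                 background = "numeric", fieldWidth = "integer",
                 fieldHeight = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
      msg <- c(msg, "'pixelSize' must be > 0")
    if (!is.finite(object@psfSigma) || object@psfSigma <= 0)
      msg <- c(msg, "'psfSigma' must be > 0")
    if (!is.finite(object@axialGain) || object@axialGain == 0)
      msg <- c(msg, "'axialGain' must be non-zero")
    if (length(object@prismAxis) != 2L ||
        abs(sqrt(sum(object@prismAxis^2)) - 1) > 1e-8)
      msg <- c(msg, "'prismAxis' must be a unit 2-vector")
    if (length(msg)) msg else TRUE
  })

#' Time-stamped 3D trajectory
#'
#' Container for a tracked or simulated 3D marker trajectory.  Each frame
#' carries a quality flag (`"ok"` or a short failure code); flagged frames
#' are retained, and downstream stages decide whether to exclude them.
#'
#' @param times frame times (s), strictly increasing.
#' @param positions numeric matrix, one row per frame, columns x, y, z (nm).
#' @param flags character vector of per-frame QC flags; default all `"ok"`.
#' @return A `Trajectory3D` object.
#' @seealso [times()], [positions()], [frameFlags()]
#' @examples
#' tr <- Trajectory3D(times = (0:99) * 5e-4,
#'                    positions = cbind(cos(1:100), sin(1:100), 0) * 250)
#' nFrames(tr)
#' @export
Trajectory3D <- function(times, positions, flags = rep("ok", length(times))) {
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y", "z")
  new("Trajectory3D", times = as.numeric(times), positions = positions,
      flags = as.character(flags))
}

setClass("Trajectory3D",
  representation(times = "numeric", positions = "matrix", flags = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@times)
    if (any(diff(object@times) <= 0)) msg <- c(msg, "'times' must be strictly increasing")
    if (!is.numeric(object@positions) || ncol(object@positions) != 3L ||
        nrow(object@positions) != n)
      msg <- c(msg, "'positions' must be a numeric n x 3 matrix matching 'times'")
    ok <- object@flags == "ok"
    if (any(!is.finite(object@positions[ok, , drop = FALSE])))
      msg <- c(msg, "positions of unflagged frames must be finite")
    if (length(object@flags) != n) msg <- c(msg, "'flags' must match 'times'")
    if (length(msg)) msg else TRUE
  })

#' Dual-spot image stack
#'
#' A stack of prism-split camera frames together with the optical model that
#' rendered (or will decode) them.  Frames are stored height x width x frame,
#' in counts.
#'
#' @param frames numeric array (height, width, nFrames) of pixel counts.
#' @param optics an [OpticsParams] object.
#' @param metadata list of free-form stack metadata (e.g. overlap warnings,
#'   ground-truth z values of a calibration stack).
#' @return An `ImageStack` object.
#' @export
ImageStack <- function(frames, optics, metadata = list()) {
  new("ImageStack", frames = frames, optics = optics, metadata = metadata)
}

setClass("ImageStack",
  representation(frames = "array", optics = "OpticsParams", metadata = "list"),
  validity = function(object) {
    if (length(dim(object@frames)) != 3L)
      "'frames' must be a 3-d array (height, width, frame)" else TRUE
  })

#' Axial calibration of the dual-spot separation
#'
#' Linear map from spot-pair separation to axial position:
#' z = (separation - intercept) / slope.
#'
#' @param slope separation change per nm of z.
#' @param intercept separation at z = 0 (nm).
#' @param residualRms RMS residual of the calibration line (nm).
#' @return An `AxialCalibration` object.
#' @export
AxialCalibration <- function(slope, intercept, residualRms = 0) {
  new("AxialCalibration", slope = as.numeric(slope),
      intercept = as.numeric(intercept), residualRms = as.numeric(residualRms))
}

setClass("AxialCalibration",
  representation(slope = "numeric", intercept = "numeric", residualRms = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@slope) || object@slope == 0)
      msg <- c(msg, "'slope' must be non-zero")
    if (!is.finite(object@residualRms) || object@residualRms < 0)
      msg <- c(msg, "'residualRms' must be >= 0")
    if (length(msg)) msg else TRUE
  })

## ---- analysis results -------------------------------------------------

setClass("PlaneFit",
  representation(theta = "numeric", phi = "numeric", center = "numeric",
                 circularityScore = "numeric", outOfPlaneRms = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@theta < -1e-9 || object@theta > 90 + 1e-9)
      msg <- c(msg, "'theta' must be in [0, 90]")
    if (object@circularityScore < 0) msg <- c(msg, "score must be >= 0")
    if (length(msg)) msg else TRUE
  })

setClass("CircleFit",
  representation(radius = "numeric", center = "numeric", radialRms = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@radius) || object@radius <= 0)
      msg <- c(msg, "'radius' must be > 0")
    if (object@radialRms < 0) msg <- c(msg, "'radialRms' must be >= 0")
    if (length(msg)) msg else TRUE
  })

setClass("RateEstimate",
  representation(rate = "numeric", direction = "character", phase = "numeric",
                 times = "numeric", rateSe = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@rate) || object@rate < 0)
      msg <- c(msg, "'rate' must be >= 0")
    if (!object@direction %in% c("CW", "CCW"))
      msg <- c(msg, "'direction' must be CW or CCW")
    if (length(msg)) msg else TRUE
  })

setClass("QCReport",
  representation(modulationDepth60 = "numeric", smooth = "logical",
                 accepted = "logical", reason = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@modulationDepth60) || object@modulationDepth60 < 0)
      msg <- c(msg, "'modulationDepth60' must be >= 0")
    if (object@accepted && !object@smooth)
      msg <- c(msg, "an accepted trace must be smooth")
    if (length(msg)) msg else TRUE
  })

#' Drag-coefficient estimate
#'
#' Result of a closed-form drag computation: the raw drag, the wall
#' correction factor (1 when no correction applies), the corrected drag and
#' an identifier of the formula used.
#'
#' @name DragEstimate-class
#' @aliases DragEstimate
#' @exportClass DragEstimate
setClass("DragEstimate",
  representation(gamma = "numeric", correctionFactor = "numeric",
                 gammaCorrected = "numeric", formulaId = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@gamma) || object@gamma < 0)
      msg <- c(msg, "'gamma' must be >= 0")
    if (!is.finite(object@correctionFactor) || object@correctionFactor < 1)
      msg <- c(msg, "'correctionFactor' must be >= 1")
    if (abs(object@gammaCorrected - object@gamma * object@correctionFactor) >
        1e-9 * max(1, object@gammaCorrected))
      msg <- c(msg, "'gammaCorrected' must equal gamma * correctionFactor")
    if (length(msg)) msg else TRUE
  })

DragEstimate <- function(gamma, correctionFactor = 1, formulaId) {
  new("DragEstimate", gamma = gamma, correctionFactor = correctionFactor,
      gammaCorrected = gamma * correctionFactor, formulaId = formulaId)
}

#' Benchmark marker dataset
#'
#' A table of markers (one row per marker: geometry, measured rotation rate,
#' drag coefficients, QC status) plus the generator parameters that produced
#' it, when synthetic.
#'
#' @param records data.frame with columns `marker_id, kind, diameter_nm,
#'   rotation_radius_nm, cell_length_nm, cell_radius_nm, wall_gap_nm,
#'   rate_hz, direction` and optionally `gamma_raw, gamma_corrected,
#'   qc_accepted, rate_se_hz`.
#' @param params list of generator/provenance parameters.
#' @return A `MarkerDataset` object.
#' @seealso [buildBenchmarkDataset()], [markerFriction()]
#' @export
MarkerDataset <- function(records, params = list()) {
  new("MarkerDataset", records = as.data.frame(records), params = params)
}

setClass("MarkerDataset",
  representation(records = "data.frame", params = "list"),
  validity = function(object) {
    need <- c("marker_id", "kind", "rate_hz")
    miss <- setdiff(need, names(object@records))
    if (length(miss))
      paste("missing dataset columns:", paste(miss, collapse = ", ")) else TRUE
  })

#' Constant-torque model fit
#'
#' Fit of \eqn{f(\gamma) = T_a / (2\pi(\gamma + \gamma_a))} to a marker
#' dataset, with parameter covariance and case-resampling bootstrap
#' confidence intervals.
#'
#' @name TorqueFit-class
#' @aliases TorqueFit
#' @exportClass TorqueFit
setClass("TorqueFit",
  representation(torque = "numeric", internalFriction = "numeric",
                 cov = "matrix", ci = "matrix", variant = "character",
                 nMarkers = "integer", bootstrap = "list"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@torque) || object@torque <= 0)
      msg <- c(msg, "'torque' must be > 0")
    if (object@internalFriction < 0)
      msg <- c(msg, "'internalFriction' must be >= 0")
    if (nrow(object@ci) == 2L) {
      est <- c(object@torque, object@internalFriction)
      if (any(object@ci[, 1] > est + 1e-9) || any(object@ci[, 2] < est - 1e-9))
        msg <- c(msg, "confidence intervals must bracket the point estimates")
    }
    if (length(msg)) msg else TRUE
  })

#' ATP energetics report
#'
#' Energy bookkeeping of one motor revolution: mechanical work, ATP count
#' and input energy under n-fold cooperativity of the six catalytic sites,
#' the resulting apparent efficiencies, and the smallest thermodynamically
#' feasible n.
#'
#' @name EnergeticsReport-class
#' @aliases EnergeticsReport
#' @exportClass EnergeticsReport
setClass("EnergeticsReport",
  representation(workPerRotation = "numeric", dgAtp = "numeric",
                 table = "data.frame", feasibleN = "integer",
                 tolerance = "numeric"))
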