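#' Accessors for rotorque objects
#'
#' Small accessor generics so that user code never touches slots directly.
#'
#' @param x a rotorque object.
#' @return `times()` the frame times (s); `positions()` the n x 3 position
#'   matrix (nm); `frameFlags()` the per-frame QC flags; `nFrames()` the
#'   number of frames; `torque()` the fitted or configured torque (pN nm);
#'   `internalFriction()` the internal friction constant (pN nm s);
#'   `dragCoefficient()` the (optionally wall-corrected) drag (pN nm s);
#'   `records()` the marker table of a [MarkerDataset].
#' @examples
#' tr <- Trajectory3D((0:99) * 5e-4, cbind(cos(1:100), sin(1:100), 0) * 250)
#' head(positions(tr))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("frameFlags", function(x) standardGeneric("frameFlags"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("torque", function(x) standardGeneric("torque"))
#' @rdname accessors
#' @export
setGeneric("internalFriction", function(x) standardGeneric("internalFriction"))
#' @rdname accessors
#' @param corrected logical; return the wall-corrected value?
#' @export
setGeneric("dragCoefficient", function(x, corrected = TRUE) standardGeneric("dragCoefficient"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
setMethod("times", "Trajectory3D", function(x) x@times)
#' @rdname accessors
setMethod("positions", "Trajectory3D", function(x) x@positions)
#' @rdname accessors
setMethod("frameFlags", "Trajectory3D", function(x) x@flags)
#' @rdname accessors
setMethod("nFrames", "Trajectory3D", function(x) length(x@times))
#' @rdname accessors
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3L])
#' @rdname accessors
setMethod("torque", "TorqueFit", function(x) x@torque)
#' @rdname accessors
setMethod("torque", "MotorParams", function(x) x@torque)
#' @rdname accessors
setMethod("internalFriction", "TorqueFit", function(x) x@internalFriction)
#' @rdname accessors
setMethod("internalFriction", "MotorParams", function(x) x@internalFriction)
#' @rdname accessors
setMethod("dragCoefficient", "DragEstimate", function(x, corrected = TRUE) {
  if (corrected) x@gammaCorrected else x@gamma
})
#' @rdname accessors
setMethod("records", "MarkerDataset", function(x) x@records)

#' @describeIn TorqueFit-class 95% bootstrap confidence intervals; rows
#'   `torque` and `internalFriction`.
#' @param object,parm,level,... see [stats::confint()]; `level` is fixed by
#'   the bootstrap stored in the object.
#' @export
setMethod("confint", "TorqueFit", function(object, parm, level = 0.95, ...) {
  object@ci
})
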