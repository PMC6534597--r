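setMethod("show", "Trajectory3D", function(object) {
  n <- length(object@times)
  bad <- sum(object@flags != "ok")
  cat("Trajectory3D:", n, "frames over",
      signif(diff(range(object@times)), 4), "s")
  if (bad) cat(" (", bad, " flagged)", sep = "")
  cat("\n")
  if (n) {
    r <- apply(object@positions, 2, function(x) range(x, na.rm = TRUE))
    cat(sprintf("  x [%.0f, %.0f] nm, y [%.0f, %.0f] nm, z [%.0f, %.0f] nm\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat("ImageStack:", d[3], "frames of", d[1], "x", d[2], "px (",
      object@optics@pixelSize, "nm/px )\n")
})

setMethod("show", "DragEstimate", function(object) {
  cat(sprintf("DragEstimate [%s]: gamma = %.4g pN nm s", object@formulaId,
              object@gamma))
  if (object@correctionFactor != 1)
    cat(sprintf(" (x%.3g wall -> %.4g)", object@correctionFactor,
                object@gammaCorrected))
  cat("\n")
})

setMethod("show", "PlaneFit", function(object) {
  cat(sprintf("PlaneFit: theta = %.1f deg, phi = %.1f deg, CV = %.3g, out-of-plane RMS = %.3g nm\n",
              object@theta, object@phi, object@circularityScore,
              object@outOfPlaneRms))
})

setMethod("show", "CircleFit", function(object) {
  cat(sprintf("CircleFit: R = %.1f nm, radial RMS = %.2f nm\n",
              object@radius, object@radialRms))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate: %.3f Hz (%s), SE %.3g Hz\n", object@rate,
              object@direction, object@rateSe))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %s (depth60 = %.2f, smooth = %s)\n",
              if (object@accepted) "accepted" else paste("rejected -", object@reason),
              object@modulationDepth60, object@smooth))
})

setMethod("show", "TorqueFit", function(object) {
  cat(sprintf("TorqueFit (%s, n = %d):\n", object@variant, object@nMarkers))
  cat(sprintf("  T_a     = %.4g pN nm   [%.4g, %.4g]\n", object@torque,
              object@ci[1, 1], object@ci[1, 2]))
  cat(sprintf("  gamma_a = %.4g pN nm s [%.4g, %.4g]\n",
              object@internalFriction, object@ci[2, 1], object@ci[2, 2]))
})

setMethod("show", "EnergeticsReport", function(object) {
  cat(sprintf("EnergeticsReport: W = %.4g pN nm per rotation, dG_ATP = %g pN nm\n",
              object@workPerRotation, object@dgAtp))
  tab <- object@table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  n = %d: %2d ATP, %4g pN nm in, efficiency %.1f%%\n",
                tab$n[i], tab$atp_per_rotation[i], tab$energy_in[i],
                tab$efficiency_pct[i]))
  cat(sprintf("  smallest feasible n (tolerance %.0f%%): %d\n",
              100 * object@tolerance, object@feasibleN))
})

setMethod("show", "MarkerDataset", function(object) {
  cat("MarkerDataset:", nrow(object@records), "markers\n")
  print(table(object@records$kind))
})

setMethod("show", "MotorParams", function(object) {
  cat(sprintf("MotorParams [%s]: T_a = %g pN nm, gamma_a = %g pN nm s%s, %s\n",
              object@mode, object@torque, object@internalFriction,
              if (is.finite(object@fNoLoad))
                sprintf(", f_noload = %g Hz", object@fNoLoad) else "",
              object@direction))
})
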