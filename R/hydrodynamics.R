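## Closed-form low-Reynolds-number drag coefficients for rotation-assay
## markers.  All return pN.nm.s; viscosity is given in Pa.s and converted
## internally (1 Pa.s = 1e-6 pN.s/nm^2).

#' Rotational drag of a bead on an eccentric orbit
#'
#' Drag coefficient of a sphere of radius `r` whose centre moves on a circle
#' of radius `R` about the rotation axis:
#' \deqn{\gamma = 8\pi\eta r^3 + 6\pi\eta r R^2}
#' The first term is the Stokes drag for spinning about the bead centre, the
#' second the translational drag of the orbital motion expressed as a
#' rotational drag about the axis.
#'
#' @param r bead radius (nm).
#' @param R rotation (orbit) radius (nm); `R = 0` gives the pure spinning
#'   term.
#' @param eta solution viscosity (Pa s).
#' @param wallGap surface-to-surface gap between bead and coverslip (nm), or
#'   `NA` to skip the wall correction.  When given, the method-of-reflections
#'   factor of [wallCorrection()] is applied (see `correctTerm`).
#' @param correctTerm `"total"` (default) multiplies the full two-term drag
#'   by the wall factor, as a single scalar correction per bead size;
#'   `"translation"` corrects only the orbital term.
#' @return A [DragEstimate].
#' @examples
#' sphereDrag(r = 105, R = 250)                  # free-space, ~0.206 pN nm s
#' sphereDrag(r = 105, R = 250, wallGap = 500)   # near-wall corrected
#' @export
sphereDrag <- function(r, R, eta = 1.35e-3, wallGap = NA_real_,
                       correctTerm = c("total", "translation")) {
  correctTerm <- match.arg(correctTerm)
  if (!is.finite(r) || r <= 0) stop("'r' must be a positive bead radius")
  if (!is.finite(R) || R < 0) stop("'R' must be a non-negative rotation radius")
  if (!is.finite(eta) || eta <= 0) stop("'eta' must be a positive viscosity")
  e <- eta * PA_S_TO_PN_S_NM2
  spin <- 8 * pi * e * r^3
  orbit <- 6 * pi * e * r * R^2
  gamma <- spin + orbit
  if (is.na(wallGap)) return(DragEstimate(gamma, 1, "sphere"))
  fac <- wallCorrection(diameter = 2 * r, gap = wallGap)
  if (correctTerm == "total") {
    DragEstimate(gamma, fac, "sphere+wall")
  } else {
    corrected <- spin + orbit * fac
    DragEstimate(gamma, corrected / gamma, "sphere+wall(translation)")
  }
}

#' Near-wall drag correction for a translating sphere
#'
#' Increase of the translational drag of a sphere moving parallel to a plane
#' wall, from the method-of-reflections series (Happel & Brenner):
#' \deqn{\left[1 - \tfrac{9}{16}\tfrac{r}{h} + \tfrac{1}{8}\left(\tfrac{r}{h}\right)^3
#'  - \tfrac{45}{256}\left(\tfrac{r}{h}\right)^4
#'  - \tfrac{1}{16}\left(\tfrac{r}{h}\right)^5\right]^{-1}}
#' with `r` the bead radius and `h = gap + r` the distance of the bead
#' centre from the wall.  With a 0.5-um gap (the width of the cell body
#' between bead and coverslip) this gives 1.4, 1.2 and 1.1 for 1.0-, 0.49-
#' and 0.21-um beads.
#'
#' @param diameter bead diameter (nm).
#' @param gap surface-to-surface gap between bead and wall (nm).
#' @param order highest power of r/h retained; default 5, the classical
#'   truncation.  Only orders 4 and 5 are offered (the series has no
#'   second-order term).
#' @return Dimensionless factor >= 1.
#' @examples
#' wallCorrection(1000, 500)   # 1.39
#' wallCorrection(210, 500)    # 1.11
#' @export
wallCorrection <- function(diameter, gap, order = 5L) {
  if (!is.finite(diameter) || diameter <= 0) stop("'diameter' must be > 0")
  if (!is.finite(gap) || gap < 0) stop("'gap' must be >= 0")
  r <- diameter / 2
  h <- gap + r
  if (h <= r && gap > 0) stop("impossible geometry: h <= r")
  s <- r / h
  denom <- 1 - (9 / 16) * s + (1 / 8) * s^3 - (45 / 256) * s^4
  if (order >= 5L) denom <- denom - (1 / 16) * s^5
  if (denom <= 0) stop("series truncation invalid this close to the wall")
  1 / denom
}

#' Rotational drag of a tethered cell
#'
#' Drag coefficient of a rod-shaped cell rotating about a pivot at one end.
#' The rod formula for rotation about the centre,
#' \deqn{\gamma = \tfrac{1}{3}\pi\eta L^3\,[\ln(L/2r) - 0.66]^{-1},}
#' is evaluated at `L = 2 * cellLength` and halved: a rod of twice the cell
#' length spinning about its centre sweeps the same flow field as the cell
#' pivoting about its end, and the cell is one of its two halves.
#'
#' @param cellLength pivot-to-tip cell length (nm).
#' @param cellRadius radius of the rod cross-section (nm).
#' @param eta solution viscosity (Pa s).
#' @return A [DragEstimate].  No wall correction is applied to tethered
#'   cells.
#' @examples
#' rodDragTethered(cellLength = 2500, cellRadius = 250)  # ~54 pN nm s
#' @export
rodDragTethered <- function(cellLength, cellRadius, eta = 1.35e-3) {
  if (!is.finite(cellLength) || cellLength <= 0) stop("'cellLength' must be > 0")
  if (!is.finite(cellRadius) || cellRadius <= 0) stop("'cellRadius' must be > 0")
  if (!is.finite(eta) || eta <= 0) stop("'eta' must be a positive viscosity")
  L <- 2 * cellLength
  logterm <- log(L / (2 * cellRadius)) - 0.66
  if (logterm <= 0)
    stop("rod aspect ratio too small: ln(L/2r) - 0.66 must be positive ",
         "(L = 2*cellLength = ", L, " nm, r = ", cellRadius, " nm)")
  e <- eta * PA_S_TO_PN_S_NM2
  gamma <- (1 / 3) * pi * e * L^3 / logterm
  DragEstimate(gamma / 2, 1, "rod_tethered")
}

#' Rotational drag of a helical filament
#'
#' Drag coefficient of a helical filament rotating about its axis, from the
#' resistive-force closed form
#' \deqn{\gamma = 2\pi\eta b^2 L\,\frac{2p^2 + 4\pi^2 b^2}{p^2 + 4\pi^2 b^2}
#'   \,[\ln(2p/r) - 0.5]^{-1}}
#' with `b` the helix radius, `p` the pitch, `r` the filament cross-section
#' radius and `L` the filament length.
#'
#' The length convention matters: `lengthConvention = "contour"` (default)
#' takes `L` as the contour length and uses it directly;
#' `"axial"` takes `L` as the end-to-end length along the helix axis and
#' converts it to contour length by the factor
#' \eqn{\sqrt{1 + (2\pi b/p)^2}} before applying the formula.  With the
#' default archaellar parameters the two conventions give 0.51 and
#' 0.61 pN nm s respectively.
#'
#' @param b helix radius (nm).
#' @param p helix pitch (nm).
#' @param L filament length (nm); interpretation set by `lengthConvention`.
#' @param r filament cross-section radius (nm).
#' @param eta solution viscosity (Pa s).
#' @param lengthConvention `"contour"` or `"axial"`.
#' @return A [DragEstimate].
#' @examples
#' helixDrag(b = 220, p = 2100, L = 4300, r = 7)   # archaellar filament
#' @export
helixDrag <- function(b, p, L, r, eta = 1.35e-3,
                      lengthConvention = c("contour", "axial")) {
  lengthConvention <- match.arg(lengthConvention)
  for (nm in c("b", "p", "L", "r"))
    if (!is.finite(get(nm)) || get(nm) < 0) stop("'", nm, "' must be >= 0")
  if (p <= 0 || r <= 0 || L <= 0) stop("'p', 'r' and 'L' must be > 0")
  logterm <- log(2 * p / r) - 0.5
  if (logterm <= 0) stop("helix slenderness too small: ln(2p/r) - 0.5 must be positive")
  if (lengthConvention == "axial") L <- L * sqrt(1 + (2 * pi * b / p)^2)
  e <- eta * PA_S_TO_PN_S_NM2
  gamma <- 2 * pi * e * b^2 * L * (2 * p^2 + 4 * pi^2 * b^2) /
    (p^2 + 4 * pi^2 * b^2) / logterm
  if (b == 0) return(new("DragEstimate", gamma = 0, correctionFactor = 1,
                         gammaCorrected = 0, formulaId = "helix"))
  DragEstimate(gamma, 1, paste0("helix(", lengthConvention, ")"))
}

#' Drag coefficient of any marker geometry
#'
#' Dispatches on the marker kind: spheres go through [sphereDrag()] (with
#' the wall correction when `applyWallCorrection` is `TRUE` and a wall gap
#' is set), tethered cells through [rodDragTethered()] (never wall
#' corrected), helices through [helixDrag()].
#'
#' @param geometry a [MarkerGeometry].
#' @param eta viscosity (Pa s).
#' @param applyWallCorrection logical; spheres only.
#' @return A [DragEstimate].
#' @export
markerDrag <- function(geometry, eta = 1.35e-3, applyWallCorrection = TRUE) {
  stopifnot(is(geometry, "MarkerGeometry"))
  switch(geometry@kind,
    sphere = sphereDrag(r = geometry@diameter / 2, R = geometry@rotationRadius,
                        eta = eta,
                        wallGap = if (applyWallCorrection) geometry@wallGap else NA_real_),
    rod = rodDragTethered(geometry@cellLength, geometry@cellRadius, eta),
    helix = helixDrag(geometry@helixRadius, geometry@pitch, geometry@length,
                      geometry@filamentRadius, eta))
}
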