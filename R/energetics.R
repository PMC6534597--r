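## ATP energy bookkeeping of one motor revolution under n-fold
## cooperativity of the six catalytic sites of the hexameric ATPase.

#' Mechanical work of one revolution
#'
#' A motor producing constant torque does work \eqn{W = 2\pi T_a} per full
#' rotation.
#'
#' @param torque motor torque (pN nm).
#' @return Work per rotation (pN nm).
#' @examples
#' workPerRotation(160)   # ~1000 pN nm
#' @export
workPerRotation <- function(torque) {
  if (any(!is.finite(torque) | torque < 0)) stop("'torque' must be >= 0")
  2 * pi * torque
}

#' ATP budget of one revolution under n-fold cooperativity
#'
#' With six catalytic sites and an n-fold symmetric rotor, `n` sites are
#' active at any time and a full rotation hydrolyses `6 * n` ATP, providing
#' `6 * n * dgAtp` of input energy.
#'
#' @param n rotor symmetry (positive integer).
#' @param dgAtp free energy of one ATP hydrolysis in vivo (pN nm);
#'   default 80.
#' @return A list with `count` (ATP per rotation) and `energy` (pN nm).
#' @examples
#' atpBudget(1)   # 6 ATP, 480 pN nm
#' atpBudget(2)   # 12 ATP, 960 pN nm
#' @export
atpBudget <- function(n, dgAtp = 80) {
  if (any(!is.finite(n)) || any(n < 1) || any(abs(n - round(n)) > 1e-9))
    stop("'n' must be a positive integer")
  if (any(!is.finite(dgAtp) | dgAtp <= 0)) stop("'dgAtp' must be > 0")
  n <- round(n)
  list(count = 6 * n, energy = 6 * n * dgAtp)
}

#' Apparent thermodynamic efficiency
#'
#' Ratio of mechanical output to chemical input per rotation,
#' \eqn{100\,W / (6 n\,\Delta G_{ATP})}, in percent.  Values above 100%
#' signal that the assumed ATP count is too small.
#'
#' @param work mechanical work per rotation (pN nm).
#' @param n rotor symmetry.
#' @param dgAtp ATP free energy (pN nm).
#' @return Efficiency in percent.
#' @examples
#' rotaryEfficiency(workPerRotation(160), n = 1)   # ~209% - the paradox
#' rotaryEfficiency(workPerRotation(160), n = 2)   # ~105%
#' @export
rotaryEfficiency <- function(work, n, dgAtp = 80) {
  if (any(!is.finite(work) | work < 0)) stop("'work' must be >= 0")
  100 * work / atpBudget(n, dgAtp)$energy
}

#' Smallest thermodynamically feasible rotor symmetry
#'
#' The smallest integer `n >= 1` whose apparent efficiency does not exceed
#' `100 * (1 + tolerance)` percent.  The default 10% tolerance treats an
#' efficiency marginally above 100% as consistent with full coupling.
#'
#' @param work mechanical work per rotation (pN nm).
#' @param dgAtp ATP free energy (pN nm).
#' @param tolerance allowed fractional excess over 100%; default 0.10.
#' @return Integer n.
#' @examples
#' feasibleN(workPerRotation(160))   # 2
#' @export
feasibleN <- function(work, dgAtp = 80, tolerance = 0.10) {
  if (!is.finite(tolerance) || tolerance < 0) stop("'tolerance' must be >= 0")
  if (!is.finite(work) || work < 0) stop("'work' must be >= 0")
  max(1L, as.integer(ceiling(work / (6 * dgAtp * (1 + tolerance)) - 1e-12)))
}

#' Full energetics report
#'
#' Work per rotation, the ATP budget and apparent efficiency for each rotor
#' symmetry up to `nMax`, and the smallest feasible symmetry.
#'
#' @param torque motor torque (pN nm).
#' @param dgAtp ATP free energy (pN nm); default 80.
#' @param nMax largest symmetry tabulated; default 6 (the hexamer).
#' @param tolerance tolerance passed to [feasibleN()].
#' @return An [EnergeticsReport].
#' @examples
#' energeticsReport(160)
#' @export
energeticsReport <- function(torque, dgAtp = 80, nMax = 6L, tolerance = 0.10) {
  W <- workPerRotation(torque)
  ns <- seq_len(nMax)
  tab <- data.frame(
    n = ns,
    atp_per_rotation = vapply(ns, function(n) atpBudget(n, dgAtp)$count, numeric(1)),
    energy_in = vapply(ns, function(n) atpBudget(n, dgAtp)$energy, numeric(1)),
    efficiency_pct = vapply(ns, function(n) rotaryEfficiency(W, n, dgAtp), numeric(1)))
  new("EnergeticsReport", workPerRotation = W, dgAtp = dgAtp, table = tab,
      feasibleN = feasibleN(W, dgAtp, tolerance), tolerance = tolerance)
}
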