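---
title: "Measuring the torque of an ATP-driven rotary motor from marker rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the torque of an ATP-driven rotary motor from marker rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotorque)
```

## The assay and its model

The archaellum — the rotary propeller of motile Archaea — is driven by ATP
hydrolysis in the hexameric ATPase FlaI rather than by an ion flux.  A
standard way to measure the torque of such a motor is to attach markers of
different sizes (polystyrene beads of 0.21–1.0 µm, or the cell body itself
in a tethered-cell configuration) to the rotating filament and record how
the rotation rate falls as the viscous load grows.

At low Reynolds number a motor producing constant torque $T_a$ against a
rotational drag $\gamma$ turns at $f = T_a / 2\pi\gamma$.  Measured rates
flatten at low load, which the model absorbs into a single additional
constant $\gamma_a$:

$$f(\gamma) = \frac{T_a}{2\pi(\gamma + \gamma_a)}.$$

$\gamma_a$ admits two readings that are algebraically indistinguishable in
this curve.  In **model A** it is a real drag — the rotating filament's own
friction.  In **model B** the chemistry has a rate-limiting step and the
motor has a zero-load ceiling $f_{\mathrm{noload}}$, giving
$f(\gamma) = (1/f_{\mathrm{noload}} + 2\pi\gamma/T_a)^{-1}$, which is the
same curve with $\gamma_a = T_a / 2\pi f_{\mathrm{noload}}$
(`modelBFriction()` / `modelBNoLoadRate()` convert between the two).  Both
generative mechanisms are implemented in `simulateAngularTrace()` so that
the indistinguishability can be demonstrated rather than assumed.

Units throughout: lengths in nm, time in s, torque and energy in pN·nm,
rotational drag in pN·nm·s.  Viscosity is carried in Pa·s and converted
internally (1 Pa·s = 10⁻⁶ pN·s·nm⁻²).

## What the simulators emulate

**Model A** (`mode = "model_A"`) integrates the overdamped angular Langevin
equation
$d\theta = \frac{T_a}{\gamma_{tot}}dt + \sqrt{2k_BT/\gamma_{tot}}\,dW$ with
$\gamma_{tot} = \gamma + \gamma_a$, by Euler–Maruyama on an internal grid of
one tenth of the camera interval, decimated to camera frames.  For this
constant-coefficient equation the integrator is exact in distribution at
any step size; the subdivision is kept so that the implementation remains
correct if state-dependent terms are ever added.  A guard refuses runs in
which the deterministic advance exceeds half a turn per camera frame
(aliased sampling).

**Model B** (`mode = "model_B"`) is event-driven: exponential chemical
dwells at rate $f_{\mathrm{noload}}\cdot 360/\delta$ for step size
$\delta$ (default 60°, one step per catalytic site of the hexamer),
each followed by a mechanical ramp in which the bead advances one step at
slew rate $T_a/\gamma$, i.e. a ramp of duration $\gamma\delta_{rad}/T_a$.
The chemistry is tightly coupled: the next dwell begins only when the ramp
completes, which is what makes the mean rate exactly
$(1/f_{\mathrm{noload}} + 2\pi\gamma/T_a)^{-1}$.  Thermal fluctuation is
added to the *observed* angle as independent per-frame jitter of variance
$2(k_BT/\gamma)\,dt$ rather than inside the ramp; this preserves the mean
rate exactly while giving frames a realistic Brownian scatter.  It does not
reproduce the full autocorrelation structure of a physically diffusing bead
— a deliberate simplification, since the package uses model B only for
mean-rate and stepping-signature behaviour.

**Camera and optics.**  `renderDualImageStack()` implements the wedge-prism
scheme: each frame holds two pixel-integrated Gaussian spots placed
symmetrically about the projected lateral position along the prism axis,
with separation $= \mathrm{baseline} + \mathrm{gain}\cdot z$.  Defaults are
a 98-nm pixel, 0.5-ms frames and a 130-nm PSF sigma.  The axial gain of the
prism encoding is not fixed by any published number; it is a free
calibration parameter (default 0.5 nm separation per nm of z) that the
`calibrateAxial()` stage estimates from a stack at known heights, exactly
as one would calibrate the real instrument with a piezo stage.  Shot noise
is Poisson, read noise Gaussian; no defocus or aberration model is included
(spots stay Gaussian at all heights), so tracking performance on synthetic
stacks is an upper bound on real performance.

**The benchmark dataset** (`buildBenchmarkDataset()`) emulates the marker
survey that the torque fit consumes: 32 beads of 210 nm, 31 of 490 nm, 26
of 1.0 µm and 12 tethered cells.  Rotation radii are drawn uniformly from
150–350 nm (typical bead orbits; the spread across beads is not constrained
by any published value and is a configuration choice, not a fitted one) and
tethered-cell lengths from 2.0–4.0 µm with a 250-nm cell radius, so that
the cell body width matches the 0.5-µm bead–surface gap used by the wall
correction.  Each marker's rate is the generative model's mean rate at its
true (wall-corrected) drag, times multiplicative Gaussian noise with a 10%
CV chosen to match the visual scatter of measured rate–drag data.  Rates
are drawn from the analytic mean rather than from full Langevin runs:
at the several-second durations the assay uses, the Brownian rate SE is far
below the 10% marker-to-marker scatter, so trace-level noise would be
invisible in the dataset while costing orders of magnitude more time.

## Drag coefficients

All drags are closed forms, linear in viscosity
($\eta = 1.35\times10^{-3}$ Pa·s by default, the measured viscosity of the
high-salt motility buffer at room temperature):

* bead on an eccentric orbit: $\gamma = 8\pi\eta r^3 + 6\pi\eta r R^2$
  (`sphereDrag()`), with $R$ the orbit radius measured by the circle fit;
* near-wall correction (`wallCorrection()`): the method-of-reflections
  series
  $[1 - \tfrac{9}{16}\beta + \tfrac18\beta^3 - \tfrac{45}{256}\beta^4 -
  \tfrac1{16}\beta^5]^{-1}$, $\beta = r/h$, with $h = \mathrm{gap} + r$ and
  a 0.5-µm gap equal to the width of the immobilised cell body.  This
  yields factors 1.4, 1.2 and 1.1 for 1.0-, 0.49- and 0.21-µm beads.  The
  factor is applied to the full two-term bead drag as a single per-size
  scalar, which is what shifts the bead points right in the rate–drag
  plane; whether the translational term alone should carry it is exposed
  as `correctTerm = "translation"`.  Tethered cells are never
  wall-corrected;
* tethered cell (`rodDragTethered()`): half the centred-rod drag
  $\tfrac13\pi\eta L^3[\ln(L/2r) - 0.66]^{-1}$ evaluated at
  $L = 2\times$ cell length, because the archaellar pivot sits at the cell
  end;
* helical filament (`helixDrag()`):
  $2\pi\eta b^2 L\,(2p^2+4\pi^2b^2)(p^2+4\pi^2b^2)^{-1}
  [\ln(2p/r)-0.5]^{-1}$.

**Helix length convention.**  The published working quotes
0.7 pN·nm·s for a filament with $b = 0.22$ µm, $p = 2.1$ µm, $L = 4.3$ µm,
$r = 7$ nm.  Direct evaluation of the formula gives 0.51 pN·nm·s reading
$L$ as the contour length, and 0.61 pN·nm·s reading the 4.3 µm as the
axial extent and converting by $\sqrt{1+(2\pi b/p)^2}$.  Neither reading
reproduces 0.7 at one significant figure; the package defaults to the
contour reading (electron-microscopy length measurements trace the
filament), exposes the axial one behind `lengthConvention = "axial"`, and
reports its own computed value rather than absorbing the discrepancy.
Either value remains the same order as the fitted
$\gamma_a \approx 0.8$ pN·nm·s, which is all the model-A interpretation
needs.

## Geometry: plane, circle, rate, QC

Archaella protrude obliquely, so the bead orbit is an ellipse in the camera
plane and a circle only in its true rotation plane.  `findRotationPlane()`
searches the two polar angles of the plane normal on a 1° grid seeded by
the SVD plane of the point cloud, refining to 0.1°, and minimises the
coefficient of variation of the projected radial distances — zero for a
perfect circle.  On noiseless circles both angles are recovered to the
0.1° grid floor.  On tracked data with anisotropic noise (axial
localization error is a few times the lateral error) the CV objective is
biased a few degrees toward smaller tilt, because tilting the candidate
plane away from z mixes less axial noise into the radii; the bias has
negligible effect on the fitted radius and rate, which is what the drag
and torque stages consume.

`projectAndFitCircle()` seeds a Kåsa algebraic fit and refines it by
geometric least squares.  `estimateRate()` unwraps the in-plane phase and
takes the rate from the least-squares slope of phase versus time,
CCW-positive about the plane normal oriented toward +z (the camera of an
inverted microscope looks along −z; the convention affects labels only).
The rate SE is taken from the dispersion of slopes over eight
non-overlapping blocks rather than from OLS residuals: for Brownian phase
noise the OLS residual formula underestimates the slope variance by an
unbounded factor, while the block estimator stays calibrated for both
white and random-walk phase noise.

`qcTrace()` encodes the trace-selection rule that only smooth rotation may
enter the torque fit.  Stepping with the hexamer's 60° periodicity is
detected by folding the phase modulo 60° into twelve 5° bins and
estimating each bin's speed from its occupancy (time spent per bin, whose
inverse is proportional to local speed); the modulation depth is
(max−min)/mean of the twelve bin speeds, with traces above 0.5 rejected.
Occupancy is used instead of per-frame speeds because at 0.5-ms sampling
the Brownian contribution to a single-frame speed is of order the mean
speed itself, which would reject genuinely smooth traces; the occupancy
estimator's noise floor falls as $1/\sqrt{\mathrm{revolutions}}$, so
traces should span at least ~10 revolutions — the pipeline's default.
Saw-tooth rotation is caught separately: a trace is unsmooth if any 60°
sector crossing takes more than five times the median crossing interval.
The 0.5 depth threshold and factor 5 are configurable defaults; no
published criterion fixes them.

## Torque fit and uncertainties

`fitConstantTorque()` performs nonlinear least squares of
$f = T_a/2\pi(\gamma+\gamma_a)$ over QC-accepted markers, weighted by
$1/\mathrm{SE}^2(f)$ when rate SEs are available.  Because $T_a$ enters
linearly, the fit profiles it in closed form and optimises the residual sum
of squares over $\gamma_a \ge 0$ alone; this reaches the same optimum as
the usual linearization-initialised Gauss–Newton but cannot be derailed by
a poor start and is an order of magnitude faster, which matters for the
1000-resample case bootstrap that provides the 95% confidence intervals
(sample sizes of 12–32 per class are too small for comfortable asymptotics).
A $\gamma_a$ optimum at the zero boundary is reported as $\gamma_a = 0$
with a message.  The fit is done in rate space, not in $1/f$: reciprocal
transforms inflate the noise of the fastest markers.  Both the raw and the
wall-corrected drag variants are available; the corrected one is the
headline estimate.

`apparentTorqueCurve()` tabulates $2\pi\gamma f$ and
$2\pi(\gamma+\gamma_a)f$ per marker.  Under the model the second column is
exactly $T_a$ for noiseless data and scatters around it with no dependence
on load for noisy data.  One diagnostic subtlety: with multiplicative rate
noise the same noise realisation enters both the subtracted torque and the
measured rate, so a regression of one on the other has a small positive
expected slope by construction; trend tests in the package's suite are
therefore made against the drag (the noise-free load axis).

`fitRateVsDiameter()` fits the sphere markers with the linear form
$f = A\phi + B$ in bead diameter $\phi$.  A published version of this fit
prints the reciprocal form with a negative coefficient of the same
magnitude, which is dimensionally inconsistent with the plotted rates; the
linear form is a deliberate correction and reproduces ~22 Hz at 210 nm and
~3 Hz at 1 µm with the printed constants ($A = -0.024$ Hz/nm,
$B = 27$ Hz).  Note that three summaries of the zero-load rate coexist and
disagree at the ~20% level — the diameter-fit intercept $B$, a ~25 Hz
extrapolation by eye, and $T_a/2\pi\gamma_a \approx 31$ Hz from the torque
fit; the package reports them as alternative summaries and does not
reconcile them.

## Energetics

A constant-torque motor does $W = 2\pi T_a$ of work per revolution
(~1000 pN·nm at 160 pN·nm).  With $\Delta G_{ATP} = 80$ pN·nm in vivo and
one ATP per catalytic site per revolution, six ATP provide only
~480 pN·nm — an apparent efficiency near 200%, which is the paradox that
motivates n-fold cooperativity: an n-fold symmetric rotor keeps $n$ of the
six sites active at any time, so a revolution hydrolyses $6n$ ATP.
`rotaryEfficiency()` implements the direct ratio
$100\,W/(6n\,\Delta G_{ATP})$, giving 209%, 105%, 69.8% and 34.9% for
$n = 1, 2, 3, 6$; quoted values of 67% and 33% for $n = 3, 6$ correspond to
rounding via $100\cdot 2/n$, and both paths are noted here rather than
silently merged.  `feasibleN()` returns the smallest $n$ whose efficiency
does not exceed 100%·(1 + tolerance); the default 10% tolerance encodes
the judgement that 104.7% at $n = 2$ counts as consistent with full
coupling, so the headline answer is $n = 2$.

## Problem sizes and reproducibility

The test-suite simulations are sized to hold Monte-Carlo error well below
each assertion's tolerance while keeping the default run in tens of
seconds: rate-recovery traces use 1–8 s of simulated data per marker;
the tracking round-trip benchmark uses 2000 frames at 10⁴ photons per spot
(3D RMSE stays under 10 nm); the model A/B equivalence sweep uses ten drag
values spanning 0.1–100 pN·nm·s with ≥10⁵ chemical steps per point (~0.3%
rate SE); and fit-coverage checks run 100 dataset seeds with 1000 bootstrap
resamples each.  Every stochastic stage takes an explicit seed, the
pipeline derives per-marker seeds from its master seed, and rerunning a
pipeline configuration reproduces its JSON reports byte for byte.

## Limitations

* No real data ship with the package; all validation is against synthetic
  data whose generative assumptions (Gaussian PSF, linear axial encoding,
  multiplicative rate noise, no drift or stage vibration) are idealised.
  Passing tests demonstrate correctness of the computations, not the
  instrument model.
* The plane-search objective is noise-anisotropy biased, as described
  above.
* No hydrodynamic coupling between bead and filament, no boundary-element
  numerics — drag enters only through the closed forms; and the two prism
  images are treated as optically independent.
* Saw-tooth (stepping) traces are only rejected, never analysed; dwell
  statistics and directional switching are out of scope.
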