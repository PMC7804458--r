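---
title: "Calibrating AFM colloidal probes with optical tweezers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating AFM colloidal probes with optical tweezers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tweezercal)
```

# The calibration problem

A colloidal probe is an AFM cantilever with a micrometre-scale sphere glued
to its end. The glue mass and distribution, the off-centre placement of the
sphere, and the sphere's own mass all change the lever's effective spring
constant, so geometry-based calibrations (Sader, thermal noise, reference
levers) carry uncertainties that are hard to bound — and dynamic methods
probe nanometre amplitudes while colloidal-probe experiments deflect the
lever by micrometres. tweezercal implements a *direct* calibration: an
optical trap pulls on the glued bead with a known force while the bead
centre is tracked in bright-field images, and Hooke's law
$F = k\,\Delta Z$ yields the spring constant at each laser power.

The workflow has four stages, each a package module:

1. **Trap-stiffness calibration** from viscous-drag sweeps.
2. **Ray-optics force model** for the trapped sphere (context and sanity
   checks; the calibration itself never derives forces from optics).
3. **Bead-centre localization** from 2D images.
4. **Probe calibration**: the parked-beam protocol and the cantilever
   models.

A synthetic-data generator with known ground truth closes the loop so every
stage is testable without instrument data.

# Trap stiffness from viscous drag

A bead held in the trap while the stage moves at speed $v$ experiences the
wall-corrected Stokes drag

$$F = \frac{6\pi\mu v r}{1-\frac{9}{16}\frac{r}{h}
 + \frac{1}{8}\left(\frac{r}{h}\right)^{3}
 + \frac{45}{256}\left(\frac{r}{h}\right)^{4}
 - \frac{1}{16}\left(\frac{r}{h}\right)^{5}},$$

with $\mu$ the dynamic viscosity, $r$ the bead radius and $h$ the distance
from the sphere centre to the surface. `faxen_factor()` evaluates the
polynomial correction; a sphere whose surface sits five radii from the wall
($h = 6r$) pays about 10% extra drag. The correction is a truncated series:
it is monotone in $r/h$ only up to $r/h \approx 0.87$ and should not be
trusted closer to contact than that. `drag_conditions()` deliberately has
no default for $h$ — assuming unbounded fluid silently is exactly the kind
of error the correction exists to prevent.

`stiffness_from_sweep()` converts each record's stage speed to a drag force
and regresses force on bead displacement; the slope is the trap stiffness
$St$ at that power. Two details matter:

* **Sawtooth offsets.** The stage alternates direction, and the bead sits
  at opposite edges of the (finite-width) trap in the two directions. That
  offset is $\pm A\,\mathrm{sgn}(v)$, which a *single* free intercept
  cannot absorb — it biases a pooled fit. The regression therefore uses one
  free intercept per stage direction, which absorbs the trap width exactly
  and reduces to an ordinary free-intercept fit for one-directional data.
  The pooled and through-origin slopes are still reported for
  transparency.
* **Heteroscedastic stiffness points.** The error of a per-power stiffness
  estimate grows with the stiffness itself (the bead excursion shrinks as
  $F/St$ while the localization noise stays fixed). `fit_stiffness_vs_power()`
  therefore weights points by their inverse squared standard error when
  those are available; unweighted least squares is used otherwise. With
  weighting, the 95% confidence intervals on the fitted slope and
  intercept are close to nominal on synthetic sweeps (the test suite
  measures coverage over 200 seeded runs).

Stiffness is only proportional to laser power up to a saturation knee.
`detect_linear_range()` formalizes the by-eye rule "discard points beyond
the linear region" as a longest-prefix test: starting at the lowest power,
the longest run of points whose straight-line fit leaves every relative
residual within `rel_tol` (default 0.05, configurable) defines the linear
range. `stiffness_at()` refuses powers outside it — powers beyond the knee
were discarded during calibration, so evaluating there would be silent
extrapolation.

# Ray-optics forces

For beads more than ten wavelengths across (`regime_check()`), geometric
optics describes trapping. A single ray of power $P$ hitting the sphere at
incidence angle $\theta$ (refraction angle $r$, Fresnel power coefficients
$R, T$) exerts

$$F_Z = \frac{nP}{c}\left\{R\sin 2\theta -
  \frac{T^2[\sin(2\theta-2r) + R\sin 2\theta]}{1+R^2+2R\cos 2r}\right\},
\qquad
F_X = \frac{nP}{c}\left\{1 + R\cos 2\theta -
  \frac{T^2[\cos(2\theta-2r) + R\cos 2\theta]}{1+R^2+2R\cos 2r}\right\}.$$

These closed forms are the geometric sums over the first reflected ray and
the infinite family of transmitted rays escaping after $n$ internal
reflections; the test suite verifies them against an independent
momentum-balance summation of those partial rays to $10^{-6}$ relative on
100 random configurations. Conventions worth stating explicitly:

* $\theta$ is the **incidence** angle and $r$ the **refraction** angle
  (the assignment under which the expressions equal the partial-ray sum).
* Polarization is rarely tracked in this kind of calibration, so the
  default Fresnel coefficient is **unpolarized** — the mean of the s and p
  power reflectances — with `"s"` and `"p"` available explicitly.
* The Fresnel coefficients are computed from the refractive indices (the
  angle-only forms are indeterminate at normal incidence).
* The dimensionless efficiencies $Q = Fc/(nP)$ cannot exceed 2 in
  magnitude (a photon cannot transfer more than twice its momentum);
  `trap_forces()` warns, rather than errors, if a supplied geometry
  violates this.

The model is single-ray by design: in this calibration the trap force
comes from the drag calibration, not from integrating a focused beam, so
beam-profile integration is out of scope.

# Bead localization

The bead appears as a dark disk on a bright field. `binarize()` thresholds
(Otsu or fixed), keeps the largest connected component and fills holes;
`edge_points()` extracts the 0.5-level contour of the mask with sub-pixel
interpolation. Coordinates are 0-based pixels, row = microscope Z (the
direction the optical force displaces the probe), column = Y.

Two centre estimators are provided:

* `lsq_circle` (default, deterministic): an algebraic Kåsa fit, solved on
  mean-centred coordinates for exact translation equivariance, then
  polished by Gauss–Newton iterations on the true geometric objective
  $\sum_i (|p_i - c| - R)^2$. The polish matters: under boundary noise the
  algebraic and geometric optima differ measurably, and the geometric one
  is the estimator the residuals describe.
* `triples_mean`: the construction that motivates the method — the
  circumcenter of three edge points, averaged over many random triples.
  Circumcenters of *thin* triangles amplify boundary noise without bound
  (the error distribution is heavy-tailed), so triples are drawn with one
  vertex from each third of the contour-ordered boundary, which keeps the
  per-triple error comparable to the boundary noise. A seed is mandatory;
  triples with triangle area below $10^{-9}\,\mathrm{px}^2$ are rejected
  as degenerate.

On synthetic noise-free frames the localization bias is below 0.05 px; with
0.5 px boundary noise on a 250 px-radius contour sampled at 200 points,
500 triples put the `triples_mean` centre within about 0.1 px RMS of
truth (measured in the test suite).

`localization_uncertainty()` propagates a centre error of $e$ pixels on a
bead imaged at $d$ pixels to a relative force-constant uncertainty of
$100\,e/d$ percent. This linear model reproduces the expected window —
0.2% at 500 px, about 0.07% at 1500 px, at most 1% for a 5 px error — and
is adopted as the documented propagation path; the implicit assumption is
that the tracked deflection is of the order of the bead diameter.

# Probe calibration

The protocol: focus the bead, record its centre with the trap off (the
reference), then repeatedly set a laser power, park the beam at the distant
edge of the bead, record the displaced centre, and increase the power —
at least five powered steps, strictly increasing. If the cantilever normal
is tilted by $\alpha$ against the force, the force is corrected by
$\cos\alpha$ (`cosine_correction()`).

**Force model.** How the trap force follows from the calibrated stiffness
when the beam is parked off-centre is the one genuinely open modelling
question in this method. tweezercal adopts
$F = St(P)\cdot d \cdot \cos\alpha$ with $d$ the trap-to-bead-centre
offset, defaulting to the bead radius ("parked at the distant edge"). This
treats the trap as a linear spring out to the parking offset, which likely
overreaches the harmonic region of a real trap; the assumption is isolated
in `step_force()` so an alternative force model is a one-function swap.

Per step, Hooke's law gives $k = F/\Delta Z$. Two cantilever models are
fitted:

* **Constant** (rectangular levers): $k$ summarized as mean ± sample SD
  over at least 5 points.
* **Logarithmic + plateau** (V-shape levers): below a breakpoint $P^*$,
  $k(P) = a\ln P + bP + c$ by least squares; above it, a plateau mean ±
  SD. If $P^*$ is not supplied it is chosen by exhaustive search over the
  observed powers (at least 5 points at or below, 2 above each candidate),
  minimizing the combined residual sum. The two branches are *not* forced
  to meet: real fitted functions of this shape are discontinuous at
  $P^*$, and the model reports the gap magnitude instead of hiding it.

**Automatic kind selection.** With `geometry = "auto"`, both kinds are
fitted and compared by AICc. Because $k = F/\Delta Z$ with (near-)uniform
jitter on the measured deflection, $k$-space residuals are heteroscedastic
— noisier at low power — which makes naive residual comparison prefer the
flexible model on truly-constant data. The comparison is therefore done on
the homoscedastic displacement scale (each kind at its displacement-space
optimum), and the small-sample AICc penalty is used because a 4-parameter
alternative against ~9 points is exactly where plain AIC overfits. A
geometry hint always overrides the automatic choice.

# The synthetic generator

`ground_truth()` fixes the emulated experiment; all randomness derives
from its mandatory seed, and every stochastic helper restores the caller's
RNG state. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| bead | 15 µm diameter, 30 nm/px (500 px) | smallest nominal bead of the imaging configuration |
| viscosity | 1.0 mPa s | water at room temperature |
| wall distance | 3 bead radii | near-surface but safely inside the valid Faxén range |
| trap line | $St(P) = 1.039P + 0.2582$ mN/m, knee 60% | the calibrated trap shape; saturation above 60% power |
| trap offset | bead radius | beam parked at the distant edge |
| rectangular $k_0$ | 0.030 N/m | typical soft colloidal-probe lever |
| V-shape $(a,b,c)$, $P^*$, plateau | $0.0528, -0.0009, -0.0422$, 30%, 0.1171 N/m | the fitted V-shape characteristic used as generator truth |
| image noise | 0.02 (normalized intensity), 1 px edge blur | high-contrast bright-field imaging |
| position jitter | 0.5 px | sub-pixel tracking error |
| sawtooth offset | 0.25 µm | finite trap width in the drag sweeps |

The stiffness-versus-power relation used as generator truth carries no
inherent units; tweezercal reads it in mN/m (equivalently nN/µm) so that
the implied probe deflections are micrometre-scale, matching the
deflection regime the method targets, with spring constants of order
0.03–0.12 N/m. One
consequence is internal to the drag sweeps: for bead excursions $F/St$ to
be micrometres — large against the 0.25 µm sawtooth and the 15 nm
position jitter — the synthetic stage must sweep fast (up to ~0.4 m/s in
the defaults used by tests and the `simulate` command). The fitting code is
unit-agnostic throughout; only the generator needs a self-consistent
choice.

What the generator does **not** emulate: diffraction and defocus (the
rendered edge is a 1 px Gaussian profile, not a point-spread function),
occlusion of the bead by the cantilever, drift, non-spherical particles,
and fluid dynamics beyond quasi-static Stokes drag. Passing tests
therefore demonstrate that the estimators invert the generator's physics
at realistic noise levels — not that a real instrument meets the same
error budget.

# Numerical choices and degenerate inputs

* Relative-residual tolerance for linear-range detection: 0.05.
* Collinear-triple rejection: triangle area $< 10^{-9}$ px².
* Gauss–Newton circle polish: at most 100 iterations, step tolerance
  $10^{-12}$ relative to the radius.
* Zero displacement → error (no deflection measured); negative apparent
  $k$ → error (mis-tracked frames); non-positive fitted trap slope →
  flagged in the result, not an exception.
* Powers ≤ 0 are a domain error wherever $\ln P$ appears.
* All randomness is seeded; derived child seeds stay below $2^{31}$.

Problem sizes in the shipped tests: sweeps of 16 records at 10 powers;
frames of 192–1000 px (test images use a 60 px-radius bead, the generator
default is 250 px); 200-seed coverage simulations for the trap line and
both cantilever models; 100 random ray-optics configurations against the
partial-ray oracle.

# Known limitations

* The parked-beam force model (trap as linear spring out to one bead
  radius) is an assumption, not a measurement; all spring constants
  inherit it multiplicatively.
* The Faxén polynomial is unreliable within ~0.15 radii of wall contact.
* The uncertainty model for centre-localization error is the simple ratio
  error/diameter; a full propagation would need the actual deflection
  magnitudes.
* Axial (X) localization, occlusion handling and non-spherical particles
  are out of scope.
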