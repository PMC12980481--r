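---
title: "Viscoelastic parameter extraction from AFM stress relaxation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelastic parameter extraction from AFM stress relaxation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxfit)
```

## The measurement this package models

Soft hydrogels — both micrometre-scale microgel beads and macroscopic bulk
gels — are routinely characterized by colloidal-probe AFM stress-relaxation
tests. A spherical probe of radius $R_p$ (typically 5 µm) glued to a soft
cantilever is driven into the sample at constant velocity $v$ until a preset
contact force is reached (phase 1), held at constant displacement for
$t_{ges}$ seconds while the force decays (phase 2), and then retracted
(phase 3). The decay during the hold carries the viscous signature of the
material; the residual force after a long hold isolates its equilibrium
elasticity. Phase 3 is dominated by adhesion artifacts and is deliberately
outside the scope of every quantitative routine here.

`relaxfit` provides the full analysis chain for such experiments: a
semi-analytic forward model, feature extraction, two-stage inverse parameter
identification, and the calibration of closed-form surrogate equations that
map a handful of curve features directly to material parameters.

## Material model and forward solution

The material is a standard linear solid (single-term Prony series): a spring
$E_0$ in parallel with a Maxwell arm $(E_1, \tau)$, giving the relaxation
modulus

$$E(t) = E_0 + E_1 e^{-t/\tau},$$

with instantaneous modulus $E_u = E_0 + E_1$, dashpot viscosity
$\eta = \tau E_1$, and Poisson ratio $\nu = 0.45$ by default (nearly
incompressible gel, overridable everywhere). Contact follows the Hertz law
for a sphere, $F = \tfrac{4}{3}\tfrac{E}{1-\nu^2}\sqrt{R_{eff}}\,
\delta^{3/2}$, with three geometry options:

* `half_space` — bulk gel, $R_{eff} = R_p$;
* `sphere_single` — microgel in one contact,
  $R_{eff} = (1/R_p + 1/R)^{-1}$;
* `sphere_double` (microgel default) — the probe–gel contact in series with
  the gel–substrate contact underneath. Since each Hertz contact has
  $F = K\delta^{3/2}$ with $K \propto \sqrt{R}$ and total displacement is
  the sum of the two contact displacements, compliances add as $K^{-2/3}$
  and the pair is force-equivalent to a single contact with
  $R_{eff} = (R_1^{-1/3} + R_2^{-1/3})^{-3}$. This is the double-contact
  correction needed because a microgel resting on a rigid substrate deforms
  on both sides.

Viscoelasticity enters through the Lee–Radok hereditary integral, valid
while the contact area is non-decreasing — which holds for phases 1 and 2.
During the constant-velocity ramp ($\delta = v t$),

$$F(t) = C_g\Big[E_0 (v t)^{3/2} + E_1\,\tfrac{3}{2} v^{3/2}
  \int_0^t \sqrt{s}\, e^{-(t-s)/\tau}\, ds\Big],
  \qquad C_g = \frac{4\sqrt{R_{eff}}}{3(1-\nu^2)}.$$

The kernel integral has the exact closed form
$\tau^{3/2}\big(X - D(X)\big)$ with $X = \sqrt{t/\tau}$ and $D$ the Dawson
function, which we evaluate through `pracma::erfi` for $X \le 4.5$ and the
asymptotic series in $1/X$ beyond. `ramp_force()` defaults to adaptive
quadrature at relative tolerance $10^{-8}$; whole-trajectory sampling inside
`simulate_protocol()` uses the vectorized closed form. The two paths agree
to about $10^{-15}$ relative and both are pinned in the test suite against a
$10^6$-step fixed-step Riemann oracle to five significant digits.

`simulate_protocol()` locates the trigger time $t_1$ by bracketed root
finding (the purely elastic $E_0$ response bounds the force from below, so
the elastic ramp time bounds $t_1$ from above; refined to $10^{-12}$
relative), sets $u_{max} = v t_1$, and emits the hold force

$$F(t) = C_g\big[E_0 u_{max}^{3/2} + E_1 J\, e^{-(t-t_1)/\tau}\big],
\qquad J = \tfrac{3}{2} v^{3/2} \int_0^{t_1}\sqrt{s}\,e^{-(t_1-s)/\tau} ds,$$

continuous at $t_1$, strictly decreasing for $E_1 > 0$, and settling on the
purely elastic plateau $C_g E_0 u_{max}^{3/2}$ once $t - t_1 \gg \tau$. Two
consequences used throughout: the hold decay is exactly single-exponential,
so its half-decay time is $t_1 + \tau\ln 2$; and in the fast-ramp (step
load) limit $(F_1 - F_0)/F_0 \to E_1/E_0$.

The model deliberately omits: finite-strain elasticity (indentations of a
few µm into gels of tens of µm stretch the small-strain Hertz assumption),
adhesion, poroelastic solvent migration (the mechanism that dominates bulk
gels at long times — fits of bulk-gel data therefore describe an effective
viscoelastic response), cantilever compliance (at a 10 nN trigger on a
0.08 N/m lever the deflection is an order of magnitude below typical
indentation, and the displacement ramp is imposed directly), and
hydrodynamic drag (piconewtons at these velocities).

## Feature extraction

`extract_features()` reduces a curve to the scalars the surrogate equations
consume: $F_1$ (force at the first hold sample — read at the phase boundary
rather than as a global maximum so trigger overshoot does not leak in),
$F_0$ (mean of the last `smoothing_window` raw hold samples; the tail is
flat to $e^{-t_{ges}/\tau}$, so this is the plateau on clean data and a
noise average on measured data), $t_1$, $u_{max}$, and the midpoint
crossing time $t_{mid}$ where the force first falls below
$F_{mid} = (F_1+F_0)/2$, located by linear interpolation between the
bracketing samples of a centered moving-average-smoothed force (default
window 21 samples; raw values are kept at the window edges). Smoothing
affects only the crossing search, never $F_1$ or $F_0$. The crossing must
be strict — a flat, purely elastic hold raises a "no relaxation midpoint"
error rather than returning a fabricated time. Whether instrument software
locates midpoints on raw or smoothed force varies; the window is a
documented, configurable choice.

`fit_hertz_approach()` fits the apparent Young's modulus to the phase-1
force–indentation record; because the model is linear in $E$ the
least-squares solution is closed-form. For viscoelastic materials the
apparent modulus lies between $E_0$ and $E_0 + E_1$ and grows with
indentation velocity — the stiffening-with-speed signature that motivates
the full relaxation analysis. The contact point is exact (zero) for
synthetic curves and a free offset argument for measured ones.

## Two-stage inverse identification

Experiments are run at three velocities (1, 3, 5 µm/s by convention) on the
same material, and the inverse problem is split to mirror the physics:

1. **Stage 1, `fit_E0()`.** After a hold much longer than $\tau$ the
   viscous arm is fully relaxed, so only $E_0$ controls the end-of-hold
   force. The objective $z_1(E_0) = \sum_{i=1}^{3} |F_{sim,i} - F_{exp,i}|$
   compares the elastic Hertz force at each experiment's measured
   $u_{max,i}$ with its measured end-of-hold force (the mean of the
   trailing 1% of hold samples). Residuals enter in absolute value — a
   signed sum would let opposite mismatches cancel. $z_1$ is piecewise
   linear and unimodal in $E_0$; bounded scalar minimization suffices. If
   the hold does not outlast $\tau$ the estimate is biased upward by the
   unrelaxed remainder $\propto E_1 e^{-t_{ges}/\tau}$; the package flags
   optima at the bounds but deliberately does not "correct" the bias.
2. **Stage 2, `fit_viscous()`.** With $E_0$ frozen, candidates $(E_1,\tau)$
   are scored against the full hold histories:
   $z_2 = \sum_i \sum_j [(F_{sim,ij} - F_{exp,ij})\, t_j/t_{ges}]^2$, with
   $t_j$ measured from the hold start, the simulated force driven by each
   experiment's imposed displacement profile (ramp at its velocity to its
   measured $u_{max}$), and the experimental force linearly interpolated
   onto the simulation time grid. The $t_j/t_{ges}$ factor up-weights the
   late, information-rich part of the decay. By default only hold samples
   enter the sum; `include_phase1 = TRUE` adds the ramp with the same
   normalizer. The optimizer is a seeded differential-evolution global
   stage (rand/1/bin, population 20 by default, never below 15) followed by
   a Nelder–Mead polish; no suitable evolutionary-optimization package is
   assumed, so the DE loop is implemented in the package and is
   deterministic given the seed.

Stage 2 never touches $E_0$; `fit_material()` chains the stages and returns
both objective values, the evaluation count and the seed. The default $E_1$
search box is capped at $0.2\,E_0$, the upper end of the experimentally
observed range for these gels; widen it for stronger viscous arms. On
noiseless synthetic data the triple is recovered to well within 1%; under
10 pN force noise the median error across seeded replicates stays within
5%.

## Surrogate equations and their calibration

Full inverse fitting is accurate but slow for large datasets. The surrogate
route predicts the parameters directly from curve features:

$$\hat E_0 = \alpha_1 \frac{F_0}{u_{max}^{\alpha_2} R^{\alpha_3}}, \qquad
  \hat\tau = \beta_1 (t_{mid} - t_1), \qquad
  \hat E_1 = \gamma_1 \Big(\frac{F_1-F_0}{F_1}\Big)^{\gamma_2}
             e^{\gamma_3 t_1/\hat\tau}\, \hat E_0 .$$

The forms are anchored in the mechanics: the first inverts the Hertz law
(exactly so when $R$ is the effective contact radius; with the microgel
radius instead, $\alpha_3$ absorbs the radius-to-contact-radius mapping as
a power law), the second is the half-decay identity ($\beta_1 = 1/\ln 2$
for an ideal single-exponential hold), and the third starts from the
step-load linearization $(F_1-F_0)/F_0 \approx E_1/E_0$ with an exponential
factor meant to compensate the relaxation already spent during the finite
ramp. `analytic_seed_coefficients()` returns exactly these mechanical
seeds.

`build_grid_dataset()` regenerates the factorial calibration study: every
combination of $E_0 \in \{500, 1000, 1500, 2000\}$ Pa,
$R \in \{20, 35, 50\}$ µm, trigger $F_1 \in \{2, 4, 6, 8, 10\}$ nN,
$E_1/E_0 \in \{0.05, 0.1, 0.15, 0.2\}$, $\tau \in \{0.05, 0.1, 0.15,
0.2\}$ s and $v \in \{3, 5\}$ µm/s — 1,920 runs with a fixed 5 µm probe,
simulated noiselessly (2 kHz sampling, 10 s hold, double-contact geometry)
and reduced to features. `calibrate_coefficients()` then minimizes the
mean-squared prediction error per output, sequentially: the $\alpha$'s by
Levenberg–Marquardt from the analytic seed, $\beta_1$ in closed form, and
the $\gamma$'s by the seeded evolutionary search plus polish, consuming the
already-calibrated $\hat E_0$ and $\hat\tau$. The printed criterion uses
absolute residuals; `residuals = "relative"` switches to relative ones. A
safeguard keeps the analytic seed whenever a stage fails to improve on it,
so calibration can never end worse than the seed. Coefficients are bound to
strict SI units; `error_map()` re-simulates any force–radius plane at fixed
conditions to chart where the predictors are trustworthy, and warns outside
the calibrated ranges.

### What the calibration achieves here — and what it cannot

On this forward model the sequential calibration drives the maximum
relative error over all 1,920 runs to a fraction of a percent for $E_0$
(the only approximation is the power-law fit of the double-contact radius
mapping across three radius levels) and to effectively zero for $\tau$ (the
half-decay identity is exact up to sampling interpolation). Both are
recomputed by `scripts/acceptance.R` and asserted in the test suite.

The $\hat E_1$ equation is different, and the package reports this
honestly rather than tuning around it. Across the calibration grid the
ramp-to-relaxation ratio $t_1/\tau$ spans roughly 0.6 to 35: soft gels
loaded to 10 nN at 3 µm/s ramp for ~1.7 s, so at $\tau = 0.05$ s the ramp
lasts ~35 time constants and more than 99% of the viscous force has already
relaxed when the hold begins ($(F_1-F_0)/F_1$ drops to ~0.2%). The exact
correction factor implied by the hereditary integral grows essentially
linearly in $t_1/\tau$ over this range, while the equation models it as an
exponential $e^{\gamma_3 t_1/\tau}$. A direct minimax search over
$(\gamma_1,\gamma_2,\gamma_3)$ against the exact surrogate relation bounds
the best achievable maximum relative $E_1$ error near 43% on this grid —
least-squares calibration lands in the hundreds of percent at the
short-$\tau$, slow-ramp corners — so no coefficient choice can reach
single-digit worst-case accuracy for $E_1$ under these study conditions
with this functional form. The acceptance suite therefore carries one
deliberately failing assertion for the $E_1$ bound; the corresponding
worst-case behaviour is easy to inspect with `error_map(..., "E1")`. In
practice the predictor is serviceable when $t_1 \lesssim$ a few $\tau$
(fast ramps, slower materials) and should not be used deep in the
ramp-relaxed regime, where the inverse fit (`fit_material()`) remains
accurate.

## Synthetic data

`generate_curve()` wraps the forward model with a seeded noise model:
additive Gaussian force noise (default 10 pN, the thermal-noise scale of a
soft lever), optional linear drift and fractional trigger overshoot. A seed
is mandatory whenever noise is non-zero and identical seeds reproduce
curves bit-for-bit. `generate_study_fixture()` writes the emulated study —
microgels (radii drawn around 33.9 µm, i.e. half the reported mean bead
diameter, with a stiffness below the bulk gel's as observed experimentally)
and bulk half-spaces, at 1/3/5 µm/s, ten replicates each — as annotated CSV
plus a JSON manifest with the ground truth. Fixture defaults chosen once:
microgel $(E_0, E_1, \tau) = (400\ \mathrm{Pa}, 60\ \mathrm{Pa},
0.12\ \mathrm{s})$, bulk $(1200\ \mathrm{Pa}, 180\ \mathrm{Pa},
0.8\ \mathrm{s})$, both with $E_1/E_0 = 0.15$; fixtures are written at
500 Hz so a full set stays a few MB of text, while the core protocol
default is 2 kHz.

The generator emulates sampling, noise, drift and overshoot. It does not
emulate poroelastic long-time relaxation, adhesion, contact-point
uncertainty, instrument vibration or cantilever dynamics — so passing
recovery tests demonstrate correctness of the analysis chain under the
stated model, not robustness to every artifact of real measurements.

## Numerical choices, in one place

* Ramp kernel: exact Dawson-function closed form for trajectories;
  adaptive quadrature (rel. tol $10^{-8}$) as the `ramp_force()` default;
  both pinned to a $10^6$-step Riemann oracle in tests.
* Trigger time: bracketed root on $[0, t_{elastic}]$, relative tolerance
  $10^{-12}$.
* Midpoint: strict crossing on smoothed force, linear interpolation;
  window 21 samples, configurable; no crossing raises an error.
* Stage-1 minimization: `stats::optimize` on the unimodal $z_1$.
* Global stages: in-package rand/1/bin differential evolution
  (population $\ge 15$, $F = 0.8$, $CR = 0.9$), Nelder–Mead polish,
  everything behind an explicit integer seed with the caller's RNG state
  restored afterwards.
* Problem sizes in the shipped tests: unit tests sample at 250–2000 Hz
  with 10 s holds; the calibration acceptance regenerates the full
  1,920-run grid at 2 kHz; noisy Monte-Carlo checks use 20–200 seeded
  replicates.
* Units: strict SI internally (m, s, N, Pa); curve files carry
  unit-suffixed column names and `# key = value` metadata written to 12
  significant digits.

## Known limitations

Small-strain Hertz contact at indentations that are not always small;
purely viscoelastic constitutive response (no poroelasticity — bulk-gel
parameters are effective, not intrinsic); single-term Prony series only;
$\hat E_1$ surrogate unreliable when the ramp outlasts a few relaxation
times (see above); no contact-point detection for measured curves beyond a
manual offset; no adhesion model, hence no phase-3 analysis.
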