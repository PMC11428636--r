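---
title: "Methods: pulsatile hemodynamics and wall shear stress index profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatile hemodynamics and wall shear stress index profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemowall)
```

## Scope and intent

`hemowall` implements the post-imaging stages of an arterial hemodynamic
profiling workflow at desk scale: blood rheology, pulsatile flow physics,
endothelial wall indices derived from wall shear stress (WSS), pressure
waveform morphology, and mesh-independence analysis. Patient-specific 3D
finite-volume simulation of an aorta requires segmented geometry and a
commercial solver; neither is reproducible in a small reusable package.
Instead the package realizes the same governing equations — incompressible
momentum balance with a Carreau generalized-Newtonian viscosity, rigid
stationary wall, no-slip — in the one geometry where analytic verification
exists: fully developed axisymmetric flow in a straight rigid tube. This is
stated openly as a desk-scale stand-in; every operation downstream of the
solver (indices, waveform analysis, sensitivity analysis) is
geometry-agnostic and applies unchanged to fields exported from a full 3D
simulation.

## Blood rheology

The Carreau model interpolates between a zero-shear viscosity $\mu_0$ and
an infinite-shear viscosity $\mu_\infty$:

$$\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
  \left[1 + (\lambda\dot\gamma)^2\right]^{\frac{n-1}{2}}$$

with defaults $\mu_0 = 0.056$ Pa s, $\mu_\infty = 0.0035$ Pa s,
$\lambda = 3.313$ s, $n = 0.568$, $\rho = 1060$ kg/m³ — a widely used fit
for whole human blood. The bracket is written with $(\lambda\dot\gamma)^2$,
the dimensionally consistent form (the product $\lambda\dot\gamma$ is
dimensionless); some sources typeset the same law ambiguously as
$\lambda\dot\gamma^2$, but only the squared-product form gives a law whose
shape is invariant under a change of time units, so no alternative form is
exposed. Two properties worth noting:

* the apparent viscosity is bounded in $[\mu_\infty, \mu_0]$ and monotone
  non-increasing for $n < 1$;
* the high-shear approach to $\mu_\infty$ is *algebraic*, not exponential:
  $\mu - \mu_\infty \approx (\mu_0-\mu_\infty)(\lambda\dot\gamma)^{\,n-1}$,
  which with $n = 0.568$ still leaves a gap of $8.0\times10^{-5}$ Pa s at
  $\dot\gamma = 10^6\,\mathrm{s^{-1}}$. Tests therefore pin the tail to
  frozen high-precision evaluations rather than to a nominal "machine zero"
  at large shear.

Shear-thickening parameterizations ($n > 1$) are rejected unless explicitly
enabled; Casson and Carreau–Yasuda laws are out of scope.

## Pulsatile tube-flow solver

The solver integrates

$$\rho\,\frac{\partial u}{\partial t} = -\frac{\partial p}{\partial x}
 + \frac{1}{r}\frac{\partial}{\partial r}\!\left(r\,
   \mu\!\left(\left|\tfrac{\partial u}{\partial r}\right|\right)
   \frac{\partial u}{\partial r}\right),\qquad u(R,t) = 0,$$

the axisymmetric, fully developed reduction of the Navier–Stokes momentum
equation with zero body force. The strain-rate magnitude reduces to
$|\partial u/\partial r|$, the only nonzero component in this geometry.

**Discretization.** Finite volumes on a stretched node set: cell faces at
midpoints, face conductances $r_f\,\mu_f/h$, so the scheme is exact for
quadratic profiles on arbitrary spacing — steady Poiseuille flow is
reproduced to round-off, which the tests exploit. Time stepping is implicit
backward Euler with Picard lagging of the viscosity: unconditionally stable
at the default $\Delta t = 10^{-3}$ s, with the per-step Picard loop capped
at 30 iterations and a relative residual target of $10^{-5}$ (matching the
solver settings a practitioner would use in a finite-volume code). A
Newtonian parameter set short-circuits the Picard loop (the problem is
linear). Failure to reach the residual sets `converged = FALSE` with a
warning rather than aborting; NaNs abort.

**Grid.** `radial_grid()` lays down a near-wall inflation stack — first
off-wall gap 0.1 mm, 5 layers, growth ratio 1.2 by default, the usual
boundary-layer prism recipe for arterial CFD — and fills the core with
geometrically graded intervals matched onto the innermost inflation gap.
Wall shear is evaluated with a second-order one-sided difference on the
last three (stretched) nodes; boundary-layer resolution is the entire point
of the inflation stack. `tau_wall` is reported as a magnitude, with a
signed variant retaining the direction of $\partial u/\partial r$.

**Driving modes.** `solve_pressure_driven()` imposes a periodic pressure
gradient; `solve_flow_driven()` imposes a periodic flow rate — the usual
situation when a measured inlet flow is the boundary condition — finding
the matching gradient at every step. For a fixed viscosity field the
discrete flow rate is affine in the gradient, so each Picard iteration
solves for the exact matching gradient from two tridiagonal solves; no
damped secant iteration is needed.

**Initialization.** Spin-up from rest in a 1.8 cm tube has a viscous time
constant $\rho R^2/(\lambda_1^2\mu) \sim 5$ s, far longer than the standard
three-cycle protocol, and would contaminate any cycle-periodicity check.
The default initial state is therefore the steady solution for the
cycle-mean driving (computed by a direct steady solve), which removes the
slow bulk transient; `u_init = "rest"` and explicit numeric profiles are
available, and the validation tests start the oscillatory Newtonian case
from the analytic periodic profile so that the measured error is purely
discretization. With these choices the cycle-3 vs cycle-2 velocity change
is below $10^{-3}$ of peak velocity, consistent with the common observation
that such simulations become asymptotic after the second cycle. Three
cycles at $\Delta t = 10^{-3}$ s over a 1 s period (3000 steps) is the
package's reference protocol; time-step robustness was checked at 0.005 and
0.0005 s (wall-shear waveforms agree within 1 % $L_2$).

**Verification oracles.** Three independent routes, all in the test suite:
steady Poiseuille closed forms ($\tau_w = GR/2$, $Q = \pi G R^4/8\mu$); the
analytic Womersley solution for oscillatory Newtonian flow, implemented
with complex Bessel series and cross-checked in the tests against a
quadrature evaluation of the integral representation of $J_0$ and against
frozen 40-digit values; and, for the Carreau steady case, the exact first
integral $\mu(|u'|)\,u' = -G r/2$ solved pointwise by root finding and
integrated inward — a semi-analytic boundary-value oracle sharing no code
with the solver. At aortic scale ($R = 17.94$ mm, 1 Hz) the Womersley
number is $\alpha \approx 23.1$ and the mean-flow Reynolds number at
$\mu = 0.004$ Pa s is $\approx 1331$, comfortably laminar; 0.004 Pa s is
the conventional constant-viscosity value for such regime checks and is
used only in the dimensionless utilities' documented examples, never in the
Carreau solve itself.

## Endothelial wall indices

Per surface-mesh cell, from a WSS vector series $\vec\tau(t)$ over one
cardiac cycle $T$:

$$\mathrm{TAWSS} = \frac1T\int_0^T\!\lVert\vec\tau\rVert\,dt,\qquad
\mathrm{OSI} = \frac12\left(1-
  \frac{\lVert\int_0^T\vec\tau\,dt\rVert}{\int_0^T\lVert\vec\tau\rVert\,dt}
  \right),$$
$$\mathrm{RRT} = \frac{1}{(1-2\,\mathrm{OSI})\,\mathrm{TAWSS}},\qquad
\mathrm{ECAP} = \frac{\mathrm{OSI}}{\mathrm{TAWSS}}.$$

TAWSS averages the *magnitude* — the standard definition, and the only one
under which OSI is bounded by $1/2$ and the familiar pairing of high TAWSS
with low OSI holds; OSI is normalized so that $0$ marks unidirectional
shear and $0.5$ a zero-mean oscillation. Quadrature is trapezoidal with a
periodic wrap segment (last sample back to the first), second-order on
periodic data and matching the per-cycle semantics. RRT and ECAP are
genuinely singular at $\mathrm{OSI}=0.5$ or $\mathrm{TAWSS}=0$; singular
cells carry a `+Inf` sentinel and are counted in the report, never NaN. In
VTK output the sentinel is a large finite value (1e30) plus a boolean mask
array, because XML readers handle literal infinities inconsistently.

Indices are cell-based (area weighting is then natural); whether a given
post-processing chain is node- or cell-based is rarely stated in the
literature, and cell-based is the default here. Vertex/cell indices are
1-based inside R and converted to VTK's 0-based convention on disk. All
stress I/O is in Pa; pressure I/O in mmHg with the fixed conversion
133.322 Pa/mmHg. `tangential_project()` removes any spurious normal
component an exporter may have left; solver-generated fields are already
tangential so projection is off by default. `threshold_area()` uses strict
inequalities; the shipped defaults are 5 Pa (a demonstration high-shear
threshold) and 0.4 Pa (the low-TAWSS proatherogenic threshold; for
diseased vessels 0.2–0.3 Pa is often quoted instead).

## Pressure waveform morphology

`extract_features()` locates the landmarks of the central aortic pulse:
systolic peak (global maximum), diastolic minimum, dicrotic notch,
end-diastolic pressure (value at cycle end), pulse pressure, trapezoidal
mean pressure, and steepest pre-peak upstroke slope. The notch — the
incisura marking aortic valve closure — is found as the most prominent
local minimum inside a post-peak window of $0.4\,T$ by default; prominence
ranking is robust on two-hump central waveforms and needs no derivative
heuristics. Constant waveforms yield absent-notch features with a warning.

Comparison metrics resample both waveforms onto a common uniform 1000-point
grid by linear interpolation (deterministic and adequate at mmHg scale):
`waveform_difference()` reports mean and max absolute difference (the
mesh-to-mesh metric), `percent_error()` the mean absolute percent error
against a strictly positive reference (the clinical-validation metric) —
the two are distinct conventions and reports state which is used —
and `delta_p()` the pointwise location-to-location pressure drop.

## Mesh-independence analysis

Given per-resolution peak velocity and peak WSS, the consecutive-mesh
percentage difference pairs each row with its next-coarser neighbour and
normalizes by the **larger** of the two values, rounding half away from
zero to an integer percent. This convention was locked by regression: it is
the unique simple rule consistent with all sixteen percentage cells of the
packaged reference tables (`inst/extdata/mesh_study_*.csv`, which also
retain a visibly repeated V\_max value in the polyhedral family exactly as
printed in the source table). Selection scans coarsest-to-finest and
accepts the first row whose rounded difference does not exceed the
threshold (3 % by default) — the least-time-consuming mesh that has stopped
moving the parameter — and reproduces the four reference selections
(0.4/0.6 mm tetrahedral, 0.6/0.2 mm polyhedral for V\_max/WSS\_max). Joint
selection over several parameters takes the finest per-parameter choice.
Runtimes are carried as metadata only; they are hardware-dependent and
never computed or asserted. Richardson extrapolation and formal grid
convergence indices are out of scope.

## Synthetic data and what passing tests show

The generators stand in for patient geometry and CFD exports that are not
publicly available, and every artifact ships its planted ground truth in
machine-readable form:

* **Pressure waveforms** exhibit the seven classical components (upstroke,
  incident rise, systolic peak, late-systolic decline, dicrotic notch,
  diastolic runoff, end-diastolic pressure), built from Gaussian bumps plus
  a smooth runoff and affinely mapped so the sampled extrema equal SBP/DBP
  exactly (defaults 120/80 mmHg, textbook healthy central values; period
  1 s, i.e. 3000 solver steps of 1 ms across three cycles). Seed-dependent
  jitter varies widths and amplitudes without moving the planted landmarks;
  landmark recovery is exact at sample resolution, by construction.
* **Flow waveforms** are single-hump systolic pulses peaking at
  $t = 0.15$ s with optional diastolic backflow, rescaled to a cycle mean
  of 0.14 m/s exactly; at the 35.88 mm reference diameter this reproduces
  the laminar mean-flow Reynolds number $\approx 1331$.
* **Tube meshes** are structured cylinder triangulations with mean edge
  length within 10 % of the requested element size (family default
  0.2–1.0 mm) and area within 2 % of the analytic lateral area. They
  emulate *resolution* families only; tetrahedral-vs-polyhedral volume
  meshing cannot be emulated without a volumetric mesher, so mesh-family
  labels are free text.
* **WSS series** (analytic mode) use per-cell square waves along the local
  tangent: the duty cycle $f$ fixes OSI $=(1-|2f-1|)/2$ and the magnitude
  fixes TAWSS in closed form. Sign transitions are placed halfway between
  samples and duty cycles snapped to the sample grid, making the periodic
  trapezoid quadrature exact — the planted values are recovered to
  round-off at the default 200 samples/cycle, and the snapped values are
  what the truth records. Smooth temporal bases would have required
  quadrature-tolerance oracles instead. Solver mode lays the computed wall
  shear magnitude along the tube axis with a smooth modulation (planted
  OSI = 0, unidirectional shear).
* **Mesh-study tables** follow a planted power law
  $v(h) = v_\infty + C h^p$ with seeded noise and $h^{-3}$ element counts.

Passing these tests demonstrates that the *operators* are correct on fields
whose ground truth is known exactly. It does not demonstrate fidelity to
real aortic flow: the synthetic tube has no arch curvature, no branch
ostia, no secondary flows, and its WSS oscillation is imposed rather than
emergent. Those are properties of the upstream 3D simulation, out of scope
here.

## Determinism and I/O

Every generator is a pure function of its configuration including the seed
(a local RNG stream is used; the global RNG state is untouched). Pipeline
reports embed the seed and an MD5 hash of the configuration and contain no
timestamps, so re-running with the same config is byte-identical. Waveforms
and tables travel as CSV with units in headers; surfaces and per-cell
fields as ASCII VTK-XML PolyData (written and read with `xml2`);
time-resolved flow solutions as a plain-text directory container (CSV
matrices plus JSON metadata) — human-readable, diff-able, and free of
binary-format dependencies. Floating-point values are printed with `%.17g`
so files round-trip bit-exactly; manifest time stamps are stored as
strings because generic JSON numeric printing is not ulp-exact.

## Problem sizes

The reference verification cases use 60 core intervals plus the 5-layer
inflation stack (66 nodes), $\Delta t = 10^{-3}$ s, three 1 s cycles; index
recovery uses a few-thousand-cell tube at 200 samples/cycle; the end-to-end
pipeline runs a flow-driven Carreau solve on a 46-node grid. These sizes
were chosen as the smallest at which the verification tolerances (1 %
Womersley $L_2$, 0.5 % Carreau-BVP, 0.5 % index recovery) are met with an
order-of-magnitude margin.

## Known limitations

Rigid wall (no fluid–structure interaction), no turbulence model, no
curved-tube secondary flows, no volumetric meshing, single-constituent
Carreau rheology without temperature or body-force effects. The
axisymmetric solver verifies the physics implementation; it is not a
substitute for patient-specific 3D simulation.
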