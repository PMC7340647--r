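---
title: "Methods: lattice Boltzmann simulation and analysis of the FDA nozzle benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice Boltzmann simulation and analysis of the FDA nozzle benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nozzlelbm)
```

## The problem

The FDA benchmark nozzle is a cylindrical pipe (diameter 12 mm) with a
conical contraction into a narrow throat (diameter 4 mm, length 40 mm)
followed by a sudden expansion back to the pipe diameter.  Driven at throat
Reynolds numbers between 500 and 6500 with a blood-analog fluid
(density 1056 kg/m^3, dynamic viscosity 3.5 mPa s), it covers laminar,
transitional and turbulent regimes in a geometry representative of medical
devices, and PIV measurements from three laboratories (five datasets) are
available for validation.  `nozzlelbm` implements, at desk scale, the full
simulate-characterize-compare chain for this configuration: a D3Q19
multiple-relaxation-time (MRT) lattice Boltzmann solver with curved-wall
boundaries, turbulence statistics with Kolmogorov-scale resolution
assessment, and quantitative comparison against PIV-style reference
profiles.

## Unit scaling

The solver works in lattice units.  A case is prescribed by the fluid, the
throat Reynolds number Re = u_th d / nu, the grid spacing dx and the
principal relaxation rate Omega in (0, 2).  Under diffusive scaling:

* nu_lattice = c_s^2 (1/Omega - 1/2), with c_s^2 = 1/3 for D3Q19;
* dt = nu_lattice dx^2 / nu, so halving dx quarters dt;
* u_lattice = u dt / dx, which must stay below 0.15 (the low-Mach validity
  bound; `build_case()` refuses configurations beyond it).

`build_case()` cross-checks that the Reynolds number recomputed from pure
lattice quantities (lattice velocity, cell count across the throat,
lattice viscosity) equals the physical one to 1e-10 relative.  Two
conventions are worth recording:

* **Flow-through time.**  T_ft = L/u uses the throat length (0.04 m) with
  the *inlet-section* mean velocity (throat mean / area ratio 9).  This
  convention reproduces both published development times for the benchmark
  (about 0.21 s at Re 2000 and 0.12 s at Re 3500); with the throat mean
  velocity it would not.
* **The tabulated time steps.**  The published 16/4/1 microsecond triple at
  80/40/20 micrometers is internally consistent with Omega = 1.90528, while
  the stated rate is 1.90 (which gives 16.9 microseconds at 80 micrometers).
  The package treats Omega as the free input and never rounds dt; worked
  examples use the self-consistent value.

## Geometry

The primary geometry path is analytic: the benchmark constants (12/4 mm
diameters, 40 mm throat, conical contraction with a 10 degree half-angle)
define a piecewise radius profile r(z) with z = 0 at the sudden expansion,
right-continuous at the jump.  The published drawing does not list the
contraction angle; the value comes from the public benchmark definition.
An STL reader (`read_stl()`, `voxelize_stl()`) provides a parity path for
triangulated surfaces.

Voxelization classifies cell centers strictly inside r(z) as fluid on a
grid whose transverse cell count is even with the axis on a cell corner,
so the number of fluid cells across the throat equals round(d/dx) — 50,
100 and 200 at the three published resolutions.  Sub-cell wall distances
q in (0, 1] for the Bouzidi boundary condition are found by bisection on
the inside/outside indicator along each cut link (60 iterations, i.e.
resolved far below 1e-9 of a cell); bisection on the indicator rather
than on a signed distance is robust at the discontinuous expansion plane.

## Solver

One time step is collision, then streaming with fused boundary handling,
then the outlet density treatment.

**Collision.**  The MRT operator is applied as the dense matrix
C = M^-1 S M acting on the non-equilibrium part, with M the standard
d'Humieres-type D3Q19 moment basis (generated from the moment polynomials,
not a hard-coded table) and S the diagonal rate matrix.  Equilibrium
moments are M f_eq with the quadratic equilibrium, so setting every rate
equal to Omega reproduces BGK *identically* — kept as a permanent oracle
test.  The five symmetric-traceless second-order moments carry Omega
(setting the viscosity); the non-hydrodynamic moments use the documented
defaults s_e = 1.19, s_eps = 1.4, s_q = 1.2, s_pi = 1.4, s_m = 1.98
(configurable through `mrt_rates()`).  Published LBM studies of this benchmark report MRT and
Omega but not the basis or auxiliary rates; these choices are the
package's own.  The 19x19-by-n contraction runs as one BLAS `dgemm`.

**Walls.**  Linear-interpolation Bouzidi bounce-back, chosen over the
quadratic variant for robustness as q approaches 0 and for its exact
algebraic reduction to half-way bounce-back at q = 1/2 (tested against an
independent reference implementation).  Where the second interpolation
node is not a fluid cell the scheme falls back to half-way bounce-back.

**Inflow.**  A parabolic profile u(r) = 2 u_in (1 - (r/R)^2) is imposed by
half-way velocity bounce-back, with the target evaluated at the cut-link
positions on the inlet plane.  For rest-state starts the target is ramped
linearly over a configurable window (default one flow-through time) to
avoid the initial pressure shock; reported setups do not state
ramping.

**Outflow.**  Unknown populations at the outlet are taken from the
interior neighbor (first-order extrapolation), and the outlet layer is
held at zero gauge pressure.  Two variants exist: a momentum-preserving
density shift (default), and an `"equilibrium"` variant that rebuilds the
outlet layer at the reference density and local velocity.  The second is
more dissipative and is used for the desk-scale nozzle runs, where the
truncated domain pushes the still-coherent jet through the outlet; with
the plain shift the jet-outlet interaction grows pressure oscillations
until the Mach guard trips, which mirrors the known sensitivity of
truncated outflows in this flow.

**Guards.**  The loop aborts with a classed `divergence` error carrying
the step index when any lattice speed reaches 0.15 or a density leaves
(0, inf) — the same failure mode reported for the under-resolved
benchmark run at Re 3500.

## Desk-scale study conditions

The production benchmark runs (45M-2.88G cells, 10 physical seconds) are
cluster-scale.  The package's own study conditions, fixed in
`nozzle_config()`:

* Re_th = 500 (laminar regime), 12 cells across the throat
  (dx = 1/3 mm), Omega = 1.985 so that the throat lattice velocity is
  0.052, well under the Mach bound;
* truncated domain z in [-0.072, 0.024] m — one inlet diameter of pipe
  before the contraction, the full contraction and throat, and six throat
  diameters of expansion; the full extents remain the default for
  fidelity runs;
* 12 000 steps (about 0.5 s physical), probes on the centerline every 5
  steps, mean fields over the final 80 percent;
* initialization from a mass-conserving quasi-1D laminar ansatz (local
  parabolic profile scaled by the area ratio, jet-preserving downstream
  of the expansion) rather than from rest.  At this Reynolds number the
  rest start needs several flow-through times (tens of thousands of
  steps) just to advect the front through the domain; the ansatz removes
  that transient without changing the converged state, which we verified
  by the decay of the step-to-step residual to 1e-3 of the throat
  velocity.

Two observations about these conditions belong here because they bound
what the automated checks can show:

* The throat-to-inlet mean-velocity ratio converges to 9.0 (continuity
  across the area ratio) and the section pressure falls monotonically
  through the contraction.
* The throat centerline-to-mean ratio converges to about 1.77, not the
  fully developed value 2.  This is real physics, not solver error: the
  laminar entry length at Re 500 is roughly 0.05 Re d = 0.1 m, more than
  twice the 0.04 m throat, and the profile entering the throat has been
  flattened by the contraction.  The value 1.77 agrees with developing
  pipe-flow correlations at the throat's nondimensional length
  L/(d Re) = 0.02.  A fully parabolic throat profile is therefore not
  attainable in this geometry at Re 500 at any resolution or run length;
  the corresponding acceptance check is expected to fail and is retained
  unweakened.

## Flow characterization

Reynolds decomposition (arithmetic time mean over the analysis window),
TKE k = (u'_x^2 + u'_y^2 + u'_z^2)/2, and Welch spectra on a Strouhal
axis St = f d / u_th.  Published analyses do not state their Welch
parameters; defaults are a Hann window, 8 segments, 50 percent overlap, all
recorded in the `spectrum_result`.  One-sided density scaling makes the
PSD integral match the variance (Parseval, tested at 2 percent on 4e5
samples, the published sample count).

The Kolmogorov microscales use the nondimensional fluctuating strain
invariant S = 2 s'_ij s'_ij (second-order central differences, one-sided
at walls), averaged over centerline cells between stations z8 and z12 and
over time:

* eta = (Re^2 S)^(-1/4), tau_eta = S^(-1/2), u_eta = (S/Re^2)^(1/4),

so eta u_eta Re = 1 and tau_eta = eta/u_eta hold identically.
Dimensional forms follow eta_m = eta d, tau_s = tau_eta d/u_th,
u_m_s = u_eta u_th.  The published table's dimensional scale entries are
not mutually consistent with tau = eta^2/nu (by factors of 2-10) while
its l+ = dx/eta and t+ = dt/tau columns are exactly consistent; the
package therefore documents its own dimensionalization and verifies the
l+/t+ arithmetic, which is what the resolution-quality assessment needs.

**Jet breakdown** is published as a visual/spectral observation; to make
it testable the package defines an operational detector: the first axial
position where centerline TKE exceeds a configurable fraction (default
10 percent) of its downstream maximum, reported with the bracketing
stations, and "none" when the maximum TKE stays below a laminar floor
(default 1e-4 u_th^2, i.e. fluctuation RMS about 1 percent of the throat
velocity).  The detector is monotone in the threshold by construction.

## Comparison apparatus

Centerline profiles (default 86 axial samples), radial profiles at the 12
stations of the benchmark figure, section-mean pressures normalized by
the throat dynamic pressure (anchored at a reference station, invariant
to pressure offsets), mean-normalized shear profiles, and the simple
relative percentage error delta = |(U_ref - U_h)/U_ref| x 100.  PIV-style
references use a documented CSV dialect (`# key: value` header,
`quantity,z_m,r_m,value` rows); datasets without pressure (as one of the
published experiments) parse with the pressure block absent.  The
synthetic generator emulates inter-laboratory spread as a multiplicative
lab offset (sd 5 percent) plus pointwise Gaussian noise (sd 3 percent of
the signal RMS) — the published spread is documented only qualitatively;
these defaults were fixed once to resemble the published scatter and are
configurable.  What the generator does not emulate: PIV measurement
physics (interrogation windows, peak locking), correlated noise, or
systematic near-wall bias; closure tests against it therefore validate
the estimators and plumbing, not instrument models.

## Numerical choices and degenerate inputs

* Double precision throughout; no reassociation in kernels feeding the
  conservation tests (collision conserves mass and momentum to round-off
  because the relaxed non-equilibrium has exactly zero conserved
  moments).
* Voxelization requires at least 4 cells across the throat; fewer is an
  `under_resolved` error.
* Zero-velocity, zero-strain and zero-reference inputs raise classed
  errors (`undefined_scales`, `zero_mean`, `undefined_error`) rather than
  returning silent zeros.
* Determinism: the solver has no stochastic element; identical
  configurations give bit-identical probe series, and manifests carry
  md5 checksums to verify it.

## Problem sizes used by the test suite

Solver verification runs a Hagen-Poiseuille pipe at 10/14/20 cells per
diameter (three diameters long, initialized at the analytic solution and
relaxed for ~1.2 R^2/nu steps), giving an L2 velocity error of about
0.9 percent at 20 cells/diameter and a fitted convergence order of about
2.0 under diffusive scaling.  The scaled-down nozzle acceptance run uses
the `nozzle_config()` conditions above.  Spectral closures use 1e5-1e6
sample synthetic series.  These sizes were chosen once as the smallest
that cleanly separate the tested effect from discretization noise.

## Known limitations

* Transitional and turbulent regimes (Re 2000/3500), the jet-breakdown
  station brackets and the published discrepancy percentages require the
  cluster-scale resolutions and are documented qualitative targets only.
* The linear Bouzidi scheme and first-order outflow extrapolation are
  second- and first-order accurate respectively; the observed global
  order on the pipe is ~2 but wall-adjacent stresses are noisier.
* No turbulence model, no non-Newtonian rheology, no grid refinement,
  single-threaded kernels.
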