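# nozzlelbm

A desk-scale direct numerical simulation pipeline for transitional flow in
the FDA sudden-expansion nozzle benchmark, written as an R package with
compiled (Rcpp) solver kernels.

The benchmark device — a 12 mm pipe contracting into a 4 mm, 40 mm-long
throat that expands suddenly back to the pipe diameter — is the standard
validation case for CFD of medical-device hemodynamics.  `nozzlelbm`
provides the full chain used to study it with the lattice Boltzmann
method:

* **Scaling** — diffusive-scaling translation between physical and lattice
  units: `nu_lattice = c_s^2 (1/Omega - 1/2)`,
  `dt = nu_lattice dx^2 / nu`, `u_lattice = u dt / dx` with the
  low-Mach bound `u_lattice < 0.15` enforced (`build_case()`).
* **Geometry** — analytic parametric nozzle with voxelization, sub-cell
  Bouzidi wall distances computed against the exact surface, the 12
  measurement stations, and an optional STL path
  (`fda_nozzle()`, `voxelize()`, `wall_link_distances()`).
* **Solver** — D3Q19 multiple-relaxation-time lattice Boltzmann with
  Bouzidi curved walls, parabolic velocity inflow and extrapolation
  outflow at zero gauge pressure (`build_domain()`, `lbm_run()`); the
  equal-rate reduction to BGK is exact and kept as a test oracle.
* **Characterization** — Reynolds decomposition, turbulent kinetic energy
  `k = (u'_x^2 + u'_y^2 + u'_z^2)/2`, Welch spectra on a Strouhal axis
  `St = f d / u`, fluctuating-strain Kolmogorov microscales
  `eta = (Re^2 S)^(-1/4)`, `tau_eta = S^(-1/2)`, `u_eta = (S/Re^2)^(1/4)`
  and the resolution-quality ratios `l+ = dx/eta`, `t+ = dt/tau_eta`.
* **Comparison** — centerline/radial profiles, normalized pressure
  `(p_z - p_z0) / (rho u_th^2 / 2)`, mean-normalized shear, relative
  percentage errors, a jet-breakdown detector, and a documented CSV
  dialect for PIV-style reference data.
* **Synthetic data** — analytic Poiseuille profiles, multi-laboratory
  PIV-like datasets with reproducible noise, band-limited signals with
  prescribed spectral slope, and strain fields with prescribed invariant.
* **Pipeline** — `nozzle_mesh()` / `nozzle_run()` / `nozzle_characterize()`
  / `nozzle_compare()` stages with JSON manifests, VTK and CSV outputs,
  plus a thin CLI at `inst/scripts/nozzlepipe.R`.

## Worked example

Translate a case into lattice units:

```r
library(nozzlelbm)
case <- build_case(fluid_spec(), re_throat = 500, dx = 0.004 / 12, omega = 1.985)
case
#> <flow_case> Re_th = 500 (d = 0.004 m)
#>   u_throat = 0.4143 m/s, u_inlet = 0.046033 m/s, T_ft = 0.8689 s
#>   dx = 0.000333333 m (12 cells across throat), dt = 4.2221e-05 s, Omega = 1.985
#>   nu_lattice = 0.00125945, u_lattice = 0.05248 (Mach guard 0.15)
```

A configuration whose lattice velocity lands beyond the low-Mach bound is
refused before any stepping:

```r
build_case(fluid_spec(), re_throat = 2000, dx = 80e-6, omega = 1.9053)
#> Error: lattice velocity 0.3315 (from u = 1.657 m/s) exceeds the Mach limit 0.15
```

Run the desk-scale laminar nozzle case end to end:

```r
dir <- "nozzle-out"
nozzle_mesh(nozzle_config(), dir)   # mesh: 148704 fluid cells, 12 across throat
nozzle_run(dir)                     # 12000 steps (~0.51 s physical)
ch <- nozzle_characterize(dir, window_fraction = 0.25)
ch$breakdown
#> <jet_breakdown> none (laminar)
```

From the mean fields, the throat-to-inlet mean-velocity ratio is 8.99
(continuity across the 9:1 area ratio) and the section pressure falls
monotonically through the contraction; the throat centerline-to-mean
ratio is 1.77, the developing-flow value at Re 500 (the laminar entry
length exceeds the throat length, so the parabolic value 2 is not
reachable in this geometry — see the methods vignette).

Resolution-quality arithmetic for the published resolution ladder:

```r
resolution_quality(dx = 80e-6, dt = 16e-6, eta = 4.94e-6, tau_eta = 8.37e-6)
#> $l_plus  16.19
#> $t_plus  1.91
```

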