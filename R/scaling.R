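## Diffusive scaling between physical and lattice units.
##
## The solver works in lattice units (dx = dt = 1, reference density 1).  A
## physical case (fluid, throat Reynolds number, grid spacing, relaxation
## rate) is translated into lattice units such that the Reynolds number is
## preserved exactly and the time step follows dt = nu_lattice * dx^2 / nu.

#' Fluid specification
#'
#' Bundle the physical properties of the working fluid.  The default values
#' are those of the blood-analog fluid used throughout the FDA nozzle
#' benchmark: density 1056 kg/m^3 and dynamic viscosity 0.0035 Pa s.
#'
#' @param density_kg_m3 fluid density in kg/m^3 (> 0).
#' @param dynamic_viscosity_Pa_s dynamic viscosity in Pa s (> 0).
#' @return An object of class `fluid_spec` with fields `rho`, `mu` and the
#'   derived kinematic viscosity `nu = mu / rho` (m^2/s).
#' @examples
#' f <- fluid_spec()
#' f$nu          # 3.314e-6 m^2/s
#' @export
fluid_spec <- function(density_kg_m3 = 1056, dynamic_viscosity_Pa_s = 0.0035) {
  if (!is.numeric(density_kg_m3) || density_kg_m3 <= 0)
    nz_error("invalid_parameter", "density must be > 0")
  if (!is.numeric(dynamic_viscosity_Pa_s) || dynamic_viscosity_Pa_s <= 0)
    nz_error("invalid_parameter", "dynamic viscosity must be > 0")
  structure(list(
    rho = density_kg_m3,
    mu  = dynamic_viscosity_Pa_s,
    nu  = dynamic_viscosity_Pa_s / density_kg_m3
  ), class = "fluid_spec")
}

#' @export
print.fluid_spec <- function(x, ...) {
  cat(sprintf("<fluid_spec> rho = %g kg/m^3, mu = %g Pa s, nu = %g m^2/s\n",
              x$rho, x$mu, x$nu))
  invisible(x)
}

#' Reynolds number
#'
#' Re = u * d / nu, based on a characteristic length `d` (the nozzle throat
#' diameter in this benchmark).  Works identically for physical quantities
#' (m/s, m, m^2/s) and lattice quantities (lattice velocity, cell count,
#' lattice viscosity): consistency of the two routes is the prescription
#' check for a lattice setup.
#'
#' @param u_mean mean velocity (>= 0).
#' @param d characteristic length (> 0).
#' @param nu kinematic viscosity (> 0).
#' @return dimensionless Reynolds number.
#' @export
compute_reynolds <- function(u_mean, d, nu) {
  if (!is.numeric(d) || any(d <= 0)) nz_error("invalid_parameter", "d must be > 0")
  if (!is.numeric(nu) || any(nu <= 0)) nz_error("invalid_parameter", "nu must be > 0")
  if (any(u_mean < 0)) nz_error("invalid_parameter", "u_mean must be >= 0")
  u_mean * d / nu
}

#' Lattice viscosity from the relaxation rate
#'
#' nu_lattice = c_s^2 (1/Omega - 1/2) with c_s^2 = 1/3 for the D3Q19 stencil.
#' Omega must lie in the open stability interval (0, 2); the viscosity is
#' strictly decreasing in Omega and tends to 0 as Omega approaches 2.
#'
#' @param omega principal relaxation rate, 0 < Omega < 2.
#' @return lattice viscosity (dimensionless, > 0).
#' @export
lattice_viscosity <- function(omega) {
  if (!is.numeric(omega) || any(omega <= 0) || any(omega >= 2))
    nz_error("stability_domain", "relaxation rate must satisfy 0 < Omega < 2")
  (1 / 3) * (1 / omega - 1 / 2)
}

#' Time step under diffusive scaling
#'
#' dt = nu_lattice(Omega) * dx^2 / nu.  Halving dx quarters dt.
#'
#' @param dx grid spacing in m (> 0).
#' @param omega relaxation rate in (0, 2).
#' @param nu physical kinematic viscosity in m^2/s.
#' @return time step in seconds.
#' @export
timestep_from_dx <- function(dx, omega, nu) {
  if (any(dx <= 0)) nz_error("invalid_parameter", "dx must be > 0")
  if (any(nu <= 0)) nz_error("invalid_parameter", "nu must be > 0")
  lattice_viscosity(omega) * dx^2 / nu
}

#' Lattice velocity and the Mach guard
#'
#' u_lattice = u * dt / dx.  Lattice velocities at or above `mach_limit`
#' (default 0.15) violate the low-Mach assumption of the method; by default
#' an error of class `mach_violation` naming the offending velocity is
#' raised so that a simulation cannot be started outside its validity
#' domain.  Set `enforce = FALSE` to obtain the value with a warning
#' instead.
#'
#' @param u_mean physical velocity (m/s).
#' @param dt time step (s, > 0).
#' @param dx grid spacing (m, > 0).
#' @param mach_limit maximum admissible lattice velocity (default 0.15).
#' @param enforce raise an error on violation (default TRUE).
#' @return lattice velocity (dimensionless).
#' @export
lattice_velocity <- function(u_mean, dt, dx, mach_limit = 0.15, enforce = TRUE) {
  if (any(dt <= 0) || any(dx <= 0))
    nz_error("invalid_parameter", "dt and dx must be > 0")
  ul <- u_mean * dt / dx
  if (any(abs(ul) >= mach_limit)) {
    bad <- u_mean[which.max(abs(ul))]
    msg <- sprintf(
      "lattice velocity %.4g (from u = %.4g m/s) exceeds the Mach limit %.3g",
      max(abs(ul)), bad, mach_limit)
    if (enforce) nz_error("mach_violation", msg, u_lattice = max(abs(ul)))
    warning(msg)
  }
  ul
}

#' Flow-through time
#'
#' T_ft = L / u_ref: the residence time of a fluid parcel used to size
#' development and averaging windows.  For the benchmark cases the package
#' follows the convention L = throat length (0.04 m) with the
#' inlet-section mean velocity (throat mean / area ratio 9) as reference,
#' which reproduces the reported 0.21 s (Re 2000) and 0.12 s (Re 3500).
#'
#' @param L characteristic length (m, > 0).
#' @param u_ref reference velocity (m/s, > 0).
#' @return time in seconds.
#' @export
flow_through_time <- function(L, u_ref) {
  if (any(L <= 0) || any(u_ref <= 0))
    nz_error("invalid_parameter", "L and u_ref must be > 0")
  L / u_ref
}

#' Build a flow case in physical and lattice units
#'
#' Translates (fluid, throat Reynolds number, grid spacing, relaxation rate)
#' into a fully populated physical flow case and its lattice-unit scaling,
#' and cross-checks that the Reynolds number computed from lattice
#' quantities equals the physical one.
#'
#' @param fluid a [fluid_spec()].
#' @param re_throat throat Reynolds number (> 0).
#' @param dx grid spacing in m; must resolve the throat with >= 4 cells.
#' @param omega principal relaxation rate in (0, 2).
#' @param geometry a [fda_nozzle()] geometry (supplies throat diameter,
#'   throat length and the inlet:throat area ratio).
#' @param mach_limit lattice-velocity bound (default 0.15).
#' @return An object of class `flow_case`: a list with components `flow`
#'   (Re, d, u_mean_throat, u_mean_inlet, L_th, T_ft), `lattice`
#'   (dx, dt, omega, nu_lattice, u_lattice, cs2, cells_throat) and `fluid`.
#' @export
build_case <- function(fluid, re_throat, dx, omega,
                       geometry = fda_nozzle(), mach_limit = 0.15) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (re_throat <= 0) nz_error("invalid_parameter", "re_throat must be > 0")
  d <- 2 * geometry$throat_radius
  n_th <- round(d / dx)
  if (n_th < 4)
    nz_error("under_resolved",
             sprintf("dx = %g m yields %d cells across the %g m throat (need >= 4)",
                     dx, n_th, d))
  area_ratio <- (geometry$inlet_radius / geometry$throat_radius)^2
  u_th <- re_throat * fluid$nu / d
  u_in <- u_th / area_ratio
  dt <- timestep_from_dx(dx, omega, fluid$nu)
  u_lat <- lattice_velocity(u_th, dt, dx, mach_limit = mach_limit)
  nu_lat <- lattice_viscosity(omega)
  ## prescription check: Re from lattice quantities must equal physical Re
  re_lat <- compute_reynolds(u_lat, d / dx, nu_lat)
  if (abs(re_lat - re_throat) > 1e-10 * re_throat)
    nz_error("prescription_inconsistent",
             sprintf("lattice Re %.12g != physical Re %.12g", re_lat, re_throat))
  structure(list(
    fluid = fluid,
    flow = list(
      re_throat = re_throat, d = d,
      u_mean_throat = u_th, u_mean_inlet = u_in,
      area_ratio = area_ratio,
      L_th = geometry$throat_length,
      T_ft = flow_through_time(geometry$throat_length, u_in),
      T_ft_reference = "inlet-section mean velocity (throat mean / area ratio)"
    ),
    lattice = list(
      dx = dx, dt = dt, omega = omega,
      nu_lattice = nu_lat, u_lattice = u_lat,
      u_lattice_inlet = u_in * dt / dx,
      cs2 = 1 / 3, cells_throat = n_th
    )
  ), class = "flow_case")
}

#' @export
print.flow_case <- function(x, ...) {
  f <- x$flow; l <- x$lattice
  cat(sprintf("<flow_case> Re_th = %g (d = %g m)\n", f$re_throat, f$d))
  cat(sprintf("  u_throat = %.5g m/s, u_inlet = %.5g m/s, T_ft = %.4g s\n",
              f$u_mean_throat, f$u_mean_inlet, f$T_ft))
  cat(sprintf("  dx = %g m (%d cells across throat), dt = %.5g s, Omega = %g\n",
              l$dx, l$cells_throat, l$dt, l$omega))
  cat(sprintf("  nu_lattice = %.6g, u_lattice = %.4g (Mach guard 0.15)\n",
              l$nu_lattice, l$u_lattice))
  invisible(x)
}

#' Recover physical quantities from a lattice scaling
#'
#' Inverse of the diffusive-scaling translation; used for round-trip
#' verification and for rescaling solver output to physical units.
#'
#' @param case a `flow_case`.
#' @return list with `nu` (m^2/s), `u_mean_throat` (m/s) and `d` (m)
#'   reconstructed from lattice quantities.
#' @export
physical_from_lattice <- function(case) {
  stopifnot(inherits(case, "flow_case"))
  l <- case$lattice
  list(
    nu = l$nu_lattice * l$dx^2 / l$dt,
    u_mean_throat = l$u_lattice * l$dx / l$dt,
    d = l$cells_throat * l$dx
  )
}
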