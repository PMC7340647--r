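## Canonical flows: straight circular pipe (Hagen-Poiseuille) used as the
## solver's verification workhorse and by the convergence study.

#' Straight circular pipe geometry
#'
#' A constant-radius pipe along z, voxelizable with the same machinery as
#' the nozzle ([voxelize()], [wall_link_distances()]).
#'
#' @param radius pipe radius (m).
#' @param length pipe length (m).
#' @param z_min axial start (default 0).
#' @return object of class `pipe_geometry`.
#' @export
pipe_geometry <- function(radius, length, z_min = 0) {
  stopifnot(radius > 0, length > 0)
  structure(list(
    throat_radius = radius, inlet_radius = radius,
    z_min = z_min, z_max = z_min + length
  ), class = "pipe_geometry")
}

#' Parabolic inflow profile closure
#'
#' Returns `function(x, y, z)` giving the axial Hagen-Poiseuille profile
#' u_z(r) = 2 u_mean (1 - (r/R)^2), clipped to zero outside the radius,
#' in the units of `u_mean` (the solver passes lattice units).
#'
#' @param u_mean mean (bulk) velocity.
#' @param radius profile radius R.
#' @param center transverse center `c(x0, y0)` (default origin).
#' @return closure suitable for `build_domain(inlet_velocity = ...)`.
#' @export
parabolic_inflow <- function(u_mean, radius, center = c(0, 0)) {
  force(u_mean); force(radius); force(center)
  function(x, y, z) {
    r2 <- (x - center[1])^2 + (y - center[2])^2
    uz <- 2 * u_mean * pmax(0, 1 - r2 / radius^2)
    cbind(0, 0, uz)
  }
}

#' Build a solver-ready Poiseuille pipe domain
#'
#' Voxelizes a straight pipe, computes Bouzidi wall distances against the
#' analytic cylinder, and attaches a parabolic inflow at the configured
#' lattice bulk velocity with a zero-gauge-pressure extrapolation outlet.
#'
#' @param cells_per_diameter target resolution (fluid cells across the
#'   diameter).
#' @param length_diameters pipe length in diameters (default 3).
#' @param u_mean_lattice bulk lattice velocity (default 0.03).
#' @param radius physical radius in m (default 0.002; only sets the unit
#'   of `dx`, the physics is fixed by the lattice numbers).
#' @return an `lbm_domain`; the inflow profile and parameters are attached
#'   as attributes `u_mean_lattice` and `radius_cells`.
#' @export
pipe_domain <- function(cells_per_diameter, length_diameters = 3,
                        u_mean_lattice = 0.03, radius = 0.002) {
  dx <- 2 * radius / cells_per_diameter
  geom <- pipe_geometry(radius, length_diameters * 2 * radius)
  field <- voxelize(geom, dx)
  field <- wall_link_distances(field)
  dom <- build_domain(field,
                      inlet_velocity = parabolic_inflow(u_mean_lattice, radius))
  attr(dom, "u_mean_lattice") <- u_mean_lattice
  attr(dom, "radius_cells") <- radius / dx
  dom
}

#' Analytic Poiseuille velocity at the domain's cell centers
#'
#' @param dom a pipe domain from [pipe_domain()].
#' @return per-fluid-cell axial velocity (lattice units).
#' @export
pipe_analytic_velocity <- function(dom) {
  u_mean <- attr(dom, "u_mean_lattice")
  R <- dom$geometry$throat_radius
  r2 <- dom$centers[, 1]^2 + dom$centers[, 2]^2
  2 * u_mean * pmax(0, 1 - r2 / R^2)
}

#' Quasi-one-dimensional laminar initial guess for a nozzle domain
#'
#' Mass-conserving Poiseuille ansatz: at each axial position the axial
#' velocity is the parabolic profile of the local radius with the bulk
#' velocity scaled by the local area ratio,
#' u_z(r, z) = 2 u_in (R_in / r(z))^2 (1 - (r / r(z))^2).
#' Initializing the desk-scale laminar runs from this guess (instead of
#' the rest state) removes most of the flush-through transient; it is an
#' initialization aid only and does not alter the converged state.
#'
#' @param dom an `lbm_domain` carrying a geometry.
#' @param u_inlet_lattice bulk inlet velocity in lattice units.
#' @return 3 x n velocity matrix (lattice units).
#' @export
nozzle_laminar_guess <- function(dom, u_inlet_lattice) {
  g <- dom$geometry
  if (is.null(g)) nz_error("invalid_parameter", "domain has no geometry")
  rz <- radius_at(g, pmin(pmax(dom$centers[, 3], g$z_min), g$z_max))
  r2 <- dom$centers[, 1]^2 + dom$centers[, 2]^2
  ub <- u_inlet_lattice * (g$inlet_radius / rz)^2
  uz <- 2 * ub * pmax(0, 1 - r2 / rz^2)
  rbind(0, 0, uz)
}

#' Inlet- and outlet-side mass flux of a run
#'
#' Plane-summed axial mass flux (rho u_z dx^2) on a cross-section near the
#' inlet and one near the outlet; their relative imbalance is the
#' open-system mass-balance diagnostic.  The planes sit `offset` cells
#' inside the domain: the cells immediately adjacent to the velocity and
#' extrapolation boundaries carry local closure errors that do not
#' represent transport through the interior.
#'
#' @param dom an `lbm_domain` with inlet and outlet.
#' @param m macroscopic fields: list with `rho` and `u` (from
#'   [macroscopic()]), or a 3 x n velocity matrix (rho taken as 1).
#' @param offset plane distance from the domain ends in cells (default 4).
#' @return list with `inlet`, `outlet` (lattice mass flux times dx^2) and
#'   `imbalance_fraction`.
#' @export
plane_flux <- function(dom, m, offset = 4L) {
  if (!is.list(m)) m <- list(rho = rep(1, ncol(m)), u = m)
  k <- (dom$fluid_idx - 1L) %/% (dom$dim[1] * dom$dim[2])
  kin <- min(k) + offset; kout <- max(k) - offset
  phi <- m$rho * m$u[3, ]
  qi <- sum(phi[k == kin])
  qo <- sum(phi[k == kout])
  list(inlet = qi * dom$dx^2, outlet = qo * dom$dx^2,
       imbalance_fraction = abs(qo - qi) / abs(qi))
}
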