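## D3Q19 stencil, equilibrium distribution and collision operators.
##
## Distributions are stored as a 19 x n_cells matrix (one column per cell)
## so that per-cell collision is a contiguous 19-vector operation.

#' The D3Q19 stencil
#'
#' Nineteen discrete velocities: the rest vector, 6 axis vectors (weight
#' 1/18) and 12 face diagonals (weight 1/36); rest weight 1/3; speed of
#' sound c_s^2 = 1/3.  Direction 1 is the rest link; directions are paired
#' with their opposites via `opp`.
#'
#' @return list with `c` (19 x 3 integer matrix), `w` (weights), `opp`
#'   (index of the reversed direction) and `cs2`.
#' @export
d3q19 <- function() {
  cvec <- rbind(
    c(0, 0, 0),
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1),
    c(1, 1, 0), c(-1, -1, 0), c(1, -1, 0), c(-1, 1, 0),
    c(1, 0, 1), c(-1, 0, -1), c(1, 0, -1), c(-1, 0, 1),
    c(0, 1, 1), c(0, -1, -1), c(0, 1, -1), c(0, -1, 1))
  w <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
  opp <- vapply(seq_len(19), function(i) {
    which(colSums(t(cvec) == -cvec[i, ]) == 3L)
  }, integer(1))
  list(c = cvec, w = w, opp = opp, cs2 = 1 / 3)
}

#' Second-order equilibrium distribution
#'
#' f_eq,i = w_i rho (1 + c.u/cs2 + (c.u)^2/(2 cs4) - u^2/(2 cs2)).
#' The moments Sum f_eq = rho, Sum f_eq c = rho u and
#' Sum f_eq c c = rho cs2 I + rho u u hold exactly.
#'
#' @param rho density (scalar or length-n vector).
#' @param u velocity: length-3 vector or 3 x n matrix (lattice units).
#' @return 19-vector or 19 x n matrix of equilibrium distributions.
#' @export
equilibrium <- function(rho, u) {
  st <- d3q19()
  if (is.matrix(u)) {
    n <- ncol(u)
    cu <- st$c %*% u                      # 19 x n
    u2 <- colSums(u * u)                  # n
    f <- st$w * sweep(1 + 3 * cu + 4.5 * cu^2, 2, 1.5 * u2, "-")
    sweep(f, 2, rho, "*")
  } else {
    cu <- as.vector(st$c %*% u)
    u2 <- sum(u * u)
    rho * st$w * (1 + 3 * cu + 4.5 * cu^2 - 1.5 * u2)
  }
}

#' Macroscopic moments of a distribution state
#'
#' rho = Sum_i f_i and u = Sum_i f_i c_i / rho.
#'
#' @param f 19 x n matrix (or 19-vector) of distributions.
#' @return list with `rho` (length n) and `u` (3 x n matrix).
#' @export
macroscopic <- function(f) {
  st <- d3q19()
  if (!is.matrix(f)) f <- matrix(f, nrow = 19)
  rho <- colSums(f)
  if (any(!is.finite(rho)) || any(rho <= 0))
    nz_error("divergence",
             sprintf("non-positive or non-finite density at cell %d",
                     which(!is.finite(rho) | rho <= 0)[1]))
  u <- crossprod(st$c, f)                 # 3 x n
  u <- sweep(u, 2, rho, "/")
  list(rho = rho, u = u)
}

#' BGK collision (single relaxation time)
#'
#' f' = f + Omega (f_eq(rho, u) - f).  Serves as the independent oracle for
#' the multiple-relaxation-time operator with all rates equal.
#'
#' @param f 19 x n matrix of distributions.
#' @param omega relaxation rate in (0, 2).
#' @return collided 19 x n matrix.
#' @export
collide_bgk <- function(f, omega) {
  if (omega <= 0 || omega >= 2)
    nz_error("stability_domain", "0 < Omega < 2 required")
  m <- macroscopic(f)
  f + omega * (equilibrium(m$rho, m$u) - f)
}

#' Moment basis of the D3Q19 MRT operator
#'
#' Rows are the standard Gram-Schmidt moment polynomials of the
#' d'Humieres-type D3Q19 moment set evaluated at the 19 velocities:
#' density, energy, energy square, momentum and heat-flux vectors,
#' the five second-order (viscous stress) moments with their quartic
#' companions, and the three third-order antisymmetric moments.
#'
#' @return 19 x 19 numeric matrix `M` (rows = moments).
#' @export
mrt_moment_matrix <- function() {
  st <- d3q19()
  cx <- st$c[, 1]; cy <- st$c[, 2]; cz <- st$c[, 3]
  e2 <- cx^2 + cy^2 + cz^2
  rbind(
    rep(1, 19),
    19 * e2 - 30,
    (21 * e2^2 - 53 * e2 + 24) / 2,
    cx,
    (5 * e2 - 9) * cx,
    cy,
    (5 * e2 - 9) * cy,
    cz,
    (5 * e2 - 9) * cz,
    3 * cx^2 - e2,
    (3 * e2 - 5) * (3 * cx^2 - e2),
    cy^2 - cz^2,
    (3 * e2 - 5) * (cy^2 - cz^2),
    cx * cy,
    cy * cz,
    cx * cz,
    (cy^2 - cz^2) * cx,
    (cz^2 - cx^2) * cy,
    (cx^2 - cy^2) * cz)
}

#' Moment relaxation rates
#'
#' The five symmetric-traceless second-order moments (rows 10, 12, 14, 15,
#' 16 of [mrt_moment_matrix()]) are relaxed at the principal rate Omega
#' which sets the kinematic viscosity; the remaining non-conserved moments
#' use documented defaults that damp non-hydrodynamic (ghost) modes.
#' Conserved moments (density, momentum) are assigned rate 0 - they are
#' unaffected by collision regardless.
#'
#' @param omega principal relaxation rate.
#' @param s_e,s_eps,s_q,s_pi,s_m auxiliary rates for the energy, energy
#'   square, heat-flux, quartic-stress and third-order moments.  Pass
#'   `omega` for all to recover the BGK operator exactly.
#' @return length-19 vector of rates in moment order.
#' @export
mrt_rates <- function(omega, s_e = 1.19, s_eps = 1.4, s_q = 1.2,
                      s_pi = 1.4, s_m = 1.98) {
  c(0, s_e, s_eps, 0, s_q, 0, s_q, 0, s_q,
    omega, s_pi, omega, s_pi, omega, omega, omega, s_m, s_m, s_m)
}

#' Dense MRT collision operator
#'
#' C = M^-1 diag(s) M, so that collision is f' = f + C (f_eq - f).  The
#' equilibrium moments are taken as M f_eq with the quadratic equilibrium
#' of [equilibrium()], hence equal rates reduce the operator to BGK
#' identically.
#'
#' @param omega principal relaxation rate in (0, 2).
#' @param rates optional length-19 rate vector (default [mrt_rates()]).
#' @return 19 x 19 collision matrix.
#' @export
mrt_collision_matrix <- function(omega, rates = mrt_rates(omega)) {
  if (omega <= 0 || omega >= 2)
    nz_error("stability_domain", "0 < Omega < 2 required")
  M <- mrt_moment_matrix()
  solve(M, rates * M)     # M^-1 S M
}

#' MRT collision (R reference path)
#'
#' Matrix-form multiple-relaxation-time collision; the C++ kernel used by
#' the solver applies the same operator cell-by-cell.
#'
#' @param f 19 x n matrix.
#' @param C collision matrix from [mrt_collision_matrix()].
#' @return collided 19 x n matrix.
#' @export
collide_mrt <- function(f, C) {
  m <- macroscopic(f)
  f + C %*% (equilibrium(m$rho, m$u) - f)
}

#' Deviatoric shear stress from non-equilibrium moments
#'
#' sigma = -(1 - Omega/2) Pi_neq_dev, where Pi_neq = Sum_i (f_i - f_eq,i)
#' c_i c_i.  Local (no finite differences).  With a `flow_case` the result
#' is rescaled to Pa via rho_phys (dx/dt)^2.
#'
#' @param f 19 x n matrix.
#' @param omega principal relaxation rate.
#' @param case optional `flow_case` for physical rescaling.
#' @return 6 x n matrix with rows (xx, yy, zz, xy, yz, xz).
#' @export
shear_stress <- function(f, omega, case = NULL) {
  st <- d3q19()
  if (!is.matrix(f)) f <- matrix(f, nrow = 19)
  m <- macroscopic(f)
  fneq <- f - equilibrium(m$rho, m$u)
  cx <- st$c[, 1]; cy <- st$c[, 2]; cz <- st$c[, 3]
  pxx <- colSums(fneq * cx * cx)
  pyy <- colSums(fneq * cy * cy)
  pzz <- colSums(fneq * cz * cz)
  tr3 <- (pxx + pyy + pzz) / 3
  fac <- -(1 - omega / 2)
  out <- rbind(xx = fac * (pxx - tr3), yy = fac * (pyy - tr3),
               zz = fac * (pzz - tr3),
               xy = fac * colSums(fneq * cx * cy),
               yz = fac * colSums(fneq * cy * cz),
               xz = fac * colSums(fneq * cx * cz))
  if (!is.null(case)) {
    scale <- case$fluid$rho * (case$lattice$dx / case$lattice$dt)^2
    out <- out * scale
  }
  out
}
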