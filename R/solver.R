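## Time integration: collide -> boundary-fused stream -> outlet pin.

#' Initial distribution state
#'
#' Equilibrium state at the given density and velocity (defaults: the
#' zero-velocity reference state, mirroring the zero pressure / zero
#' velocity initial condition of the benchmark runs).
#'
#' @param dom an `lbm_domain`.
#' @param rho density per cell (scalar or vector, default `dom$rho0`).
#' @param u velocity (3-vector, 3 x n matrix, or NULL for rest).
#' @return 19 x n distribution matrix.
#' @export
init_state <- function(dom, rho = dom$rho0, u = NULL) {
  n <- dom$n_fluid
  if (is.null(u)) u <- matrix(0, 3, n)
  if (!is.matrix(u)) u <- matrix(u, 3, n)
  rho <- rep_len(rho, n)
  equilibrium(rho, u)
}

#' Run the lattice Boltzmann time loop
#'
#' One step is: MRT collision, streaming with fused wall/inlet/outlet
#' handling, and the outlet density pin.  The inflow target is ramped
#' linearly from zero over `ramp_steps` steps to avoid the initial
#' pressure shock.  The loop aborts with a `divergence` error (carrying
#' the step index) if any lattice speed reaches `mach_limit` or a density
#' turns non-positive or non-finite.
#'
#' @param dom an `lbm_domain`.
#' @param omega principal relaxation rate.
#' @param f0 initial 19 x n state (default [init_state()]).
#' @param n_steps number of time steps (>= 0).
#' @param rates optional moment relaxation rates ([mrt_rates()] default;
#'   pass `rep(omega, 19)` for BGK).
#' @param ramp_steps inflow ramp length in steps (default 0: full strength).
#' @param probe_cells fluid-cell column indices to sample.
#' @param probe_every sampling cadence in steps (default 1).
#' @param sample_every accumulate running mean fields every this many
#'   steps (0 = off).
#' @param sample_from first step included in the mean (default
#'   `n_steps %/% 5 + 1`, i.e. the final 80 percent of the run).
#' @param mach_limit abort threshold on the lattice speed (default 0.15).
#' @param check_every guard-check cadence (default 8).
#' @param outlet_mode "pin" (momentum-preserving density shift, default)
#'   or "equilibrium" (equilibrium at the reference density and the local
#'   velocity in the outlet layer; more dissipative, recommended when a
#'   jet leaves through the outlet).
#' @return object of class `lbm_run`: final state `f`, probe series
#'   (`probes`: array steps x cells x (rho, ux, uy, uz), `probe_t` step
#'   indices), running-mean fields (`mean_rho`, `mean_u`, `n_samples`),
#'   and the configuration echo.
#' @export
lbm_run <- function(dom, omega, f0 = NULL, n_steps,
                    rates = mrt_rates(omega),
                    ramp_steps = 0L,
                    probe_cells = NULL, probe_every = 1L,
                    sample_every = 0L, sample_from = NULL,
                    mach_limit = 0.15, check_every = 8L,
                    outlet_mode = c("pin", "equilibrium")) {
  stopifnot(inherits(dom, "lbm_domain"), n_steps >= 0)
  outlet_mode <- match.arg(outlet_mode)
  omode <- if (outlet_mode == "equilibrium") 1L else 0L
  st <- dom$stencil
  C <- mrt_collision_matrix(omega, rates)
  f <- f0 %||% init_state(dom)
  f <- f + 0          # own copy: collision mutates in place
  fbuf <- matrix(0, 19, dom$n_fluid)
  work <- matrix(0, 19, dom$n_fluid)   # collision scratch (non-equilibrium)
  sample_from <- sample_from %||% (n_steps %/% 5 + 1L)
  nprobe <- length(probe_cells)
  probes <- NULL; probe_t <- integer(0)
  if (nprobe) {
    nrec <- n_steps %/% probe_every
    probes <- array(NA_real_, dim = c(nrec, nprobe, 4L))
    dimnames(probes) <- list(NULL, NULL, c("rho", "ux", "uy", "uz"))
    probe_t <- integer(nrec)
  }
  mean_acc <- NULL; n_samp <- 0L
  prec <- 0L
  for (step in seq_len(n_steps)) {
    guard <- lbm_collide_cpp(f, C, st$c, st$w, work)
    if (step %% check_every == 0L || step == n_steps) {
      if (!is.finite(guard[2]) || guard[2] <= 0)
        nz_error("divergence",
                 sprintf("non-positive density at step %d", step), step = step)
      if (guard[1] >= mach_limit)
        nz_error("divergence",
                 sprintf("lattice speed %.3f reached the Mach limit %.3g at step %d",
                         guard[1], mach_limit, step),
                 step = step, u_lattice = guard[1])
    }
    ramp <- if (ramp_steps > 0L) min(1, step / ramp_steps) else 1
    lbm_stream_cpp(f, fbuf, dom$pull, dom$ltype, dom$q, dom$aux,
                   dom$icoef, ramp, st$opp)
    tmp <- f; f <- fbuf; fbuf <- tmp
    if (length(dom$outlet_cells))
      lbm_density_pin_cpp(f, dom$outlet_cells, st$w, dom$rho0, st$c, omode)
    if (nprobe && step %% probe_every == 0L) {
      prec <- prec + 1L
      m <- lbm_macro_cpp(f[, probe_cells, drop = FALSE], st$c)
      probes[prec, , ] <- t(m)
      probe_t[prec] <- step
    }
    if (sample_every > 0L && step >= sample_from &&
        (step - sample_from) %% sample_every == 0L) {
      m <- lbm_macro_cpp(f, st$c)
      if (is.null(mean_acc)) mean_acc <- m * 0
      mean_acc <- mean_acc + m
      n_samp <- n_samp + 1L
    }
  }
  mean_rho <- NULL; mean_u <- NULL
  if (n_samp > 0L) {
    mean_acc <- mean_acc / n_samp
    mean_rho <- mean_acc[1, ]
    mean_u <- mean_acc[2:4, , drop = FALSE]
  }
  structure(list(
    f = f, dom = dom, omega = omega, rates = rates,
    n_steps = n_steps, ramp_steps = ramp_steps,
    probes = if (nprobe) probes[seq_len(prec), , , drop = FALSE] else NULL,
    probe_t = probe_t, probe_cells = probe_cells,
    mean_rho = mean_rho, mean_u = mean_u, n_samples = n_samp
  ), class = "lbm_run")
}

#' @export
print.lbm_run <- function(x, ...) {
  cat(sprintf("<lbm_run> %d steps on %d fluid cells (Omega = %g)\n",
              x$n_steps, x$dom$n_fluid, x$omega))
  if (!is.null(x$probes))
    cat(sprintf("  probes: %d cells x %d records\n",
                dim(x$probes)[2], dim(x$probes)[1]))
  if (x$n_samples > 0)
    cat(sprintf("  mean fields accumulated over %d samples\n", x$n_samples))
  invisible(x)
}

#' Streaming step (R surface)
#'
#' Applies one streaming step (with boundary handling) to a state; thin
#' wrapper over the fused kernel for tests and single-step use.
#'
#' @param f 19 x n post-collision state.
#' @param dom an `lbm_domain`.
#' @param ramp inflow ramp factor in `[0, 1]` (default 1).
#' @return streamed 19 x n state.
#' @export
stream <- function(f, dom, ramp = 1) {
  out <- matrix(0, 19, dom$n_fluid)
  lbm_stream_cpp(f, out, dom$pull, dom$ltype, dom$q, dom$aux,
                 dom$icoef, ramp, dom$stencil$opp)
  out
}

#' Vorticity magnitude of a velocity field
#'
#' Curl by second-order central differences, one-sided at walls and domain
#' boundaries (cells without an opposing fluid neighbor).  Exact for
#' linear fields: a rigid rotation at rate omega gives magnitude 2*omega.
#'
#' @param ux,uy,uz 3-D arrays of velocity components (NA outside fluid).
#' @param dx grid spacing.
#' @return 3-D array of the vorticity magnitude (NA outside fluid).
#' @export
vorticity <- function(ux, uy, uz, dx) {
  duy_dx <- deriv3d(uy, 1, dx); duz_dx <- deriv3d(uz, 1, dx)
  dux_dy <- deriv3d(ux, 2, dx); duz_dy <- deriv3d(uz, 2, dx)
  dux_dz <- deriv3d(ux, 3, dx); duy_dz <- deriv3d(uy, 3, dx)
  wx <- duz_dy - duy_dz
  wy <- dux_dz - duz_dx
  wz <- duy_dx - dux_dy
  sqrt(wx^2 + wy^2 + wz^2)
}

## Partial derivative of a 3-D array along `axis` by central differences,
## falling back to one-sided differences where a neighbor is NA (walls),
## NA where no fluid neighbor exists on either side.
deriv3d <- function(a, axis, dx) {
  d <- dim(a)
  shift <- function(arr, by) {
    n <- d[axis]
    out <- array(NA_real_, dim = d)
    if (by > 0) { dst <- seq_len(n - by); src <- dst + by }
    else        { src <- seq_len(n + by); dst <- src - by }
    switch(axis,
           out[dst, , ] <- arr[src, , , drop = FALSE],
           out[, dst, ] <- arr[, src, , drop = FALSE],
           out[, , dst] <- arr[, , src, drop = FALSE])
    out
  }
  ap <- shift(a, +1L)   # value at i+1
  am <- shift(a, -1L)   # value at i-1
  ctr <- (ap - am) / (2 * dx)
  fwd <- (ap - a) / dx
  bwd <- (a - am) / dx
  out <- ctr
  use_fwd <- is.na(ctr) & !is.na(fwd)
  use_bwd <- is.na(ctr) & !is.na(bwd)
  out[use_fwd] <- fwd[use_fwd]
  out[use_bwd] <- bwd[use_bwd]
  out[is.na(a)] <- NA_real_
  out
}
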