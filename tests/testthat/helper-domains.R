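# Small domain builders and independent reference implementations used as
# oracles across the solver tests.

blood <- fluid_spec()   # benchmark fluid: 1056 kg/m^3, 0.0035 Pa s

periodic_box <- function(n = c(6L, 6L, 6L)) {
  build_domain(array(1L, n), dx = 1, periodic = c(TRUE, TRUE, TRUE))
}

# plane channel: walls at the y extremes, periodic in x and z
channel_domain <- function(nx = 4L, ny = 10L, nz = 4L, wall_u = NULL) {
  flags <- array(1L, c(nx, ny, nz))
  flags[, 1, ] <- 0L
  flags[, ny, ] <- 0L
  build_domain(flags, dx = 1, periodic = c(TRUE, FALSE, TRUE),
               wall_velocity = wall_u)
}

# random admissible state: positive perturbation of an equilibrium
random_state <- function(dom, seed = 1) {
  set.seed(seed)
  f <- init_state(dom, rho = 1 + 0.05 * runif(dom$n_fluid),
                  u = matrix(runif(3 * dom$n_fluid, -0.05, 0.05), 3))
  f * (1 + 0.1 * matrix(runif(length(f)), nrow = 19))
}

# independent half-way bounce-back streaming reference: plain pull for
# fluid-fluid links, f_i(x) <- fpost_opp(i)(x) for links whose upstream
# neighbor is not fluid.  Written directly against the flag array, not the
# solver's link tables.
ref_stream_halfway <- function(fpost, flags, periodic) {
  st <- d3q19()
  d <- dim(flags)
  fluid_idx <- which(flags == 1L)
  map <- array(0L, dim = d); map[fluid_idx] <- seq_along(fluid_idx)
  i0 <- (fluid_idx - 1L) %% d[1]
  j0 <- ((fluid_idx - 1L) %/% d[1]) %% d[2]
  k0 <- (fluid_idx - 1L) %/% (d[1] * d[2])
  out <- matrix(0, 19, length(fluid_idx))
  out[1, ] <- fpost[1, ]
  for (i in 2:19) {
    j <- st$opp[i]
    ii <- i0 - st$c[i, 1]; jj <- j0 - st$c[i, 2]; kk <- k0 - st$c[i, 3]
    if (periodic[1]) ii <- ii %% d[1]
    if (periodic[2]) jj <- jj %% d[2]
    if (periodic[3]) kk <- kk %% d[3]
    up <- 1L + ii + d[1] * (jj + d[2] * kk)
    from_fluid <- flags[up] == 1L
    out[i, from_fluid] <- fpost[i, map[up[from_fluid]]]
    out[i, !from_fluid] <- fpost[j, !from_fluid]
  }
  out
}

# L2 relative error helper
l2_rel <- function(x, ref) sqrt(sum((x - ref)^2) / sum(ref^2))
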