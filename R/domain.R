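## Assembly of a solver-ready domain from a flag field.
##
## For every fluid cell and every stencil direction the builder resolves
## where the post-streaming population comes from: a fluid neighbor, a
## Bouzidi wall link, the inflow plane, or the extrapolation outflow.

#' Build a solver domain
#'
#' Turns a flag array (0 solid, 1 fluid, 2 inlet, 3 outlet) into the link
#' tables consumed by the streaming kernel.  Non-periodic axes must be
#' padded so that every fluid cell has in-array neighbors ([voxelize()]
#' guarantees this); periodic axes wrap.
#'
#' @param flags integer 3-D array, or a `flag_field` from [voxelize()] /
#'   [wall_link_distances()] (its `q` matrix is then used for wall links;
#'   otherwise walls default to half-way bounce-back, q = 1/2).
#' @param dx grid spacing (m); taken from the `flag_field` if given.
#' @param periodic logical length-3: wrap the x/y/z axis.
#' @param inlet_velocity `function(x, y, z)` returning the inflow velocity
#'   (3-vector or n x 3 matrix, lattice units) at link-cut positions on the
#'   inlet plane.
#' @param wall_velocity optional `function(x, y, z)` for moving walls
#'   (lattice units), evaluated at the wall intersection point.
#' @param rho0 reference (outlet) density, default 1.
#' @param origin grid origin (m), center of cell `[1,1,1]`.
#' @return object of class `lbm_domain`.
#' @export
build_domain <- function(flags, dx = NULL, periodic = c(FALSE, FALSE, FALSE),
                         inlet_velocity = NULL, wall_velocity = NULL,
                         rho0 = 1, origin = NULL) {
  qfield <- NULL; geom <- NULL; zlim <- NULL
  if (inherits(flags, "flag_field")) {
    field <- flags
    dx <- dx %||% field$dx
    origin <- origin %||% field$origin
    qfield <- field$q
    geom <- field$geometry
    zlim <- field$zlim
    flags <- field$flags
  }
  stopifnot(is.array(flags), length(dim(flags)) == 3)
  dx <- dx %||% 1
  origin <- origin %||% c(0, 0, 0)
  st <- d3q19()
  d <- dim(flags)
  fluid_idx <- which(flags == 1L)
  n <- length(fluid_idx)
  if (n == 0L) nz_error("invalid_parameter", "no fluid cells")
  map <- array(0L, dim = d)
  map[fluid_idx] <- seq_len(n)
  i0 <- (fluid_idx - 1L) %% d[1]
  j0 <- ((fluid_idx - 1L) %/% d[1]) %% d[2]
  k0 <- (fluid_idx - 1L) %/% (d[1] * d[2])

  neighbor_of <- function(ci) {
    ii <- i0 + ci[1]; jj <- j0 + ci[2]; kk <- k0 + ci[3]
    if (periodic[1]) ii <- ii %% d[1]
    if (periodic[2]) jj <- jj %% d[2]
    if (periodic[3]) kk <- kk %% d[3]
    out <- ii < 0L | ii >= d[1] | jj < 0L | jj >= d[2] | kk < 0L | kk >= d[3]
    if (any(out))
      nz_error("invalid_parameter",
               "fluid cell touches the array boundary on a non-periodic axis; pad the flag array")
    1L + ii + d[1] * (jj + d[2] * kk)
  }

  pull <- matrix(0L, 19, n); ltype <- matrix(0L, 19, n)
  aux <- matrix(0L, 19, n); qm <- matrix(0, 19, n)
  icoef <- matrix(0, 19, n)
  pull[1, ] <- seq_len(n)     # rest population stays

  centers <- cbind(origin[1] + i0 * dx, origin[2] + j0 * dx,
                   origin[3] + k0 * dx)
  inlet_cells <- integer(0); outlet_cells <- integer(0)

  for (i in 2:19) {
    j <- st$opp[i]
    up <- neighbor_of(st$c[j, ])           # upstream cell y = x + c_j
    fl <- flags[up]
    ## type 0: fluid upstream
    is_f <- fl == 1L
    pull[i, is_f] <- map[up[is_f]]
    ## type 1: wall upstream (Bouzidi on link j)
    is_w <- fl == 0L
    if (any(is_w)) {
      ltype[i, is_w] <- 1L
      qv <- if (!is.null(qfield)) qfield[j, is_w] else rep(0.5, sum(is_w))
      qv[is.na(qv)] <- 0.5
      qm[i, is_w] <- qv
      dn <- neighbor_of(st$c[i, ])         # x + c_i, second node
      ok <- is_w & flags[dn] == 1L
      aux[i, ok] <- map[dn[ok]]
      if (!is.null(wall_velocity)) {
        wcells <- which(is_w)
        p <- centers[wcells, , drop = FALSE] +
          matrix(st$c[j, ], nrow = length(wcells), ncol = 3, byrow = TRUE) *
          qm[i, wcells] * dx
        uw <- wall_velocity(p[, 1], p[, 2], p[, 3])
        uw <- matrix(uw, ncol = 3)
        icoef[i, wcells] <- -6 * st$w[j] * rho0 * (uw %*% st$c[j, ])
      }
    }
    ## type 2: inlet upstream (half-way velocity bounce-back)
    is_in <- fl == 2L
    if (any(is_in)) {
      ltype[i, is_in] <- 2L
      wcells <- which(is_in)
      inlet_cells <- union(inlet_cells, wcells)
      if (is.null(inlet_velocity))
        nz_error("invalid_parameter",
                 "flag field has inlet cells but no inlet_velocity was given")
      p <- centers[wcells, , drop = FALSE] +
        matrix(st$c[j, ], nrow = length(wcells), ncol = 3, byrow = TRUE) *
        0.5 * dx
      uw <- matrix(inlet_velocity(p[, 1], p[, 2], p[, 3]), ncol = 3)
      icoef[i, wcells] <- -6 * st$w[j] * rho0 * (uw %*% st$c[j, ])
    }
    ## type 3: outlet upstream (extrapolate from the interior neighbor)
    is_out <- fl == 3L
    if (any(is_out)) {
      ltype[i, is_out] <- 3L
      wcells <- which(is_out)
      outlet_cells <- union(outlet_cells, wcells)
      ## interior neighbor against the outlet normal (the z axis by
      ## construction of voxelize); fall back to the cell itself
      into <- neighbor_of(c(0L, 0L, -1L))
      src <- ifelse(flags[into[wcells]] == 1L, map[into[wcells]], wcells)
      pull[i, wcells] <- src
    }
  }

  structure(list(
    dim = d, dx = dx, origin = origin, periodic = periodic,
    flags = flags, fluid_idx = fluid_idx, map = map,
    n_fluid = n,
    pull = pull, ltype = ltype, aux = aux, q = qm, icoef = icoef,
    inlet_cells = sort(inlet_cells), outlet_cells = sort(outlet_cells),
    rho0 = rho0, stencil = st,
    geometry = geom, zlim = zlim,
    centers = centers
  ), class = "lbm_domain")
}

#' @export
print.lbm_domain <- function(x, ...) {
  cat(sprintf("<lbm_domain> %d fluid cells in a %d x %d x %d box (dx = %g)\n",
              x$n_fluid, x$dim[1], x$dim[2], x$dim[3], x$dx))
  cat(sprintf("  inlet-adjacent cells: %d, outlet-adjacent cells: %d, periodic: %s\n",
              length(x$inlet_cells), length(x$outlet_cells),
              paste(ifelse(x$periodic, "T", "F"), collapse = "")))
  invisible(x)
}

#' Scatter per-fluid-cell values onto the 3-D grid
#'
#' @param dom an `lbm_domain`.
#' @param values length `n_fluid` vector.
#' @param fill value for non-fluid cells (default NA).
#' @return 3-D array of `dim(dom$dim)`.
#' @export
field_array <- function(dom, values, fill = NA_real_) {
  a <- array(fill, dim = dom$dim)
  a[dom$fluid_idx] <- values
  a
}
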