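## Parametric sudden-expansion nozzle geometry and lattice voxelization.
##
## The benchmark device is a circular pipe (diameter 0.012 m) with a conical
## contraction down to a throat (diameter 0.004 m, length 0.04 m) followed by
## a sudden expansion back to the pipe diameter.  The axial coordinate z has
## its origin at the sudden-expansion plane; flow is in +z.

#' Parametric FDA nozzle geometry
#'
#' Analytic axisymmetric description of the sudden-expansion nozzle.  The
#' published drawings do not list every dimension; the constants here are
#' the public benchmark definition: inlet/outlet diameter 0.012 m, throat
#' diameter 0.004 m, throat length 0.04 m, and a conical contraction whose
#' length follows from the 10 degree half-angle.  Inlet and outlet
#' extensions default to the full extents z = -0.14 m and z = 0.253 m and
#' may be truncated for desk-scale runs.
#'
#' @param throat_radius throat radius in m (default 0.002).
#' @param inlet_radius inlet/outlet pipe radius in m (default 0.006).
#' @param throat_length throat length in m (default 0.04).
#' @param contraction_half_angle_deg half-angle of the conical contraction
#'   in degrees (default 10).
#' @param z_min,z_max axial extent in m (defaults -0.14 and 0.253).
#' @return Object of class `nozzle_geometry` with the radius profile
#'   breakpoints precomputed.  The sudden expansion sits at z = 0.
#' @export
fda_nozzle <- function(throat_radius = 0.002, inlet_radius = 0.006,
                       throat_length = 0.04, contraction_half_angle_deg = 10,
                       z_min = -0.14, z_max = 0.253) {
  stopifnot(throat_radius > 0, inlet_radius > throat_radius, throat_length > 0)
  con_len <- (inlet_radius - throat_radius) /
    tan(contraction_half_angle_deg * pi / 180)
  z_throat_start <- -throat_length
  z_con_start <- z_throat_start - con_len
  if (z_min >= z_con_start)
    nz_error("invalid_parameter", "z_min must lie upstream of the contraction")
  if (z_max <= 0)
    nz_error("invalid_parameter", "z_max must lie downstream of the expansion")
  structure(list(
    throat_radius = throat_radius,
    inlet_radius = inlet_radius,
    throat_length = throat_length,
    contraction_half_angle_deg = contraction_half_angle_deg,
    z_con_start = z_con_start,
    z_throat_start = z_throat_start,
    z_expansion = 0,
    z_min = z_min, z_max = z_max
  ), class = "nozzle_geometry")
}

#' @export
print.nozzle_geometry <- function(x, ...) {
  cat(sprintf("<nozzle_geometry> throat d = %g m (length %g m), pipe d = %g m\n",
              2 * x$throat_radius, x$throat_length, 2 * x$inlet_radius))
  cat(sprintf("  contraction z in [%.5g, %.5g] m, expansion at z = 0, extent [%g, %g] m\n",
              x$z_con_start, x$z_throat_start, x$z_min, x$z_max))
  invisible(x)
}

#' Truncate a nozzle geometry for desk-scale runs
#'
#' Shortens the inlet and outlet extensions; the contraction, throat and
#' expansion plane are untouched.
#'
#' @param geometry a `nozzle_geometry`.
#' @param z_min,z_max new axial extent (m).
#' @return a `nozzle_geometry` with the new extent and a `truncated` flag.
#' @export
truncate_nozzle <- function(geometry, z_min, z_max) {
  stopifnot(inherits(geometry, "nozzle_geometry"))
  g <- fda_nozzle(geometry$throat_radius, geometry$inlet_radius,
                  geometry$throat_length, geometry$contraction_half_angle_deg,
                  z_min = z_min, z_max = z_max)
  g$truncated <- TRUE
  g
}

#' Analytic radius profile r(z)
#'
#' Piecewise profile: inlet pipe radius upstream of the contraction, linear
#' taper through the contraction, throat radius on the throat interval, and
#' the outlet pipe radius from the expansion plane on.  The profile is
#' right-continuous at the sudden expansion: r(0) is the outlet radius,
#' while the limit from upstream is the throat radius.
#'
#' @param geometry a `nozzle_geometry` or `pipe_geometry`.
#' @param z axial position(s) in m, within `[z_min, z_max]`.
#' @return radius in m (vectorized over `z`).
#' @export
radius_at <- function(geometry, z) UseMethod("radius_at")

#' @export
radius_at.pipe_geometry <- function(geometry, z) {
  if (any(z < geometry$z_min - 1e-12) || any(z > geometry$z_max + 1e-12))
    nz_error("range_error", "z outside the geometry extent")
  rep_len(geometry$throat_radius, length(z))
}

#' @export
radius_at.nozzle_geometry <- function(geometry, z) {
  if (any(z < geometry$z_min - 1e-12) || any(z > geometry$z_max + 1e-12))
    nz_error("range_error", "z outside the geometry extent")
  g <- geometry
  r <- numeric(length(z))
  r[z < g$z_con_start] <- g$inlet_radius
  in_con <- z >= g$z_con_start & z < g$z_throat_start
  frac <- (z[in_con] - g$z_con_start) / (g$z_throat_start - g$z_con_start)
  r[in_con] <- g$inlet_radius + frac * (g$throat_radius - g$inlet_radius)
  r[z >= g$z_throat_start & z < 0] <- g$throat_radius
  r[z >= 0] <- g$inlet_radius
  r
}

## Point-membership test: strictly inside the fluid region.
inside_nozzle <- function(geometry, x, y, z) {
  ok <- z >= geometry$z_min & z <= geometry$z_max
  ok & sqrt(x^2 + y^2) < radius_at(geometry, pmin(pmax(z, geometry$z_min),
                                                  geometry$z_max))
}

#' Measurement stations of the benchmark
#'
#' The 12 axial stations at which profiles, pressure and spectra are
#' analyzed (z = 0 is the sudden-expansion plane).
#'
#' @return data.frame with columns `station` ("z1".."z12") and `z_m`.
#' @export
nozzle_stations <- function() {
  data.frame(
    station = paste0("z", 1:12),
    z_m = c(-0.088, -0.064, -0.048, -0.02, -0.008, 0.0,
            0.008, 0.016, 0.024, 0.032, 0.06, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Voxelize a geometry onto a uniform lattice
#'
#' Cell-center classification on a uniform grid of spacing `dx`.  The
#' transverse grid is symmetric about the axis with an even cell count, so
#' that the number of fluid cells across a diameter equals `round(d/dx)`.
#' The first and last axial planes inside the extent are flagged inlet and
#' outlet respectively (one ghost plane each is added beyond them).
#'
#' Flag legend: 0 = solid, 1 = fluid, 2 = inlet, 3 = outlet.
#'
#' @param geometry a `nozzle_geometry` or `pipe_geometry` (any object with
#'   a [radius_at()] method).
#' @param dx grid spacing in m; must put >= 4 cells across the throat.
#' @param zlim optional axial sub-extent `c(zmin, zmax)` to voxelize
#'   (defaults to the geometry extent).
#' @return Object of class `flag_field`: list with the integer `flags`
#'   array, `dx`, `origin` (coordinates of the center of cell \[1,1,1\]),
#'   grid dimensions and the generating geometry.
#' @export
voxelize <- function(geometry, dx, zlim = NULL) {
  stopifnot(inherits(geometry, "nozzle_geometry") ||
              inherits(geometry, "pipe_geometry"))
  d <- 2 * geometry$throat_radius
  if (round(d / dx) < 4)
    nz_error("under_resolved",
             sprintf("dx = %g m puts fewer than 4 cells across the throat", dx))
  zlim <- zlim %||% c(geometry$z_min, geometry$z_max)
  rmax <- geometry$inlet_radius
  ## transverse: even number of cells, axis on a cell-corner
  nhalf <- ceiling(rmax / dx) + 1L
  nx <- 2L * nhalf
  xc <- (seq_len(nx) - nhalf - 0.5) * dx      # cell centers, symmetric about 0
  nz <- max(3L, floor((zlim[2] - zlim[1]) / dx))
  zc <- zlim[1] + (seq_len(nz) - 0.5) * dx
  flags <- array(0L, dim = c(nx, nx, nz + 2L)) # +2 ghost planes (inlet/outlet)
  ## classify interior planes
  r2 <- outer(xc^2, xc^2, "+")
  for (k in seq_len(nz)) {
    rk <- radius_at(geometry, zc[k])
    flags[, , k + 1L][r2 < rk^2] <- 1L
  }
  ## ghost planes carry the inlet/outlet flags, shaped like the adjacent plane
  flags[, , 1L][flags[, , 2L] == 1L] <- 2L
  flags[, , nz + 2L][flags[, , nz + 1L] == 1L] <- 3L
  structure(list(
    flags = flags, dx = dx,
    origin = c(xc[1], xc[1], zc[1] - dx),  # center of cell [1,1,1] (ghost plane)
    dim = dim(flags),
    zlim = zlim,
    geometry = geometry
  ), class = "flag_field")
}

#' @export
print.flag_field <- function(x, ...) {
  n <- table(factor(x$flags, levels = 0:3,
                    labels = c("solid", "fluid", "inlet", "outlet")))
  cat(sprintf("<flag_field> %d x %d x %d cells at dx = %g m\n",
              x$dim[1], x$dim[2], x$dim[3], x$dx))
  cat("  ", paste(names(n), n, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

## Cell-center coordinates for linear indices into the flag array.
cell_centers <- function(field, idx) {
  d <- field$dim
  idx <- idx - 1L
  i <- idx %% d[1]
  j <- (idx %/% d[1]) %% d[2]
  k <- idx %/% (d[1] * d[2])
  cbind(x = field$origin[1] + i * field$dx,
        y = field$origin[2] + j * field$dx,
        z = field$origin[3] + k * field$dx)
}

#' Count fluid cells across the throat diameter
#'
#' Convenience check mirroring the benchmark's tabulated `nCells_th`
#' (50/100/200 at 80/40/20 um).
#'
#' @param field a `flag_field` that covers part of the throat.
#' @return integer cell count along an axis-crossing transverse line at a
#'   throat plane.
#' @export
throat_cell_count <- function(field) {
  g <- field$geometry
  zq <- (g$z_throat_start + 0) / 2          # mid-throat
  k <- round((zq - field$origin[3]) / field$dx) + 1L
  k <- min(max(k, 2L), field$dim[3] - 1L)
  jrow <- field$dim[2] %/% 2L               # row adjacent to the axis
  sum(field$flags[, jrow, k] == 1L)
}

#' Sub-cell wall distances for the Bouzidi boundary condition
#'
#' For every lattice link from a fluid cell to a solid cell, computes the
#' fraction q in (0, 1] of the link length at which the analytic surface is
#' crossed.  The crossing is located by bisection on the inside/outside
#' indicator, which is robust at the sudden-expansion discontinuity and
#' converges well below 1e-9 of a cell.
#'
#' @param field a `flag_field` from [voxelize()].
#' @param iters bisection iterations (default 60: q resolved to ~1e-18).
#' @return the `flag_field` with a `q` matrix attached: 19 rows (stencil
#'   directions; row 1 is the rest link and unused) by n_fluid columns,
#'   NA where the link is not cut.
#' @export
wall_link_distances <- function(field, iters = 60L) {
  st <- d3q19()
  g <- field$geometry
  flags <- field$flags
  fluid_idx <- which(flags == 1L)
  centers <- cell_centers(field, fluid_idx)
  d <- field$dim
  nfl <- length(fluid_idx)
  qmat <- matrix(NA_real_, nrow = 19L, ncol = nfl)
  ## decompose linear indices once
  i0 <- (fluid_idx - 1L) %% d[1]
  j0 <- ((fluid_idx - 1L) %/% d[1]) %% d[2]
  k0 <- (fluid_idx - 1L) %/% (d[1] * d[2])
  for (q in 2:19) {
    ci <- st$c[q, ]
    ii <- i0 + ci[1]; jj <- j0 + ci[2]; kk <- k0 + ci[3]
    inb <- ii >= 0L & ii < d[1] & jj >= 0L & jj < d[2] & kk >= 0L & kk < d[3]
    nidx <- 1L + ii + d[1] * (jj + d[2] * kk)
    nidx_safe <- pmin(pmax(nidx, 1L), length(flags))
    is_solid <- inb & flags[nidx_safe] == 0L
    cut <- which(is_solid)
    if (!length(cut)) next
    p0 <- centers[cut, , drop = FALSE]
    dxv <- ci * field$dx
    ## bisection on the inside indicator along the link
    lo <- rep(0, length(cut)); hi <- rep(1, length(cut))
    for (it in seq_len(iters)) {
      mid <- 0.5 * (lo + hi)
      ins <- inside_nozzle(g, p0[, 1] + mid * dxv[1], p0[, 2] + mid * dxv[2],
                           p0[, 3] + mid * dxv[3])
      lo[ins] <- mid[ins]
      hi[!ins] <- mid[!ins]
    }
    qv <- 0.5 * (lo + hi)
    ## a link flagged as cut must actually cross the surface
    if (any(qv <= 0))
      nz_error("geometry_consistency",
               "cut link with no surface intersection found")
    qmat[q, cut] <- pmin(qv, 1)
  }
  field$q <- qmat
  field$fluid_idx <- fluid_idx
  field
}

#' Station cell masks
#'
#' Maps each measurement station to its nearest lattice plane and returns
#' the fluid-cell index sets of the full cross-section and of a radial
#' line (y ~ 0, x across the diameter), plus the near-axis centerline cells.
#'
#' @param field a `flag_field`.
#' @param stations data.frame with columns `station`, `z_m`
#'   (default [nozzle_stations()]); stations outside the voxelized extent
#'   are dropped with a message unless `strict`.
#' @param strict error on out-of-extent stations (default FALSE).
#' @return list with one element per retained station: list(station, z_m,
#'   plane_k, section (linear indices), radial (indices ordered by x),
#'   centerline (the 4 cells nearest the axis)).
#' @export
station_profiles_mask <- function(field, stations = nozzle_stations(),
                                  strict = FALSE) {
  d <- field$dim
  zs <- stations$z_m
  keep <- zs >= field$zlim[1] & zs <= field$zlim[2]
  if (any(!keep)) {
    if (strict) nz_error("range_error", "station outside voxelized extent")
    stations <- stations[keep, , drop = FALSE]
  }
  jc <- d[2] %/% 2L   # the two rows adjacent to the axis are jc, jc+1
  out <- lapply(seq_len(nrow(stations)), function(s) {
    k <- round((stations$z_m[s] - field$origin[3]) / field$dx) + 1L
    k <- min(max(k, 2L), d[3] - 1L)
    plane <- field$flags[, , k]
    sec <- which(plane == 1L) # indices within plane
    sec_lin <- sec + (k - 1L) * d[1] * d[2] # linear indices in 3-D array
    radial_i <- which(plane[, jc] == 1L)
    radial_lin <- radial_i + (jc - 1L) * d[1] + (k - 1L) * d[1] * d[2]
    ic <- d[1] %/% 2L
    ctr <- as.vector(outer(c(ic, ic + 1L), c(jc, jc + 1L), function(i, j)
      i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]))
    list(station = stations$station[s], z_m = stations$z_m[s], plane_k = k,
         section = sec_lin, radial = radial_lin, centerline = ctr)
  })
  names(out) <- stations$station
  out
}

#' Read a triangulated surface in STL format
#'
#' Supports both ASCII and binary STL.  Provided for parity with runs on
#' the distributed benchmark surface; the primary path is the analytic
#' parametric geometry.
#'
#' @param path file path.
#' @return matrix with 9 columns (v1,v2,v3 coordinates), one row per facet.
#' @export
read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 80L)
  txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  con <- file(path, "rb"); on.exit(close(con))
  if (grepl("^\\s*solid", txt)) {
    ## might still be binary with a header starting "solid": check size
    seek(con, 80L); ntri <- readBin(con, "integer", 1L, size = 4L)
    sz <- file.info(path)$size
    if (!is.na(ntri) && sz == 84 + 50 * ntri) {
      return(read_stl_binary(con, ntri))
    }
    lines <- readLines(path, warn = FALSE)
    vx <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- t(vapply(strsplit(trimws(vx), "\\s+"), function(p)
      as.numeric(p[2:4]), numeric(3)))
    if (nrow(nums) %% 3 != 0)
      nz_error("parse_error", "ASCII STL vertex count not a multiple of 3")
    return(matrix(t(nums), ncol = 9, byrow = TRUE))
  }
  seek(con, 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L)
  read_stl_binary(con, ntri)
}

read_stl_binary <- function(con, ntri) {
  out <- matrix(NA_real_, nrow = ntri, ncol = 9)
  for (t in seq_len(ntri)) {
    readBin(con, "numeric", 3L, size = 4L)           # normal
    out[t, ] <- readBin(con, "numeric", 9L, size = 4L)
    readBin(con, "raw", 2L)                           # attribute bytes
  }
  out
}

#' Voxelize a triangulated surface
#'
#' Classifies cell centers by parity of ray crossings along +z.  The grid
#' follows the same conventions as [voxelize()] (even transverse count,
#' axis-centered).  Intended for small desk-scale surfaces.
#'
#' @param tri facet matrix from [read_stl()].
#' @param dx grid spacing (same units as the surface).
#' @param pad cells of solid padding around the bounding box (default 1).
#' @return logical 3-D array: TRUE where the cell center is inside.
#' @export
voxelize_stl <- function(tri, dx, pad = 1L) {
  v1 <- tri[, 1:3]; v2 <- tri[, 4:6]; v3 <- tri[, 7:9]
  lo <- apply(rbind(v1, v2, v3), 2, min) - pad * dx
  hi <- apply(rbind(v1, v2, v3), 2, max) + pad * dx
  nn <- pmax(ceiling((hi - lo) / dx), 1)
  xs <- lo[1] + (seq_len(nn[1]) - 0.5) * dx
  ys <- lo[2] + (seq_len(nn[2]) - 0.5) * dx
  zs <- lo[3] + (seq_len(nn[3]) - 0.5) * dx
  inside <- array(FALSE, dim = nn)
  eps <- dx * 1e-4   # ray-origin jitter avoids edge-grazing degeneracies
  for (i in seq_along(xs)) {
    for (j in seq_along(ys)) {
      px <- xs[i] + eps; py <- ys[j] + eps * 0.5
      ## triangles whose xy-projection contains (px, py)
      zhits <- ray_z_hits(px, py, v1, v2, v3)
      if (!length(zhits)) next
      cnt <- vapply(zs, function(z) sum(zhits > z), integer(1))
      inside[i, j, ] <- cnt %% 2L == 1L
    }
  }
  inside
}

## z-coordinates where the vertical ray through (px, py) crosses facets.
ray_z_hits <- function(px, py, v1, v2, v3) {
  ## barycentric test in the xy-plane, vectorized over triangles
  x1 <- v1[, 1] - px; y1 <- v1[, 2] - py
  x2 <- v2[, 1] - px; y2 <- v2[, 2] - py
  x3 <- v3[, 1] - px; y3 <- v3[, 2] - py
  d1 <- x1 * y2 - x2 * y1
  d2 <- x2 * y3 - x3 * y2
  d3 <- x3 * y1 - x1 * y3
  hit <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
  hit <- hit & (abs(d1) + abs(d2) + abs(d3)) > 0
  if (!any(hit)) return(numeric(0))
  idx <- which(hit)
  s <- abs(d1[idx]) + abs(d2[idx]) + abs(d3[idx])
  w1 <- abs(d2[idx]) / s; w2 <- abs(d3[idx]) / s; w3 <- abs(d1[idx]) / s
  w1 * v1[idx, 3] + w2 * v2[idx, 3] + w3 * v3[idx, 3]
}

#' Export stations as CSV
#' @param stations data.frame from [nozzle_stations()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_stations_csv <- function(stations, path) {
  write.csv(stations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
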