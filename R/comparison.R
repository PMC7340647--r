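## Comparison observables and PIV-style reference data.
##
## The reference CSV dialect (also written by the synthetic generators):
## comment header lines starting with '#' carrying `experiment` and
## optional metadata, then columns
##   quantity, z_m, r_m, value
## with quantity one of "u_z" (m/s; r_m = NA on the centerline), "p"
## (Pa, section mean, r_m = NA) or "tau" (Pa).

#' Time-mean centerline axial-velocity profile
#'
#' Samples the mean axial velocity on the axis at `n_points` uniformly
#' spaced axial locations (the benchmark plots use 86 between the first
#' and last station; dense mode uses 120 points 0.002 m apart).  The
#' "axis" value is the average of the four cells nearest the axis (the
#' grid is cell-centered with the axis on a cell corner).
#'
#' @param dom an `lbm_domain` built from a voxelized geometry.
#' @param u 3 x n mean velocity matrix (lattice or physical units).
#' @param n_points number of axial samples (default 86).
#' @param zlim axial range (default: the domain's voxelized extent,
#'   shrunk by one cell at each end).
#' @return data.frame with `z_m` and `u_z`.
#' @export
centerline_profile <- function(dom, u, n_points = 86, zlim = NULL) {
  d <- dom$dim
  ic <- d[1] %/% 2L; jc <- d[2] %/% 2L
  ## centerline cells: the four columns around the axis, every z plane
  sel <- which(((dom$fluid_idx - 1L) %% d[1]) %in% c(ic - 1L, ic) &
                 (((dom$fluid_idx - 1L) %/% d[1]) %% d[2]) %in% c(jc - 1L, jc))
  if (!length(sel)) nz_error("range_error", "axis not inside the fluid")
  zc <- dom$centers[sel, 3]
  uz <- tapply(u[3, sel], zc, mean)
  zs <- as.numeric(names(uz))
  zlim <- zlim %||% (range(zs) + c(1, -1) * dom$dx)
  zq <- seq(zlim[1], zlim[2], length.out = n_points)
  data.frame(z_m = zq, u_z = approx(zs, as.numeric(uz), xout = zq)$y)
}

#' Radial profile at a station
#'
#' Mean axial velocity along a diameter of the station plane, optionally
#' normalized by a reference velocity (the mean throat velocity in the
#' benchmark plots).
#'
#' @param dom an `lbm_domain`.
#' @param u 3 x n velocity matrix (mean, or instantaneous for snapshot
#'   profiles).
#' @param station_z axial position of the station (m).
#' @param normalize optional reference velocity; output `u_norm` = u_z /
#'   normalize.
#' @return data.frame with `r_m`, `u_z` (input units) and optionally
#'   `u_norm`.
#' @export
radial_profile <- function(dom, u, station_z, normalize = NULL) {
  d <- dom$dim
  k <- round((station_z - dom$origin[3]) / dom$dx) + 1L
  if (k < 1L || k > d[3]) nz_error("range_error", "station outside domain")
  jc <- d[2] %/% 2L
  sel <- which((((dom$fluid_idx - 1L) %/% d[1]) %% d[2]) == (jc - 1L) &
                 ((dom$fluid_idx - 1L) %/% (d[1] * d[2])) == (k - 1L))
  if (!length(sel)) nz_error("station_in_solid", "station plane holds no fluid on the diameter")
  r <- dom$centers[sel, 1]
  ord <- order(r)
  out <- data.frame(r_m = r[ord], u_z = u[3, sel][ord])
  if (!is.null(normalize)) out$u_norm <- out$u_z / normalize
  out
}

#' Normalized pressure profile
#'
#' Delta p_norm(z) = (p_z - p_z0) / (0.5 rho u_throat^2): section-mean
#' gauge pressures referenced to station z0 and normalized by the throat
#' dynamic pressure.  By construction the profile is zero at z0 and
#' invariant to adding a constant to all pressures.
#'
#' @param p_z section-mean pressures (Pa), one per station.
#' @param z axial positions (m) of the sections.
#' @param z0 reference station (default: the first).
#' @param rho fluid density (kg/m^3).
#' @param u_throat mean throat velocity (m/s, > 0).
#' @return object of class `pressure_profile`: data.frame with `z_m`,
#'   `p_Pa`, `dp_norm` plus attributes `z0`, `q_dyn`.
#' @export
normalized_pressure <- function(p_z, z, z0 = z[1], rho, u_throat) {
  if (u_throat <= 0) nz_error("invalid_parameter", "u_throat must be > 0")
  i0 <- which.min(abs(z - z0))
  q <- 0.5 * rho * u_throat^2
  out <- data.frame(z_m = z, p_Pa = p_z, dp_norm = (p_z - p_z[i0]) / q)
  attr(out, "z0") <- z[i0]; attr(out, "q_dyn") <- q
  class(out) <- c("pressure_profile", "data.frame")
  out
}

#' Section-mean pressure from a run
#'
#' Area-weighted mean gauge pressure over all fluid cells of the lattice
#' plane nearest each requested station, p = cs^2 (rho - rho0) rescaled to
#' Pa via the flow case.
#'
#' @param dom an `lbm_domain`.
#' @param rho per-cell lattice density (e.g. `run$mean_rho`).
#' @param z stations (m).
#' @param case optional `flow_case` for rescaling to Pa (otherwise
#'   lattice pressure units).
#' @return numeric vector of section pressures.
#' @export
section_pressure <- function(dom, rho, z, case = NULL) {
  d <- dom$dim
  kcell <- (dom$fluid_idx - 1L) %/% (d[1] * d[2])
  scale <- if (!is.null(case))
    case$fluid$rho * (case$lattice$dx / case$lattice$dt)^2 else 1
  vapply(z, function(zq) {
    k <- round((zq - dom$origin[3]) / dom$dx)
    sel <- kcell == k
    if (!any(sel)) nz_error("range_error", sprintf("no fluid at z = %g", zq))
    mean((rho[sel] - dom$rho0) / 3) * scale
  }, numeric(1))
}

#' Mean-normalized shear-stress profile
#'
#' Divides a profile by its mean so that profiles from different sources
#' can be compared shape-to-shape; scale-invariant by construction.
#'
#' @param tau numeric profile (nonzero mean).
#' @return normalized profile with mean 1.
#' @export
normalized_shear <- function(tau) {
  m <- mean(tau)
  if (!is.finite(m) || m == 0)
    nz_error("zero_mean", "profile mean is zero; cannot normalize")
  tau / m
}

#' Relative percentage error
#'
#' delta = |(U_ref - U_h) / U_ref| * 100.
#'
#' @param u_ref reference value(s), nonzero.
#' @param u_h computed value(s).
#' @return percent error (>= 0), vectorized.
#' @export
relative_error <- function(u_ref, u_h) {
  if (any(u_ref == 0))
    nz_error("undefined_error", "relative error undefined for zero reference")
  abs((u_ref - u_h) / u_ref) * 100
}

#' Jet-breakdown location from centerline turbulent kinetic energy
#'
#' Operational detector: the first axial position at which the centerline
#' TKE exceeds `frac` of its downstream maximum.  Runs whose maximum TKE
#' stays at or below `floor` (laminar) report no breakdown.  The estimate
#' is reported with the pair of benchmark stations bracketing it.
#'
#' @param z axial positions (m), increasing.
#' @param k centerline TKE at those positions (velocity^2 units).
#' @param frac threshold fraction of the downstream maximum (default 0.1).
#' @param floor laminar floor on max TKE (same units as `k`; default 0).
#' @param stations station table for bracket reporting (default
#'   [nozzle_stations()]).
#' @return object of class `jet_breakdown`: list with `z_breakdown` (m or
#'   NA), `detected`, `bracket` (character(2) or NA) and the threshold
#'   used.
#' @export
jet_breakdown_location <- function(z, k, frac = 0.1, floor = 0,
                                   stations = nozzle_stations()) {
  ord <- order(z); z <- z[ord]; k <- k[ord]
  kmax <- max(k, na.rm = TRUE)
  if (!is.finite(kmax) || kmax <= floor) {
    return(structure(list(z_breakdown = NA_real_, detected = FALSE,
                          bracket = c(NA_character_, NA_character_),
                          frac = frac, floor = floor),
                     class = "jet_breakdown"))
  }
  thr <- frac * kmax
  idx <- which(k > thr)[1]
  zb <- z[idx]
  lo <- stations$station[max(which(stations$z_m <= zb), 0L)] %|0|% NA_character_
  hi <- stations$station[which(stations$z_m >= zb)[1]] %|0|% NA_character_
  structure(list(z_breakdown = zb, detected = TRUE, bracket = c(lo, hi),
                 frac = frac, floor = floor),
            class = "jet_breakdown")
}

`%|0|%` <- function(a, b) if (length(a) == 0L || is.na(a[1])) b else a[1]

#' @export
print.jet_breakdown <- function(x, ...) {
  if (!x$detected) cat("<jet_breakdown> none (laminar)\n")
  else cat(sprintf("<jet_breakdown> z = %.4g m (between %s and %s)\n",
                   x$z_breakdown, x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Read a PIV-style reference dataset
#'
#' Parses the package CSV dialect (see the module header): '#'-prefixed
#' metadata lines (`# experiment: 243`), then `quantity,z_m,r_m,value`
#' rows.  Pressure-less datasets (the benchmark's experiment #999) are
#' valid: the pressure component is simply NULL.
#'
#' @param path file path.
#' @return object of class `piv_dataset`: list with `experiment`, `meta`,
#'   `centerline` (z_m, u_z), `profiles` (z_m, r_m, u_z), `pressure`
#'   (z_m, p or NULL), `shear` (z_m, r_m, tau or NULL).
#' @export
read_piv_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  metaln <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in metaln) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl(":", kv)) {
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      meta[[key]] <- val
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- tryCatch(
    read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE),
    error = function(e) nz_error("parse_error", conditionMessage(e)))
  need <- c("quantity", "z_m", "r_m", "value")
  if (!all(need %in% names(df)))
    nz_error("parse_error",
             sprintf("missing columns: %s",
                     paste(setdiff(need, names(df)), collapse = ", ")))
  bad <- which(!df$quantity %in% c("u_z", "p", "tau"))
  if (length(bad))
    nz_error("parse_error",
             sprintf("unknown quantity '%s' at data row %d",
                     df$quantity[bad[1]], bad[1]))
  if (!is.numeric(df$z_m) || !is.numeric(df$value))
    nz_error("parse_error", "non-numeric z_m or value column")
  uz <- df[df$quantity == "u_z", ]
  ctr <- uz[is.na(uz$r_m), c("z_m", "value")]
  names(ctr) <- c("z_m", "u_z")
  prof <- uz[!is.na(uz$r_m), c("z_m", "r_m", "value")]
  names(prof) <- c("z_m", "r_m", "u_z")
  pr <- df[df$quantity == "p", c("z_m", "value")]
  names(pr) <- c("z_m", "p")
  sh <- df[df$quantity == "tau", c("z_m", "r_m", "value")]
  names(sh) <- c("z_m", "r_m", "tau")
  structure(list(
    experiment = meta$experiment %||% NA_character_,
    meta = meta,
    centerline = ctr[order(ctr$z_m), ],
    profiles = prof,
    pressure = if (nrow(pr)) pr[order(pr$z_m), ] else NULL,
    shear = if (nrow(sh)) sh else NULL
  ), class = "piv_dataset")
}

#' Write a PIV-style reference dataset
#'
#' Inverse of [read_piv_table()]; full-precision round trip.
#'
#' @param ds a `piv_dataset` (or a compatible list).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_piv_table <- function(ds, path) {
  rows <- list()
  if (!is.null(ds$centerline) && nrow(ds$centerline))
    rows$ctr <- data.frame(quantity = "u_z", z_m = ds$centerline$z_m,
                           r_m = NA_real_, value = ds$centerline$u_z)
  if (!is.null(ds$profiles) && nrow(ds$profiles))
    rows$prof <- data.frame(quantity = "u_z", z_m = ds$profiles$z_m,
                            r_m = ds$profiles$r_m, value = ds$profiles$u_z)
  if (!is.null(ds$pressure) && nrow(ds$pressure))
    rows$p <- data.frame(quantity = "p", z_m = ds$pressure$z_m,
                         r_m = NA_real_, value = ds$pressure$p)
  if (!is.null(ds$shear) && nrow(ds$shear))
    rows$tau <- data.frame(quantity = "tau", z_m = ds$shear$z_m,
                           r_m = ds$shear$r_m, value = ds$shear$tau)
  df <- do.call(rbind, rows)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# experiment: %s", ds$experiment %||% "NA"), con)
  for (key in setdiff(names(ds$meta %||% list()), "experiment"))
    writeLines(sprintf("# %s: %s", key, ds$meta[[key]]), con)
  writeLines("quantity,z_m,r_m,value", con)
  writeLines(sprintf("%s,%.17g,%s,%.17g", df$quantity, df$z_m,
                     ifelse(is.na(df$r_m), "NA", sprintf("%.17g", df$r_m)),
                     df$value), con)
  invisible(path)
}

#' Station-wise comparison against a reference dataset
#'
#' Interpolates the computed centerline profile to the reference stations
#' and tabulates the relative percentage errors; pressure rows are
#' included when the reference provides them.
#'
#' @param computed data.frame with `z_m`, `u_z` (e.g. from
#'   [centerline_profile()], physical units).
#' @param reference a `piv_dataset`.
#' @param pressure optional computed `pressure_profile` to compare when
#'   the reference carries pressure.
#' @return object of class `comparison_report`: data.frame with columns
#'   `quantity`, `z_m`, `reference`, `computed`, `delta_pct`.
#' @export
compare_with_reference <- function(computed, reference, pressure = NULL) {
  stopifnot(inherits(reference, "piv_dataset"))
  ref <- reference$centerline
  uh <- approx(computed$z_m, computed$u_z, xout = ref$z_m, rule = 1)$y
  ok <- !is.na(uh) & ref$u_z != 0
  out <- data.frame(quantity = "u_z", z_m = ref$z_m[ok],
                    reference = ref$u_z[ok], computed = uh[ok],
                    delta_pct = relative_error(ref$u_z[ok], uh[ok]))
  if (!is.null(reference$pressure) && !is.null(pressure)) {
    ph <- approx(pressure$z_m, pressure$p_Pa, xout = reference$pressure$z_m,
                 rule = 1)$y
    okp <- !is.na(ph) & reference$pressure$p != 0
    out <- rbind(out, data.frame(
      quantity = "p", z_m = reference$pressure$z_m[okp],
      reference = reference$pressure$p[okp], computed = ph[okp],
      delta_pct = relative_error(reference$pressure$p[okp], ph[okp])))
  }
  attr(out, "experiment") <- reference$experiment
  attr(out, "pressure_available") <- !is.null(reference$pressure)
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> vs experiment #%s (%d rows%s)\n",
              attr(x, "experiment"), nrow(x),
              if (attr(x, "pressure_available")) ", incl. pressure"
              else ", pressure absent"))
  print.data.frame(head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("  ...\n")
  cat(sprintf("  median delta = %.2f%%, max delta = %.2f%%\n",
              median(x$delta_pct), max(x$delta_pct)))
  invisible(x)
}
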