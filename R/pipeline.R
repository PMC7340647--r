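## Pipeline stages: mesh -> run -> characterize -> compare, each writing
## its artifacts plus a JSON manifest so that every stage can be re-run
## from the previous stage's on-disk outputs alone.

#' Build the solver domain for a nozzle case
#'
#' Voxelizes the (possibly truncated) nozzle, computes Bouzidi wall
#' distances and attaches the parabolic inflow at the case's lattice
#' inlet velocity.
#'
#' @param case a [build_case()] result.
#' @param geometry a `nozzle_geometry` (default [fda_nozzle()]).
#' @param zlim optional truncated axial extent (m).
#' @return an `lbm_domain`.
#' @export
nozzle_domain <- function(case, geometry = fda_nozzle(), zlim = NULL) {
  stopifnot(inherits(case, "flow_case"))
  if (!is.null(zlim)) geometry <- truncate_nozzle(geometry, zlim[1], zlim[2])
  field <- voxelize(geometry, case$lattice$dx)
  field <- wall_link_distances(field)
  build_domain(field,
               inlet_velocity = parabolic_inflow(case$lattice$u_lattice_inlet,
                                                 geometry$inlet_radius))
}

#' Write a field snapshot in legacy VTK format
#'
#' ASCII STRUCTURED_POINTS dataset with the density, velocity and any
#' extra scalar fields; readable by ParaView.
#'
#' @param dom an `lbm_domain`.
#' @param m macroscopic fields (list with `rho`, `u`).
#' @param path output file.
#' @param scalars optional named list of per-fluid-cell scalar vectors.
#' @return invisibly, the path.
#' @export
write_vtk <- function(dom, m, path, scalars = list()) {
  d <- dom$dim
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "nozzlelbm field snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", dom$origin[1], dom$origin[2],
                       dom$origin[3]),
               sprintf("SPACING %g %g %g", dom$dx, dom$dx, dom$dx),
               sprintf("POINT_DATA %d", prod(d))), con)
  emit_scalar <- function(name, vals) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(vals, digits = 9, trim = TRUE, scientific = TRUE), con)
  }
  emit_scalar("rho", as.vector(field_array(dom, m$rho, fill = 0)))
  writeLines("VECTORS velocity double", con)
  ua <- lapply(1:3, function(i) as.vector(field_array(dom, m$u[i, ], fill = 0)))
  writeLines(paste(format(ua[[1]], digits = 9, trim = TRUE),
                   format(ua[[2]], digits = 9, trim = TRUE),
                   format(ua[[3]], digits = 9, trim = TRUE)), con)
  for (nm in names(scalars))
    emit_scalar(nm, as.vector(field_array(dom, scalars[[nm]], fill = 0)))
  invisible(path)
}

## manifest helpers -----------------------------------------------------

manifest_path <- function(dir) file.path(dir, "manifest.json")

read_manifest <- function(dir) {
  p <- manifest_path(dir)
  if (!file.exists(p)) list() else jsonlite::read_json(p, simplifyVector = TRUE)
}

update_manifest <- function(dir, stage, entries) {
  mf <- read_manifest(dir)
  entries$files <- as.list(entries$files)
  if (length(entries$files)) {
    paths <- file.path(dir, unlist(entries$files))
    entries$checksums <- as.list(setNames(unname(tools::md5sum(paths)),
                                          unlist(entries$files)))
  }
  entries$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  entries$package_version <- as.character(utils::packageVersion("nozzlelbm"))
  mf[[stage]] <- entries
  jsonlite::write_json(mf, manifest_path(dir), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(mf)
}

#' Default desk-scale nozzle configuration
#'
#' The scaled-down study conditions: laminar throat Reynolds number 500 on
#' a truncated domain with 12 cells across the throat.  All entries can be
#' overridden; [nozzle_mesh()] and [nozzle_run()] accept the same list
#' read from a YAML file.
#'
#' @param ... overrides for the default entries.
#' @return named list.
#' @export
nozzle_config <- function(...) {
  cfg <- list(
    fluid = list(density_kg_m3 = 1056, dynamic_viscosity_Pa_s = 0.0035),
    case = list(re_throat = 500, dx_m = 0.004 / 12, omega = 1.985),
    domain = list(z_min = -0.072, z_max = 0.024),
    run = list(n_steps = 12000L, ramp_flow_throughs = 1,
               probe_every = 5L, sample_every = 10L,
               init = "laminar", outlet = "equilibrium"),
    seed = 1L
  )
  utils::modifyList(cfg, list(...))
}

#' Stage 1: mesh
#'
#' Voxelizes the configured geometry, computes wall distances and writes
#' the flag-field container, the station table and the manifest.
#'
#' @param config list as from [nozzle_config()] or
#'   `yaml::read_yaml(file)`.
#' @param dir output directory (created if needed).
#' @return the `lbm_domain`, invisibly; artifacts on disk.
#' @export
nozzle_mesh <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fl <- fluid_spec(config$fluid$density_kg_m3, config$fluid$dynamic_viscosity_Pa_s)
  case <- build_case(fl, config$case$re_throat, config$case$dx_m,
                     config$case$omega)
  zlim <- c(config$domain$z_min, config$domain$z_max)
  dom <- nozzle_domain(case, zlim = zlim)
  saveRDS(dom, file.path(dir, "domain.rds"))
  saveRDS(case, file.path(dir, "case.rds"))
  write_stations_csv(nozzle_stations(), file.path(dir, "stations.csv"))
  ## count across the throat for the log
  stats <- list(
    n_fluid = dom$n_fluid,
    cells_throat = case$lattice$cells_throat,
    dx_m = case$lattice$dx, dt_s = case$lattice$dt,
    omega = config$case$omega,
    u_lattice_throat = case$lattice$u_lattice,
    zlim = zlim
  )
  update_manifest(dir, "mesh", list(
    config = config, scaling = stats,
    files = c("domain.rds", "case.rds", "stations.csv")))
  message(sprintf("mesh: %d fluid cells, %d across throat, dx = %g m",
                  dom$n_fluid, stats$cells_throat, stats$dx_m))
  invisible(dom)
}

#' Stage 2: run
#'
#' Executes the time loop from the meshed artifacts: inflow ramp over the
#' configured number of flow-through times, centerline probes at the
#' configured cadence, running-mean fields over the final 80 percent of
#' the run, a final VTK snapshot and a probe CSV.
#'
#' @param dir stage directory holding the mesh artifacts.
#' @param n_steps override the configured step count.
#' @return the `lbm_run`, invisibly; artifacts on disk.
#' @export
nozzle_run <- function(dir, n_steps = NULL) {
  mf <- read_manifest(dir)
  if (is.null(mf$mesh)) nz_error("missing_stage", "run requires a meshed directory")
  config <- mf$mesh$config
  dom <- readRDS(file.path(dir, "domain.rds"))
  case <- readRDS(file.path(dir, "case.rds"))
  n_steps <- as.integer(n_steps %||% config$run$n_steps)
  init <- config$run$init %||% "rest"
  outlet_mode <- config$run$outlet %||% "pin"
  if (init == "laminar") {
    ## mass-conserving laminar ansatz, jet-preserving downstream of the
    ## expansion; consistent with the full-strength inflow, so no ramp
    u0 <- nozzle_laminar_guess(dom, case$lattice$u_lattice_inlet)
    g <- dom$geometry
    jet <- dom$centers[, 3] >= 0
    r2 <- dom$centers[jet, 1]^2 + dom$centers[jet, 2]^2
    u0[3, jet] <- 2 * case$lattice$u_lattice *
      pmax(0, 1 - r2 / g$throat_radius^2)
    f0 <- init_state(dom, rho = 1, u = u0)
    ramp <- 0L
  } else {
    f0 <- init_state(dom)
    ramp <- as.integer(config$run$ramp_flow_throughs * case$flow$T_ft /
                         case$lattice$dt)
    ramp <- min(ramp, max(1L, n_steps %/% 5L))
  }
  ## probes: centerline cells (4 nearest the axis) at every 4th plane
  d <- dom$dim; ic <- d[1] %/% 2L; jc <- d[2] %/% 2L
  i0 <- (dom$fluid_idx - 1L) %% d[1]
  j0 <- ((dom$fluid_idx - 1L) %/% d[1]) %% d[2]
  k0 <- (dom$fluid_idx - 1L) %/% (d[1] * d[2])
  ctr <- which(i0 %in% c(ic - 1L, ic) & j0 %in% c(jc - 1L, jc) &
                 k0 %% 4L == 0L)
  run <- lbm_run(dom, omega = case$lattice$omega, f0 = f0,
                 n_steps = n_steps, ramp_steps = ramp,
                 probe_cells = ctr, probe_every = config$run$probe_every,
                 sample_every = config$run$sample_every,
                 outlet_mode = outlet_mode)
  m <- list(rho = run$mean_rho, u = run$mean_u)
  write_vtk(dom, m, file.path(dir, "mean_fields.vtk"))
  ## probe CSV: t_s, x, y, z, rho, ux, uy, uz (physical units)
  cc <- dom$centers[ctr, , drop = FALSE]
  conv <- case$lattice$dx / case$lattice$dt
  pr <- do.call(rbind, lapply(seq_along(run$probe_t), function(s) {
    data.frame(t_s = run$probe_t[s] * case$lattice$dt,
               x = cc[, 1], y = cc[, 2], z = cc[, 3],
               rho = run$probes[s, , 1],
               ux = run$probes[s, , 2] * conv,
               uy = run$probes[s, , 3] * conv,
               uz = run$probes[s, , 4] * conv)
  }))
  write.csv(pr, file.path(dir, "probes.csv"), row.names = FALSE)
  saveRDS(run[c("mean_rho", "mean_u", "n_samples", "probe_t", "probes",
                "probe_cells", "n_steps", "ramp_steps")],
          file.path(dir, "run.rds"))
  update_manifest(dir, "run", list(
    n_steps = n_steps, ramp_steps = ramp,
    files = c("mean_fields.vtk", "probes.csv", "run.rds")))
  message(sprintf("run: %d steps (%.3g s physical), %d probe records",
                  n_steps, n_steps * case$lattice$dt, length(run$probe_t)))
  invisible(run)
}

#' Stage 3: characterize
#'
#' Computes centerline TKE, the jet-breakdown estimate, Welch spectra at
#' the post-expansion stations and the Kolmogorov/resolution-quality
#' report from the run artifacts.
#'
#' @param dir stage directory holding mesh + run artifacts.
#' @param laminar_floor TKE floor (fraction of u_throat^2) below which the
#'   run is reported laminar (default 1e-4).
#' @param window_fraction fraction of the probe records (taken from the
#'   end) entering the statistics (default 0.8, mirroring an 8-of-10
#'   averaging protocol; reduce when the development transient occupies
#'   more of a short run).
#' @param eta_m,tau_eta_s optional Kolmogorov length (m) and time (s) from
#'   an external estimate; when given, the l+/t+ resolution-quality ratios
#'   are added to the report.
#' @return list with `tke` (data.frame z, k), `breakdown`, `spectra`,
#'   `quality` (l+/t+ or NULL), invisibly; artifacts on disk.
#' @export
nozzle_characterize <- function(dir, laminar_floor = 1e-4,
                                window_fraction = 0.8,
                                eta_m = NULL, tau_eta_s = NULL) {
  mf <- read_manifest(dir)
  if (is.null(mf$run)) nz_error("missing_stage", "characterize requires a completed run")
  dom <- readRDS(file.path(dir, "domain.rds"))
  case <- readRDS(file.path(dir, "case.rds"))
  run <- readRDS(file.path(dir, "run.rds"))
  conv <- case$lattice$dx / case$lattice$dt
  nrec <- dim(run$probes)[1]
  win <- c(max(1L, as.integer(nrec * (1 - window_fraction)) + 1L), nrec)
  dec <- reynolds_decompose(run$probes[, , 2:4] * conv, window = win)
  kser <- tke(dec)
  zc <- dom$centers[run$probe_cells, 3]
  ## collapse the 4 near-axis cells per plane
  ktab <- tapply(kser, zc, mean)
  ktab_z <- as.numeric(names(ktab))
  u_th <- case$flow$u_mean_throat
  bd <- jet_breakdown_location(ktab_z, as.numeric(ktab),
                               floor = laminar_floor * u_th^2)
  fs <- 1 / (case$lattice$dt * diff(run$probe_t[1:2]))
  ## spectra at the stations inside the probed extent, downstream of z6
  st <- nozzle_stations()
  st <- st[st$z_m > 0 & st$z_m <= max(zc) & st$z_m >= min(zc), ]
  spectra <- lapply(seq_len(nrow(st)), function(s) {
    cell <- which.min(abs(zc - st$z_m[s]))
    sig <- rowSums(run$probes[win[1]:win[2], cell, 2:4, drop = FALSE]^2)
    welch_psd(0.5 * sig * conv^2, fs = fs, d = case$flow$d, u_mean = u_th)
  })
  names(spectra) <- st$station
  ## spectra CSV (one file, long format)
  spdf <- do.call(rbind, lapply(names(spectra), function(nm)
    data.frame(station = nm, st = spectra[[nm]]$st, f_Hz = spectra[[nm]]$f,
               psd = spectra[[nm]]$psd)))
  if (!is.null(spdf)) write.csv(spdf, file.path(dir, "spectra.csv"),
                                row.names = FALSE)
  quality <- NULL
  if (!is.null(eta_m) && !is.null(tau_eta_s))
    quality <- resolution_quality(case$lattice$dx, case$lattice$dt,
                                  eta_m, tau_eta_s)
  report <- list(
    breakdown = unclass(bd),
    laminar = !bd$detected,
    tke_max = max(ktab), u_throat = u_th,
    resolution = c(list(dx_m = case$lattice$dx, dt_s = case$lattice$dt),
                   quality)
  )
  jsonlite::write_json(report, file.path(dir, "characterization.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tkedf <- data.frame(z_m = ktab_z, k = as.numeric(ktab))
  write.csv(tkedf, file.path(dir, "tke_centerline.csv"), row.names = FALSE)
  update_manifest(dir, "characterize", list(
    laminar = !bd$detected,
    files = c("characterization.json", "tke_centerline.csv",
              if (!is.null(spdf)) "spectra.csv")))
  invisible(list(tke = tkedf, breakdown = bd, spectra = spectra,
                 quality = quality))
}

#' Stage 4: compare
#'
#' Extracts the centerline profile and section pressures from the run and
#' compares them against one or more PIV-style reference files.
#'
#' @param dir stage directory with mesh + run artifacts.
#' @param ref_paths character vector of reference CSV paths.
#' @return list of `comparison_report`s (one per reference), invisibly;
#'   `comparison.csv` on disk.
#' @export
nozzle_compare <- function(dir, ref_paths) {
  mf <- read_manifest(dir)
  if (is.null(mf$run)) nz_error("missing_stage", "compare requires a completed run")
  dom <- readRDS(file.path(dir, "domain.rds"))
  case <- readRDS(file.path(dir, "case.rds"))
  run <- readRDS(file.path(dir, "run.rds"))
  conv <- case$lattice$dx / case$lattice$dt
  ctr <- centerline_profile(dom, run$mean_u * conv)
  st <- nozzle_stations()
  st <- st[st$z_m >= dom$zlim[1] + dom$dx & st$z_m <= dom$zlim[2] - dom$dx, ]
  p <- section_pressure(dom, run$mean_rho, st$z_m, case)
  pp <- normalized_pressure(p, st$z_m, rho = case$fluid$rho,
                            u_throat = case$flow$u_mean_throat)
  reports <- lapply(ref_paths, function(pth) {
    ref <- read_piv_table(pth)
    compare_with_reference(ctr, ref, pressure = pp)
  })
  all <- do.call(rbind, lapply(seq_along(reports), function(i)
    cbind(experiment = attr(reports[[i]], "experiment"),
          as.data.frame(reports[[i]]))))
  write.csv(all, file.path(dir, "comparison.csv"), row.names = FALSE)
  update_manifest(dir, "compare", list(
    references = as.list(basename(ref_paths)),
    files = c("comparison.csv")))
  invisible(reports)
}
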