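## Synthetic inputs: analytic laminar profiles, PIV-like multi-laboratory
## datasets, band-limited random signals with prescribed spectral slope,
## and linear-shear fields with a prescribed strain invariant.  All
## generators are pure functions of their parameters and the seed.

#' Analytic Hagen-Poiseuille radial profile
#'
#' u(r) = 2 u_mean (1 - (r/R)^2) sampled at `n_r` radial positions.
#'
#' @param R pipe radius (m, > 0).
#' @param u_mean bulk velocity (m/s, > 0).
#' @param n_r number of radial samples from 0 to R (default 101).
#' @return data.frame with `r_m` and `u_z`.
#' @export
poiseuille_pipe <- function(R, u_mean, n_r = 101L) {
  if (R <= 0 || u_mean <= 0)
    nz_error("invalid_parameter", "R and u_mean must be > 0")
  r <- seq(0, R, length.out = n_r)
  data.frame(r_m = r, u_z = 2 * u_mean * (1 - (r / R)^2))
}

#' Synthetic multi-laboratory PIV datasets
#'
#' Emulates the benchmark's five PIV datasets from three laboratories:
#' each lab observes the truth scaled by a multiplicative lab-level offset
#' (1 + N(0, offset_sd)) plus pointwise additive Gaussian noise with
#' standard deviation `noise_sd` times the local signal scale.  Offsets
#' and noise are drawn reproducibly from `seed`.
#'
#' @param truth list with `centerline` (data.frame z_m, u_z) and
#'   optionally `profiles` (z_m, r_m, u_z) and `pressure` (z_m, p).
#' @param n_labs number of datasets (default 5).
#' @param noise_sd pointwise noise, fraction of the signal RMS (default
#'   0.03).
#' @param offset_sd lab offset spread, fraction (default 0.05).
#' @param seed integer seed.
#' @param ids experiment id labels (default benchmark-style ids).
#' @param drop_pressure_in id (or index) whose pressure block is omitted,
#'   mirroring the benchmark's dataset without pressure (default none).
#' @return list of `piv_dataset` objects.
#' @export
synthetic_piv <- function(truth, n_labs = 5L, noise_sd = 0.03,
                          offset_sd = 0.05, seed = 1L,
                          ids = c("243", "297", "763", "999", "999b")[seq_len(n_labs)],
                          drop_pressure_in = NULL) {
  if (noise_sd < 0 || offset_sd < 0)
    nz_error("invalid_parameter", "noise parameters must be >= 0")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  offs <- 1 + rnorm(n_labs, 0, offset_sd)
  lapply(seq_len(n_labs), function(i) {
    noisy <- function(x) {
      s <- noise_sd * stats::sd(x)
      if (!is.finite(s) || length(x) < 2L) s <- noise_sd * mean(abs(x))
      x * offs[i] + rnorm(length(x), 0, s)
    }
    ctr <- truth$centerline
    ctr$u_z <- noisy(ctr$u_z)
    prof <- truth$profiles
    if (!is.null(prof)) prof$u_z <- noisy(prof$u_z)
    pres <- truth$pressure
    if (!is.null(pres)) pres$p <- noisy(pres$p)
    if (!is.null(drop_pressure_in) &&
        (identical(ids[i], as.character(drop_pressure_in)) ||
         identical(i, as.integer(drop_pressure_in))))
      pres <- NULL
    structure(list(
      experiment = ids[i],
      meta = list(experiment = ids[i], seed = as.character(seed),
                  lab_offset = sprintf("%.6f", offs[i])),
      centerline = ctr, profiles = prof, pressure = pres, shear = truth$shear
    ), class = "piv_dataset")
  })
}

## save/restore .Random.seed so generators do not disturb the caller's stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Random signal with power-law spectrum in a band
#'
#' Random-phase Fourier synthesis: amplitudes proportional to f^(slope/2)
#' inside `band`, zero outside, inverse-transformed to a real stationary
#' series.  The Welch estimator applied to the output recovers `slope`
#' within its estimation error; used to verify the -5/3 inertial-range
#' diagnostics.
#'
#' @param slope power-law exponent of the PSD (e.g. -5/3).
#' @param band frequency band `c(f_lo, f_hi)` in Hz, inside (0, fs/2).
#' @param fs sampling rate (Hz).
#' @param n number of samples.
#' @param seed integer seed.
#' @param rms target root-mean-square of the series (default 1).
#' @return numeric series of length `n`.
#' @export
spectral_signal <- function(slope, band, fs, n, seed = 1L, rms = 1) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    nz_error("invalid_band", "band must satisfy 0 < f_lo < f_hi < fs/2")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  f <- (0:(n %/% 2)) * fs / n
  amp <- numeric(length(f))
  sel <- f >= band[1] & f <= band[2]
  amp[sel] <- f[sel]^(slope / 2)
  ph <- runif(length(f), 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  m <- length(f)                       # bins 0 .. floor(n/2)
  full <- complex(n)
  full[1:m] <- spec
  if (n %% 2 == 0) full[m] <- Re(full[m])   # Nyquist bin must be real
  kk <- 2:(if (n %% 2 == 0) m - 1 else m)   # Hermitian completion
  full[n - kk + 2] <- Conj(full[kk])
  x <- Re(fft(full, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Linear-shear fluctuation field with prescribed strain invariant
#'
#' Builds u'_x = k y (plus an optional rigid rotation, which the strain
#' operator must ignore) on a 3-D grid, with k chosen so that the strain
#' invariant S = 2 s'_ij s'_ij equals `S0` exactly: for the pure shear,
#' s'_xy = k/2 and S = k^2.
#'
#' @param S0 target invariant (>= 0).
#' @param shape grid dimensions (length 3).
#' @param dx grid spacing (default 1; S0 is in the corresponding units).
#' @param rotation optional rigid-rotation rate to superpose (default 0).
#' @return list with arrays `ux`, `uy`, `uz`, the shear rate `k` and `dx`.
#' @export
strain_fixture <- function(S0, shape = c(8, 8, 8), dx = 1, rotation = 0) {
  if (S0 < 0) nz_error("invalid_parameter", "S0 must be >= 0")
  k <- sqrt(S0)
  y <- (seq_len(shape[2]) - 1) * dx
  x <- (seq_len(shape[1]) - 1) * dx
  ux <- array(rep(k * y, each = shape[1]), dim = shape)
  uy <- array(0, dim = shape)
  uz <- array(0, dim = shape)
  if (rotation != 0) {
    ## rigid rotation about z: u += omega x r
    ux <- ux - rotation * array(rep(y, each = shape[1]), dim = shape)
    uy <- uy + rotation * array(rep(x, times = shape[2] * shape[3]), dim = shape)
  }
  list(ux = ux, uy = uy, uz = uz, k = k, dx = dx)
}
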