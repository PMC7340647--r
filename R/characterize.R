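## Turbulence statistics: Reynolds decomposition, turbulent kinetic
## energy, Welch spectra on a Strouhal axis, fluctuating strain and the
## Kolmogorov microscales with the l+/t+ resolution-quality ratios.

#' Reynolds decomposition of a velocity time series
#'
#' u(x, t) = ubar(x) + u'(x, t) with ubar the arithmetic time mean over
#' the analysis window.  By construction the fluctuations average to zero.
#'
#' @param series numeric vector, matrix (time x components) or array
#'   (time x points x components) of velocity samples.
#' @param window optional integer range `c(first, last)` of samples to
#'   analyze (default: all).
#' @return object of class `reynolds_stats`: list with `mean`
#'   (per point/component), `fluct` (same shape as the windowed input) and
#'   the window actually used.
#' @export
reynolds_decompose <- function(series, window = NULL) {
  a <- as.array(series)
  if (length(dim(a)) == 1L) a <- array(a, dim = c(length(a), 1L, 1L))
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a)[1], 1L, dim(a)[2]))
  window <- window %||% c(1L, dim(a)[1])
  if (diff(window) < 1L) nz_error("empty_window", "need >= 2 samples in window")
  a <- a[window[1]:window[2], , , drop = FALSE]
  mn <- apply(a, c(2, 3), mean)
  fl <- sweep(a, c(2, 3), mn, "-")
  structure(list(mean = mn, fluct = fl, window = window),
            class = "reynolds_stats")
}

#' Turbulent kinetic energy
#'
#' k = (1/2) (mean(u'_x^2) + mean(u'_y^2) + mean(u'_z^2)) per point: half
#' the trace of the velocity covariance.
#'
#' @param stats a `reynolds_stats` (fluctuations with the component axis
#'   last), or an array/matrix of fluctuations directly.
#' @return numeric vector of k, one value per point (velocity^2 units).
#' @export
tke <- function(stats) {
  fl <- if (inherits(stats, "reynolds_stats")) stats$fluct else as.array(stats)
  if (length(dim(fl)) == 2L) fl <- array(fl, dim = c(dim(fl)[1], 1L, dim(fl)[2]))
  0.5 * apply(fl^2, 2, function(m) sum(colMeans(as.matrix(m))))
}

#' Strouhal number
#'
#' St = f d / u, the dimensionless frequency based on the throat diameter
#' and mean throat velocity.
#'
#' @param f frequency in Hz.
#' @param d characteristic length in m.
#' @param u_mean mean velocity in m/s (> 0).
#' @return dimensionless Strouhal number.
#' @export
strouhal <- function(f, d, u_mean) {
  if (any(u_mean <= 0)) nz_error("invalid_parameter", "u_mean must be > 0")
  f * d / u_mean
}

#' Welch power spectral density
#'
#' Averaged modified periodogram (Hann window by default, 50 percent
#' overlap, 8 segments) with one-sided density scaling, so that
#' `sum(psd) * df` approximates the signal variance (Parseval).  If `d`
#' and `u_mean` are given the abscissa is also returned as a Strouhal
#' number.
#'
#' @param x numeric time series.
#' @param fs sampling rate in Hz.
#' @param n_segments number of (overlapping) segments (default 8).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @param window "hann" or "rectangular".
#' @param demean subtract the series mean first (default TRUE).
#' @param d,u_mean optional length/velocity for the Strouhal axis.
#' @return object of class `spectrum_result`: data.frame-like list with
#'   `f` (Hz), `psd`, optionally `st`, plus segmentation metadata
#'   (`n_segments`, `segment_length`, `overlap`, `window`, `fs`).
#' @export
welch_psd <- function(x, fs, n_segments = 8L, overlap = 0.5,
                      window = c("hann", "rectangular"), demean = TRUE,
                      d = NULL, u_mean = NULL) {
  window <- match.arg(window)
  n <- length(x)
  ## segment length L with hop h = L (1 - overlap): n = L + (k-1) h
  L <- floor(n / (1 + (n_segments - 1) * (1 - overlap)))
  if (L < 8L) nz_error("series_too_short",
                       "series shorter than one usable segment")
  h <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = h)
  if (demean) x <- x - mean(x)
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
       else rep(1, L)
  U <- sum(w^2)                     # window power normalization
  nf <- L %/% 2L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    X <- fft(seg)
    p <- Mod(X[2:(nf + 1L)])^2
    acc <- acc + p
  }
  psd <- 2 * acc / (length(starts) * fs * U)
  ## Nyquist bin (even L) should not be doubled
  if (L %% 2L == 0L) psd[nf] <- psd[nf] / 2
  f <- (1:nf) * fs / L
  out <- list(f = f, psd = psd,
              n_segments = length(starts), segment_length = L,
              overlap = overlap, window = window, fs = fs)
  if (!is.null(d) && !is.null(u_mean)) out$st <- strouhal(f, d, u_mean)
  structure(out, class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> %d bins to %.4g Hz (%d x %d-sample %s segments, %.0f%% overlap)\n",
              length(x$f), max(x$f), x$n_segments, x$segment_length,
              x$window, 100 * x$overlap))
  invisible(x)
}

#' Fit a log-log spectral slope
#'
#' Least-squares slope of log10(PSD) vs log10(f) over a frequency band;
#' used to check the inertial-subrange decay against the Kolmogorov -5/3
#' law.
#'
#' @param spec a `spectrum_result`.
#' @param band frequency band `c(f_lo, f_hi)` in Hz.
#' @return fitted slope (dimensionless).
#' @export
spectral_slope <- function(spec, band) {
  sel <- spec$f >= band[1] & spec$f <= band[2] & spec$psd > 0
  if (sum(sel) < 3L) nz_error("invalid_parameter", "band holds < 3 PSD bins")
  unname(coef(lm(log10(spec$psd[sel]) ~ log10(spec$f[sel])))[2])
}

#' Fluctuating rate-of-strain tensor
#'
#' s'_ij = (u'_i,j + u'_j,i) / 2 by second-order central differences
#' (one-sided at walls), and the scalar invariant S = 2 s'_ij s'_ij.
#' Inputs are fluctuation velocity components on the grid, already
#' nondimensionalized by the reference velocity and length if
#' nondimensional scales are wanted downstream.
#'
#' @param ux,uy,uz 3-D arrays of a fluctuation velocity field (NA outside
#'   fluid).
#' @param dx grid spacing (same length unit as the nondimensionalization).
#' @return list with the six tensor arrays (`xx`, `yy`, `zz`, `xy`, `yz`,
#'   `xz`) and the invariant array `S` (= 2 s'_ij s'_ij, >= 0).
#' @export
fluctuating_strain <- function(ux, uy, uz, dx) {
  gxx <- deriv3d(ux, 1, dx); gxy <- deriv3d(ux, 2, dx); gxz <- deriv3d(ux, 3, dx)
  gyx <- deriv3d(uy, 1, dx); gyy <- deriv3d(uy, 2, dx); gyz <- deriv3d(uy, 3, dx)
  gzx <- deriv3d(uz, 1, dx); gzy <- deriv3d(uz, 2, dx); gzz <- deriv3d(uz, 3, dx)
  sxy <- (gxy + gyx) / 2; syz <- (gyz + gzy) / 2; sxz <- (gxz + gzx) / 2
  S <- 2 * (gxx^2 + gyy^2 + gzz^2 + 2 * (sxy^2 + syz^2 + sxz^2))
  list(xx = gxx, yy = gyy, zz = gzz, xy = sxy, yz = syz, xz = sxz, S = S)
}

#' Kolmogorov microscales from the mean strain invariant
#'
#' In nondimensional form (velocities by u_ref, lengths by d):
#' eta = (1 / (Re^2 S))^(1/4), tau_eta = S^(-1/2),
#' u_eta = (S / Re^2)^(1/4), where S is the time-averaged fluctuating
#' strain invariant 2 s'_ij s'_ij.  The identities eta u_eta Re = 1 and
#' tau_eta = eta / u_eta hold by construction.  Dimensional forms follow
#' the package convention eta_dim = eta d, tau_dim = tau_eta d / u_ref,
#' u_dim = u_eta u_ref.
#'
#' @param S_mean time- and band-averaged nondimensional strain invariant
#'   (> 0).
#' @param re Reynolds number (> 0).
#' @param d,u_ref optional reference length (m) and velocity (m/s) for the
#'   dimensional forms.
#' @return object of class `kolmogorov_scales`: `eta`, `tau_eta`, `u_eta`
#'   (nondimensional) and, when references are given, `eta_m`, `tau_eta_s`,
#'   `u_eta_m_s`.
#' @export
kolmogorov_scales <- function(S_mean, re, d = NULL, u_ref = NULL) {
  if (!is.finite(S_mean) || S_mean <= 0)
    nz_error("undefined_scales", "strain invariant must be > 0")
  if (re <= 0) nz_error("invalid_parameter", "re must be > 0")
  eta <- (1 / (re^2 * S_mean))^0.25
  tau <- S_mean^-0.5
  ue <- (S_mean / re^2)^0.25
  out <- list(eta = eta, tau_eta = tau, u_eta = ue, S_mean = S_mean, re = re)
  if (!is.null(d) && !is.null(u_ref)) {
    out$eta_m <- eta * d
    out$tau_eta_s <- tau * d / u_ref
    out$u_eta_m_s <- ue * u_ref
  }
  structure(out, class = "kolmogorov_scales")
}

#' @export
print.kolmogorov_scales <- function(x, ...) {
  cat(sprintf("<kolmogorov_scales> eta = %.4g, tau_eta = %.4g, u_eta = %.4g (nondim; Re = %g)\n",
              x$eta, x$tau_eta, x$u_eta, x$re))
  if (!is.null(x$eta_m))
    cat(sprintf("  dimensional: eta = %.4g um, tau_eta = %.4g us, u_eta = %.4g m/s\n",
                1e6 * x$eta_m, 1e6 * x$tau_eta_s, x$u_eta_m_s))
  invisible(x)
}

#' Average the strain invariant over the jet-breakdown station band
#'
#' Spatial average of S over centerline cells between two stations
#' (defaults z8 and z12, the band of largest TKE variation downstream of
#' the expansion), then time average.
#'
#' @param S_series matrix (time x cells) or vector of strain invariants on
#'   centerline cells.
#' @param z axial position of each centerline cell (m).
#' @param z_band stations bounding the band (default c(0.016, 0.08), i.e.
#'   z8..z12).
#' @return scalar mean invariant.
#' @export
average_strain_over_stations <- function(S_series, z,
                                         z_band = c(0.016, 0.08)) {
  S_series <- rbind(S_series)
  sel <- z >= min(z_band) & z <= max(z_band)
  if (!any(sel)) nz_error("empty_band", "no centerline cells in the station band")
  mean(colMeans(S_series[, sel, drop = FALSE]), na.rm = TRUE)
}

#' Resolution-quality ratios l+ and t+
#'
#' l+ = dx / eta and t+ = dt / tau_eta: grid spacing and time step
#' relative to the Kolmogorov length and time.  Values near or below one
#' indicate resolution at the smallest dynamically active scales.
#'
#' @param dx grid spacing (m).
#' @param dt time step (s).
#' @param eta Kolmogorov length (m) or a `kolmogorov_scales` with
#'   dimensional fields.
#' @param tau_eta Kolmogorov time (s); ignored when `eta` is a
#'   `kolmogorov_scales`.
#' @return list with `l_plus` and `t_plus`.
#' @export
resolution_quality <- function(dx, dt, eta, tau_eta = NULL) {
  if (inherits(eta, "kolmogorov_scales")) {
    tau_eta <- eta$tau_eta_s
    eta <- eta$eta_m
  }
  if (any(c(dx, dt, eta, tau_eta) <= 0))
    nz_error("invalid_parameter", "all inputs must be > 0")
  list(l_plus = dx / eta, t_plus = dt / tau_eta)
}
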