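# Reynolds decomposition, TKE, spectra, strain and Kolmogorov scales.

test_that("Reynolds decomposition removes the mean exactly", {
  ## constant series: zero fluctuations
  d0 <- reynolds_decompose(rep(3.2, 50))
  expect_equal(as.numeric(d0$mean), 3.2)
  expect_true(all(d0$fluct == 0))
  ## pure sinusoid over integer periods: zero mean, fluctuation = input
  t <- seq(0, 1, length.out = 401)[-401]
  x <- sin(2 * pi * 4 * t)
  d1 <- reynolds_decompose(x)
  expect_lt(abs(d1$mean), 1e-12)
  expect_equal(as.numeric(d1$fluct), x, tolerance = 1e-12)
  ## variance is preserved by mean removal
  set.seed(8)
  y <- cumsum(rnorm(300))
  d2 <- reynolds_decompose(y)
  expect_equal(var(as.numeric(d2$fluct)), var(y))
  expect_error(reynolds_decompose(1, window = c(1, 1)), class = "empty_window")
})

test_that("TKE is half the sum of fluctuation variances", {
  ## constant-magnitude fluctuation (1,1,1) -> k = 1.5
  fl <- array(1, dim = c(10, 1, 3))
  expect_equal(unname(tke(fl)), 1.5)
  ## sinusoidal x-fluctuation of amplitude A -> A^2/4 over long windows
  A <- 0.7
  t <- seq(0, 50, length.out = 20001)[-20001]
  arr <- array(0, dim = c(length(t), 1, 3))
  arr[, 1, 1] <- A * sin(2 * pi * t)
  expect_equal(unname(tke(arr)), A^2 / 4, tolerance = 0.01)
  ## identity with half the covariance trace on random data
  set.seed(12)
  u <- matrix(rnorm(3 * 500), ncol = 3)
  dec <- reynolds_decompose(array(u, dim = c(500, 1, 3)))
  k1 <- unname(tke(dec))
  cv <- stats::cov(u) * (499 / 500)          # population covariance
  expect_equal(k1, sum(diag(cv)) / 2, tolerance = 1e-12)
})

test_that("Strouhal numbers match the worked example", {
  expect_equal(strouhal(0, 0.004, 1), 0)
  expect_equal(strouhal(250, 0.004, 1), 1)
  ## f = 414.3 Hz at the Re 2000 throat velocity: St ~ 1
  u2000 <- 2000 * blood$nu / 0.004
  expect_equal(strouhal(414.3, 0.004, u2000), 1.0, tolerance = 1e-3)
  expect_error(strouhal(1, 1, 0), class = "invalid_parameter")
})

test_that("Welch PSD satisfies Parseval and localizes a sinusoid", {
  set.seed(77)
  n <- 4e5
  x <- rnorm(n, sd = 2)
  sp <- welch_psd(x, fs = 1000)
  expect_true(all(sp$psd >= 0))
  df <- sp$f[2] - sp$f[1]
  expect_equal(sum(sp$psd) * df, var(x), tolerance = 0.02)
  ## spectral peak at the sinusoid frequency within one bin
  t <- (0:(2^15 - 1)) / 1000
  y <- sin(2 * pi * 37 * t) + 0.01 * rnorm(length(t))
  spy <- welch_psd(y, fs = 1000, d = 0.004, u_mean = 1.657)
  fpk <- spy$f[which.max(spy$psd)]
  expect_lt(abs(fpk - 37), spy$f[2] - spy$f[1] + 1e-9)
  ## Strouhal axis is f d / u
  expect_equal(spy$st, spy$f * 0.004 / 1.657)
  expect_error(welch_psd(rnorm(10), fs = 1, n_segments = 8),
               class = "series_too_short")
})

test_that("a synthetic -5/3 signal is recovered by the Welch slope fit", {
  x <- spectral_signal(-5 / 3, band = c(5, 200), fs = 1000, n = 2^17,
                       seed = 42)
  sp <- welch_psd(x, fs = 1000)
  sl <- spectral_slope(sp, band = c(10, 100))
  expect_equal(sl, -5 / 3, tolerance = 0.2 / (5 / 3))
  ## white band is flat
  xw <- spectral_signal(0, band = c(5, 200), fs = 1000, n = 2^17, seed = 43)
  slw <- spectral_slope(welch_psd(xw, fs = 1000), band = c(10, 100))
  expect_lt(abs(slw), 0.1)
})

test_that("fluctuating strain matches linear-field closed forms and a brute-force oracle", {
  ## uniform field: zero strain
  u0 <- strain_fixture(0, shape = c(6, 6, 6))
  s0 <- fluctuating_strain(u0$ux, u0$uy, u0$uz, dx = 1)
  expect_lt(max(abs(s0$S)), 1e-24)
  ## pure shear u_x = k y: s_xy = k/2, S = k^2
  fx <- strain_fixture(S0 = 0.49, shape = c(7, 7, 7))
  s1 <- fluctuating_strain(fx$ux, fx$uy, fx$uz, dx = 1)
  expect_equal(max(abs(s1$xy - fx$k / 2)), 0, tolerance = 1e-12)
  expect_equal(mean(s1$S), 0.49, tolerance = 1e-12)
  ## rigid rotation leaves the invariant unchanged
  fr <- strain_fixture(S0 = 0.49, shape = c(7, 7, 7), rotation = 0.3)
  sr <- fluctuating_strain(fr$ux, fr$uy, fr$uz, dx = 1)
  expect_equal(mean(sr$S), 0.49, tolerance = 1e-12)
  ## smooth random field vs dense finite-difference oracle at interior points
  set.seed(9)
  nx <- 9
  xs <- seq_len(nx)
  fxy <- function(x, y, z) sin(0.3 * x) * cos(0.2 * y) + 0.1 * z
  ux <- outer(xs, xs, function(x, y) sin(0.3 * x) * cos(0.2 * y))
  ux <- array(rep(ux, nx), dim = rep(nx, 3))
  uz <- array(0, dim = rep(nx, 3)); uy <- uz
  s2 <- fluctuating_strain(ux, uy, uz, dx = 1)
  ## central-difference oracle computed independently at one interior point
  i <- 5; j <- 4; k <- 3
  oxy <- ((ux[i, j + 1, k] - ux[i, j - 1, k]) / 2 + 0) / 2
  expect_equal(s2$xy[i, j, k], oxy, tolerance = 1e-12)
})

test_that("Kolmogorov scales satisfy their algebraic identities", {
  expect_equal(unclass(kolmogorov_scales(1, 1))[c("eta", "tau_eta", "u_eta")],
               list(eta = 1, tau_eta = 1, u_eta = 1))
  set.seed(14)
  for (i in 1:20) {
    S <- runif(1, 1e-4, 1e3)
    re <- runif(1, 10, 5000)
    ks <- kolmogorov_scales(S, re)
    expect_equal(ks$eta * ks$u_eta * re, 1, tolerance = 1e-12)
    expect_equal(ks$tau_eta, ks$eta / ks$u_eta, tolerance = 1e-12)
  }
  expect_error(kolmogorov_scales(0, 100), class = "undefined_scales")
})

test_that("the strain -> scales chain recovers a prescribed invariant", {
  S0 <- 0.0625
  re <- 2000
  fx <- strain_fixture(S0, shape = c(8, 8, 8))
  s <- fluctuating_strain(fx$ux, fx$uy, fx$uz, dx = fx$dx)
  Sbar <- mean(s$S)
  ks <- kolmogorov_scales(Sbar, re)
  expect_equal(ks$eta, (re^2 * S0)^-0.25, tolerance = 1e-6)
  expect_equal(ks$tau_eta, S0^-0.5, tolerance = 1e-6)
  expect_equal(ks$u_eta, (S0 / re^2)^0.25, tolerance = 1e-6)
})

test_that("station-band strain averaging behaves like a quadrature", {
  z <- seq(0, 0.1, by = 0.002)
  ## uniform S: same value back
  expect_equal(average_strain_over_stations(rep(2.5, length(z)), z), 2.5)
  ## S supported outside the band only: zero
  Sout <- ifelse(z < 0.016 | z > 0.08, 7, 0)
  expect_equal(average_strain_over_stations(Sout, z), 0)
  ## linear profile: mean of band endpoints within discretization tolerance
  Slin <- 3 + 40 * z
  got <- average_strain_over_stations(Slin, z)
  expect_equal(got, 3 + 40 * (0.016 + 0.08) / 2, tolerance = 1e-3)
  expect_error(average_strain_over_stations(Slin, z, z_band = c(1, 2)),
               class = "empty_band")
})

test_that("resolution-quality ratios reproduce the tabulated rows", {
  ## NR row at Re 2000: dx = 80 um, dt = 16 us, eta = 4.94 um,
  ## tau_eta = 8.37 us
  q_nr <- resolution_quality(80e-6, 16e-6, 4.94e-6, 8.37e-6)
  expect_equal(q_nr$l_plus, 16.19, tolerance = 1e-3)
  expect_equal(q_nr$t_plus, 1.91, tolerance = 1e-2)
  ## HR row at Re 2000: 40 um / 4 us against 16.32 um / 8.69 us
  q_hr <- resolution_quality(40e-6, 4e-6, 16.32e-6, 8.69e-6)
  expect_equal(q_hr$l_plus, 2.45, tolerance = 1e-3)
  expect_equal(q_hr$t_plus, 0.46, tolerance = 1e-2)
  ## dx = eta -> l+ = 1
  expect_equal(resolution_quality(1e-5, 1e-6, 1e-5, 1e-6),
               list(l_plus = 1, t_plus = 1))
})
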