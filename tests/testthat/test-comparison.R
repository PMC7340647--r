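# Comparison observables and PIV-style reference handling.

test_that("relative percentage error matches its definition and scale invariance", {
  expect_equal(relative_error(1, 1), 0)
  expect_equal(relative_error(1.0, 0.9), 10)
  expect_equal(relative_error(2.0, 2.5), 25)
  expect_error(relative_error(0, 1), class = "undefined_error")
  set.seed(2)
  for (i in 1:10) {
    u <- runif(2, -5, 5); cc <- runif(1, 0.1, 10)
    if (u[1] == 0) next
    expect_equal(relative_error(cc * u[1], cc * u[2]),
                 relative_error(u[1], u[2]))
  }
})

test_that("normalized pressure is anchored, normalized and shift-invariant", {
  z <- c(-0.088, -0.02, 0, 0.08)
  p <- c(100, 50, -200, -100)
  pp <- normalized_pressure(p, z, rho = 1056, u_throat = 1.657)
  expect_equal(pp$dp_norm[1], 0)
  ## a step of half the dynamic pressure normalizes to 1
  u2000 <- 2000 * blood$nu / 0.004
  q <- 0.5 * 1056 * u2000^2
  expect_equal(q, 1449.3, tolerance = 1e-3)
  pp2 <- normalized_pressure(c(0, q), c(0, 1), rho = 1056, u_throat = u2000)
  expect_equal(pp2$dp_norm[2], 1, tolerance = 1e-3)
  ## adding a constant changes nothing
  pp3 <- normalized_pressure(p + 77, z, rho = 1056, u_throat = 1.657)
  expect_equal(pp3$dp_norm, pp$dp_norm)
  expect_error(normalized_pressure(p, z, rho = 1, u_throat = 0),
               class = "invalid_parameter")
})

test_that("mean-normalized shear profiles are scale-free with unit mean", {
  expect_equal(normalized_shear(rep(4, 7)), rep(1, 7))
  x <- c(0.5, 1, 2, 4)
  expect_equal(normalized_shear(3 * x), normalized_shear(x))
  expect_equal(mean(normalized_shear(x)), 1)
  expect_error(normalized_shear(c(-1, 1)), class = "zero_mean")
  ## Poiseuille stress is linear in r: normalized shape 2r/R (by |r|)
  r <- seq(0.05, 1, by = 0.05)
  tau <- 7 * r                         # arbitrary scale
  expect_equal(normalized_shear(tau), r / mean(r), tolerance = 1e-12)
})

test_that("jet breakdown detection is threshold-monotone and bracketed", {
  st <- nozzle_stations()
  z <- seq(0, 0.09, by = 0.002)
  ## flat near-zero TKE: laminar, no breakdown
  lam <- jet_breakdown_location(z, rep(1e-9, length(z)), floor = 1e-6)
  expect_false(lam$detected)
  ## synthetic step at z* = 0.026: estimate within one station spacing
  kstep <- ifelse(z >= 0.026, 1, 1e-5)
  bd <- jet_breakdown_location(z, kstep)
  expect_true(bd$detected)
  expect_lt(abs(bd$z_breakdown - 0.026), 0.008)
  expect_equal(bd$bracket, c("z9", "z10"))
  ## profile peaking between z9 and z10 reports that bracket
  kp <- exp(-((z - 0.028) / 0.004)^2)
  bd2 <- jet_breakdown_location(z, kp, frac = 0.5)
  expect_true(all(bd2$bracket %in% c("z8", "z9", "z10")))
  ## monotonicity: a larger threshold never moves the estimate upstream
  zb <- vapply(c(0.05, 0.1, 0.3, 0.6, 0.9),
               function(fr) jet_breakdown_location(z, kstep, frac = fr)$z_breakdown,
               numeric(1))
  expect_true(all(diff(zb) >= 0))
})

test_that("PIV tables round-trip losslessly and tolerate missing pressure", {
  st <- nozzle_stations()
  truth <- list(
    centerline = data.frame(z_m = st$z_m, u_z = 1 + sin(st$z_m * 30)),
    profiles = data.frame(z_m = rep(0.008, 11),
                          r_m = seq(-0.005, 0.005, by = 0.001),
                          u_z = runif(11)),
    pressure = data.frame(z_m = st$z_m, p = cumsum(rnorm(12)))
  )
  ds <- synthetic_piv(truth, n_labs = 1, noise_sd = 0, offset_sd = 0,
                      seed = 5)[[1]]
  tmp <- tempfile(fileext = ".csv"); on.exit(unlink(tmp), add = TRUE)
  write_piv_table(ds, tmp)
  back <- read_piv_table(tmp)
  expect_equal(back$centerline$u_z, ds$centerline$u_z, tolerance = 1e-15)
  expect_equal(back$profiles$u_z, ds$profiles$u_z, tolerance = 1e-15)
  expect_equal(back$pressure$p, ds$pressure$p, tolerance = 1e-15)
  expect_equal(back$experiment, ds$experiment)
  expect_equal(nrow(back$centerline), 12)
  ## dataset without a pressure block parses with pressure NULL
  ds2 <- ds; ds2$pressure <- NULL
  tmp2 <- tempfile(fileext = ".csv"); on.exit(unlink(tmp2), add = TRUE)
  write_piv_table(ds2, tmp2)
  back2 <- read_piv_table(tmp2)
  expect_null(back2$pressure)
  expect_equal(back2$centerline$u_z, ds$centerline$u_z, tolerance = 1e-15)
  ## malformed rows raise a parse error
  writeLines(c("# experiment: x", "quantity,z_m,r_m,value",
               "warp,0,NA,1"), tmp2)
  expect_error(read_piv_table(tmp2), class = "parse_error")
})

test_that("comparison against a zero-noise synthetic reference isolates solver error", {
  st <- nozzle_stations()
  computed <- data.frame(z_m = seq(-0.1, 0.1, by = 0.001))
  computed$u_z <- 2 + cos(computed$z_m * 20)
  truth <- list(centerline = data.frame(
    z_m = st$z_m, u_z = 2 + cos(st$z_m * 20)))
  ds <- synthetic_piv(truth, n_labs = 1, noise_sd = 0, offset_sd = 0)[[1]]
  rep0 <- compare_with_reference(computed, ds)
  expect_true(all(rep0$delta_pct < 1e-10))
  ## against an offset lab, the error equals the offset
  ds2 <- ds
  ds2$centerline$u_z <- ds$centerline$u_z * 1.07
  rep2 <- compare_with_reference(computed, ds2)
  expect_equal(unique(round(rep2$delta_pct, 6)), round(100 * 0.07 / 1.07, 6))
})
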