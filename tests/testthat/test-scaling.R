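# Diffusive-scaling translation between physical and lattice units.

test_that("Reynolds number arithmetic matches the benchmark worked examples", {
  expect_equal(compute_reynolds(0, 0.004, 3.314e-6), 0)
  ## u for Re 2000 at the benchmark fluid and throat: ~1.657 m/s
  u2000 <- 2000 * blood$nu / 0.004
  expect_equal(u2000, 1.6572, tolerance = 1e-4)
  expect_equal(compute_reynolds(u2000, 0.004, blood$nu), 2000)
  expect_error(compute_reynolds(1, -1, 1e-6), class = "invalid_parameter")
  expect_error(compute_reynolds(1, 0.004, 0), class = "invalid_parameter")
})

test_that("lattice viscosity follows the relaxation rate and its limits", {
  expect_equal(lattice_viscosity(1.0), 1 / 6)
  expect_equal(lattice_viscosity(1.90), (1 / 3) * (1 / 1.9 - 0.5))
  expect_equal(lattice_viscosity(1.90), 0.0087719, tolerance = 1e-5)
  ## strictly decreasing on (0, 2), tending to zero
  om <- seq(0.1, 1.99, by = 0.01)
  nus <- lattice_viscosity(om)
  expect_true(all(diff(nus) < 0))
  expect_lt(lattice_viscosity(1.9999), 1e-4)
  expect_error(lattice_viscosity(2), class = "stability_domain")
  expect_error(lattice_viscosity(0), class = "stability_domain")
})

test_that("time step reproduces the tabulated resolutions", {
  ## at the printed Omega = 1.90, the 40 um row lands on 4 us to the nearest us
  dt_hr <- timestep_from_dx(40e-6, 1.90, blood$nu)
  expect_equal(round(dt_hr * 1e6), 4)
  ## halving dx quarters dt
  expect_equal(timestep_from_dx(40e-6, 1.9, blood$nu) /
                 timestep_from_dx(80e-6, 1.9, blood$nu), 1 / 4)
  ## the internally consistent Omega for the 16/4/1 us triple: solve
  ## dt(80 um) = 16 us for Omega
  omega_tab <- 1 / (3 * 16e-6 * blood$nu / (80e-6)^2 + 0.5)
  expect_equal(omega_tab, 1.9053, tolerance = 1e-4)
  expect_equal(timestep_from_dx(80e-6, omega_tab, blood$nu) * 1e6, 16,
               tolerance = 1e-9)
  expect_equal(timestep_from_dx(40e-6, omega_tab, blood$nu) * 1e6, 4,
               tolerance = 1e-9)
  expect_equal(timestep_from_dx(20e-6, omega_tab, blood$nu) * 1e6, 1,
               tolerance = 1e-9)
})

test_that("lattice velocity enforces the Mach bound", {
  expect_equal(lattice_velocity(0, 1e-6, 1e-5), 0)
  expect_equal(lattice_velocity(1, 1e-6, 1e-5), 0.1)
  ## Re 3500 throat velocity at the HR time step: above the 0.15 bound
  u3500 <- 3500 * blood$nu / 0.004
  expect_equal(u3500, 2.90, tolerance = 1e-2)
  err <- expect_error(lattice_velocity(u3500, 4e-6, 40e-6),
                      class = "mach_violation")
  expect_equal(err$u_lattice, 0.29, tolerance = 1e-2)
  expect_match(conditionMessage(err), "2.9")
})

test_that("flow-through times match the reported values", {
  ## convention: throat length over the inlet-section mean velocity
  u_in_2000 <- 2000 * blood$nu / 0.004 / 9
  u_in_3500 <- 3500 * blood$nu / 0.004 / 9
  expect_equal(flow_through_time(0.04, u_in_3500), 0.12, tolerance = 0.05)
  expect_equal(flow_through_time(0.04, u_in_2000), 0.21, tolerance = 0.05)
  ## doubling the velocity halves the time
  expect_equal(flow_through_time(1, 2), flow_through_time(1, 1) / 2)
})

test_that("build_case populates consistent physical and lattice quantities", {
  ## note: at the tabulated 16/4 us time steps the Re 2000 throat lattice
  ## velocity is 0.33/0.17, beyond the 0.15 bound build_case enforces, so
  ## the published cell counts are exercised at an admissible Omega
  case <- build_case(blood, 2000, dx = 80e-6, omega = 1.98)
  expect_equal(case$lattice$cells_throat, 50)
  expect_equal(build_case(blood, 2000, dx = 40e-6,
                          omega = 1.97)$lattice$cells_throat, 100)
  ## lattice-side Reynolds equals the physical one
  l <- case$lattice
  expect_equal(compute_reynolds(l$u_lattice, l$cells_throat, l$nu_lattice),
               2000, tolerance = 1e-10)
  ## under-resolution guard
  expect_error(build_case(blood, 2000, dx = 2e-3, omega = 1.9),
               class = "under_resolved")
  ## Mach refusal: Re 3500 at the NR spacing and printed Omega
  expect_error(build_case(blood, 3500, dx = 80e-6, omega = 1.90),
               class = "mach_violation")
})

test_that("physical -> lattice -> physical round-trips exactly", {
  for (re in c(500, 2000)) {
    for (dxv in c(80e-6, 40e-6, 20e-6)) {
      omega <- if (re == 2000 && dxv > 20e-6) 1.98 else 1.9053
      case <- build_case(blood, re, dx = dxv, omega = omega)
      back <- physical_from_lattice(case)
      expect_equal(back$nu, blood$nu, tolerance = 1e-12)
      expect_equal(back$u_mean_throat, case$flow$u_mean_throat,
                   tolerance = 1e-12)
      expect_equal(back$d, 0.004, tolerance = 1e-12)
    }
  }
})

test_that("lattice and physical Reynolds agree for random valid setups", {
  set.seed(42)
  for (i in 1:25) {
    re <- runif(1, 50, 1500)
    omega <- runif(1, 1.2, 1.99)
    ## pick dx so the throat is resolved and the Mach guard passes
    dxv <- 0.004 / sample(10:100, 1)
    u <- re * blood$nu / 0.004
    dt <- timestep_from_dx(dxv, omega, blood$nu)
    if (u * dt / dxv >= 0.15) next
    case <- build_case(blood, re, dx = dxv, omega = omega)
    l <- case$lattice
    re_lat <- compute_reynolds(l$u_lattice, 0.004 / l$dx, l$nu_lattice)
    expect_equal(re_lat, re, tolerance = 1e-12)
  }
})

test_that("timestep scaling is exactly quadratic in dx", {
  set.seed(7)
  for (i in 1:10) {
    om <- runif(1, 0.5, 1.95)
    dxv <- runif(1, 1e-5, 1e-3)
    expect_equal(timestep_from_dx(dxv / 2, om, blood$nu),
                 timestep_from_dx(dxv, om, blood$nu) / 4, tolerance = 1e-14)
  }
})
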