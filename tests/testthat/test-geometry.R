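# Parametric nozzle, voxelization, Bouzidi wall distances and stations.

test_that("radius profile is piecewise exact with a strict jump at the expansion", {
  g <- fda_nozzle()
  ## throat interval
  expect_equal(radius_at(g, c(-0.039, -0.02, -1e-9)), rep(0.002, 3))
  ## inlet pipe
  expect_equal(radius_at(g, c(-0.14, -0.07)), rep(0.006, 2))
  ## right-continuous jump at z = 0
  expect_equal(radius_at(g, 0), 0.006)
  expect_equal(radius_at(g, -1e-12), 0.002)
  ## linear taper midpoint
  zmid <- (g$z_con_start + g$z_throat_start) / 2
  expect_equal(radius_at(g, zmid), 0.004)
  ## contraction length follows the 10 degree half-angle
  expect_equal(g$z_throat_start - g$z_con_start, 0.004 / tan(10 * pi / 180))
  expect_error(radius_at(g, 0.9), class = "range_error")
})

test_that("voxelization reproduces the tabulated throat cell counts", {
  g <- fda_nozzle()
  slab <- c(-0.022, -0.018)   # thin slab around mid-throat
  for (case in list(c(80e-6, 50), c(40e-6, 100), c(20e-6, 200))) {
    fld <- voxelize(g, case[1], zlim = slab)
    expect_equal(throat_cell_count(fld), case[2])
  }
  expect_error(voxelize(g, 2e-3), class = "under_resolved")
})

test_that("throat cross-section flags match a plain cylinder of the same bore", {
  g <- fda_nozzle()
  fld <- voxelize(g, 80e-6, zlim = c(-0.021, -0.019))
  ## brute-force point-in-cylinder oracle at one interior plane
  k <- 2L
  d <- fld$dim
  idx <- seq_len(d[1] * d[2])
  i0 <- (idx - 1L) %% d[1]; j0 <- (idx - 1L) %/% d[1]
  xc <- fld$origin[1] + i0 * fld$dx
  yc <- fld$origin[2] + j0 * fld$dx
  oracle <- as.integer(xc^2 + yc^2 < 0.002^2)
  expect_equal(as.vector(fld$flags[, , k + 1L]), oracle)
})

test_that("voxelized volume converges to the analytic volume", {
  g <- fda_nozzle()
  zlim <- c(-0.03, -0.01)   # inside the throat
  vol_true <- pi * 0.002^2 * diff(zlim)
  errs <- vapply(c(2e-4, 1e-4, 5e-5), function(dxv) {
    fld <- voxelize(g, dxv, zlim = zlim)
    abs(sum(fld$flags == 1L) * dxv^3 - vol_true) / vol_true
  }, numeric(1))
  expect_lt(errs[3], errs[1])          # decreasing with refinement
  expect_lt(errs[3], 0.05)
})

test_that("flag field is invariant under 90-degree rotation about the axis", {
  fld <- voxelize(fda_nozzle(), 1.6e-4, zlim = c(-0.05, -0.03))
  a <- fld$flags
  rot <- aperm(a[, rev(seq_len(dim(a)[2])), , drop = FALSE], c(2, 1, 3))
  expect_identical(a, rot)
})

test_that("Bouzidi q values match the analytic cylinder distance", {
  g <- fda_nozzle()
  fld <- voxelize(g, 1e-4, zlim = c(-0.022, -0.018))
  fld <- wall_link_distances(fld)
  q <- fld$q
  expect_true(all(is.na(q[1, ])))
  expect_true(all(q[!is.na(q)] > 0 & q[!is.na(q)] <= 1))
  ## analytic oracle on purely radial (axis-aligned transverse) links in
  ## the throat: q = (R - |x|)/dx for a link along +x from a cell whose
  ## center column passes the wall at x = R, y fixed
  st <- d3q19()
  ctr <- nozzlelbm:::cell_centers(fld, fld$fluid_idx)
  R <- 0.002
  for (dir in c(2L, 4L)) {       # +x and +y axis links
    cut <- which(!is.na(q[dir, ]))
    for (s in head(cut, 25)) {
      p <- ctr[s, 1:2]
      e <- st$c[dir, 1:2]
      ## exact ray-circle intersection
      a <- sum(e^2); b <- 2 * sum(p * e); cc <- sum(p^2) - R^2
      t_exact <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a) / fld$dx
      expect_equal(q[dir, s], t_exact, tolerance = 1e-9)
    }
  }
})

test_that("q agrees with a dense indicator-marching oracle", {
  g <- fda_nozzle()
  fld <- voxelize(g, 2e-4, zlim = c(-0.058, -0.052))   # in the contraction
  fld <- wall_link_distances(fld)
  st <- d3q19()
  ctr <- nozzlelbm:::cell_centers(fld, fld$fluid_idx)
  set.seed(3)
  cut <- which(!is.na(fld$q), arr.ind = TRUE)
  pick <- cut[sample(nrow(cut), 40), , drop = FALSE]
  for (rr in seq_len(nrow(pick))) {
    dir <- pick[rr, 1]; cell <- pick[rr, 2]
    p0 <- ctr[cell, ]
    dv <- st$c[dir, ] * fld$dx
    ts <- seq(0, 1, length.out = 20001)
    ins <- nozzlelbm:::inside_nozzle(g, p0[1] + ts * dv[1],
                                     p0[2] + ts * dv[2], p0[3] + ts * dv[3])
    t_march <- ts[max(which(ins))]
    ## agreement limited by the marching grid (5e-5 of a link)
    expect_lt(abs(fld$q[dir, cell] - t_march), 6e-5)
  }
})

test_that("plane walls give exact half-way and full-link q values", {
  ## a pipe wall exactly halfway between two cell centers: radius such
  ## that R/dx - (cells) = 0.5 on the axis row
  g <- pipe_geometry(radius = 0.0025, length = 0.005)
  fld <- voxelize(g, 1e-3)   # centers at +-0.5e-3, +-1.5e-3, +-2.5e-3...
  fld <- wall_link_distances(fld)
  ## along +x from the cell at x = 1.5e-3 (y ~ 0.5e-3): wall at
  ## sqrt(R^2-y^2); check the generic identity q in (0,1] and the value
  st <- d3q19()
  ctr <- nozzlelbm:::cell_centers(fld, fld$fluid_idx)
  cut <- which(!is.na(fld$q[2L, ]))
  for (s in cut) {
    y <- unname(ctr[s, 2])
    xw <- sqrt(0.0025^2 - y^2)
    expect_equal(unname(fld$q[2L, s]), unname((xw - ctr[s, 1]) / fld$dx),
                 tolerance = 1e-9)
  }
})

test_that("stations are the benchmark's twelve z-locations with usable masks", {
  st <- nozzle_stations()
  expect_equal(st$z_m, c(-0.088, -0.064, -0.048, -0.02, -0.008, 0,
                         0.008, 0.016, 0.024, 0.032, 0.06, 0.08))
  expect_true(all(diff(st$z_m) > 0))
  ## full-extent voxelization at a coarse dx: all 12 masks non-empty
  fld <- voxelize(fda_nozzle(), 4e-4, zlim = c(-0.1, 0.1))
  masks <- station_profiles_mask(fld)
  expect_length(masks, 12)
  expect_true(all(vapply(masks, function(m) length(m$section) > 0, logical(1))))
  ## station z6 maps to the nearest plane of z = 0
  k6 <- masks$z6$plane_k
  zk <- fld$origin[3] + (k6 - 1) * fld$dx
  expect_lt(abs(zk - 0), fld$dx)
  ## throat-station section area vs analytic, within 5% at 80 um
  fth <- voxelize(fda_nozzle(), 8e-5, zlim = c(-0.024, -0.016))
  mth <- station_profiles_mask(fth, data.frame(station = "z4", z_m = -0.02))
  area <- length(mth$z4$section) * fth$dx^2
  expect_equal(area, pi * 0.002^2, tolerance = 0.05)
})

test_that("STL surfaces round-trip through the reader and voxelizer", {
  ## build a closed axis-aligned box as ASCII STL
  tmp <- tempfile(fileext = ".stl"); on.exit(unlink(tmp), add = TRUE)
  quads <- list( # each face as a cyclically ordered quad -> two triangles
    list(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)),  # z=0
    list(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1)),  # z=1
    list(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1)),  # y=0
    list(c(0,1,0), c(1,1,0), c(1,1,1), c(0,1,1)),  # y=1
    list(c(0,0,0), c(0,1,0), c(0,1,1), c(0,0,1)),  # x=0
    list(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1))   # x=1
  )
  con <- file(tmp, "w")
  writeLines("solid box", con)
  for (qd in quads) {
    for (tri in list(qd[c(1, 2, 3)], qd[c(1, 3, 4)])) {
      writeLines("facet normal 0 0 0", con)
      writeLines("  outer loop", con)
      for (v in tri)
        writeLines(sprintf("    vertex %g %g %g", v[1], v[2], v[3]), con)
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
  }
  writeLines("endsolid box", con)
  close(con)
  tri <- read_stl(tmp)
  expect_equal(dim(tri), c(12, 9))
  vox <- voxelize_stl(tri, dx = 0.25)
  ## interior cells of the unit box: 4x4x4 at dx = 0.25
  expect_equal(sum(vox), 64)
})
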