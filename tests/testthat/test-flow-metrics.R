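make_disk_plane <- function(radius = 10, spacing = 0.5, shift = c(0, 0),
                            vx = 0, vy = 0, vz = 1) {
  ax <- seq(-radius, radius, by = spacing)
  g <- expand.grid(x = ax + shift[1], y = ax + shift[2])
  mask <- (g$x - shift[1])^2 + (g$y - shift[2])^2 <= radius^2
  n <- nrow(g)
  rep_or <- function(v) if (length(v) == 1) ifelse(mask, v, 0) else v
  velocity_plane(g$x, g$y, rep_or(vx), rep_or(vy), rep_or(vz), mask,
                 spacing = spacing)
}

test_that("lumen geometry: centroid, equivalent diameter, translation", {
  disk <- make_disk_plane(radius = 10, spacing = 0.5)
  geom <- lumen_geometry(disk)
  expect_equal(geom$centroid, c(0, 0))
  expect_lt(abs(geom$diameter - 20), 0.5)  # within one grid cell

  shifted <- make_disk_plane(radius = 10, spacing = 0.5, shift = c(3, 0))
  geom2 <- lumen_geometry(shifted)
  expect_equal(geom2$centroid, c(3, 0))
  expect_equal(geom2$diameter, geom$diameter)
})

test_that("lumen geometry: elliptical mask reduces to the equal-area circle", {
  ax <- seq(-12, 12, by = 0.25)
  g <- expand.grid(x = ax, y = ax)
  mask <- (g$x / 10)^2 + (g$y / 5)^2 <= 1
  plane <- velocity_plane(g$x, g$y, 0 * g$x, 0 * g$x, ifelse(mask, 1, 0),
                          mask, spacing = 0.25)
  # oracle: area pi*a*b = 50*pi, diameter 2*sqrt(50)
  expect_equal(lumen_geometry(plane)$diameter, 2 * sqrt(50), tolerance = 5e-3)
})

test_that("NFD closed forms: centered 0, quarter-diameter offset 0.25", {
  centered <- make_jet_plane(jet_params(lumen_radius = 10, grid_spacing = 0.25,
                                        jet_radius = 4, peak_velocity = 1.5))
  expect_equal(nfd(centered), 0)
  offset <- make_jet_plane(jet_params(lumen_radius = 10, grid_spacing = 0.25,
                                      jet_center_offset = c(5, 0),
                                      jet_radius = 4, peak_velocity = 1.5))
  expect_equal(nfd(offset), 0.25, tolerance = 1e-3)
})

test_that("NFD matches the brute-force oracle and is scale/translation invariant", {
  for (seed in c(1L, 2L, 3L)) {
    plane <- random_plane(seed)
    expect_equal(nfd(plane), oracle_nfd(plane), tolerance = 1e-12)
    expect_equal(nfd(plane, weighted = FALSE),
                 oracle_nfd(plane, weighted = FALSE), tolerance = 1e-12)
    # velocity scaling invariance
    scaled <- plane
    scaled$vx <- 3 * plane$vx; scaled$vy <- 3 * plane$vy
    scaled$vz <- 3 * plane$vz
    expect_equal(nfd(scaled), nfd(plane), tolerance = 1e-12)
    # rigid translation invariance
    moved <- plane
    moved$x <- plane$x + 7.3; moved$y <- plane$y - 2.1
    expect_equal(nfd(moved), nfd(plane), tolerance = 1e-12)
  }
})

test_that("NFD errors on a fully retrograde plane", {
  retro <- make_disk_plane(vz = -1)
  expect_error(nfd(retro), "forward")
})

test_that("WPD limits: axial 1, in-plane 0, balanced 0.5", {
  expect_equal(wpd(make_disk_plane(vz = 1)), 1)
  expect_equal(wpd(make_disk_plane(vx = 1, vz = 0)), 0)
  expect_equal(wpd(make_disk_plane(vx = 0.8, vz = 0.8)), 0.5)
  expect_error(wpd(make_disk_plane(vz = 0)), "zero")
})

test_that("WPD matches its oracle and decreases with swirl", {
  for (seed in c(4L, 5L)) {
    plane <- random_plane(seed)
    expect_equal(wpd(plane), oracle_wpd(plane), tolerance = 1e-12)
  }
  swirl <- vapply(c(0, 0.2, 0.6, 1.2), function(s) {
    wpd(make_jet_plane(jet_params(lumen_radius = 10, grid_spacing = 0.5,
                                  jet_radius = 10, peak_velocity = 1.5,
                                  swirl_strength = s)))
  }, numeric(1))
  expect_true(all(diff(swirl) < 0))
})

test_that("flow angle: axial 0, uniform 30-degree tilt, oracle match", {
  expect_equal(flow_angle(make_disk_plane(vz = 1)), 0)
  tilted <- make_jet_plane(jet_params(lumen_radius = 10, grid_spacing = 0.5,
                                      jet_radius = 10, peak_velocity = 1.5,
                                      tilt_deg = 30))
  expect_equal(flow_angle(tilted), 30, tolerance = 1e-9)
  for (seed in c(6L, 7L)) {
    plane <- random_plane(seed)
    expect_equal(flow_angle(plane), oracle_angle(plane), tolerance = 1e-9)
    # scaling invariance of WPD and angle
    scaled <- plane
    scaled$vx <- 2 * plane$vx; scaled$vy <- 2 * plane$vy
    scaled$vz <- 2 * plane$vz
    expect_equal(flow_angle(scaled), flow_angle(plane), tolerance = 1e-12)
    expect_equal(wpd(scaled), wpd(plane), tolerance = 1e-12)
  }
})

test_that("angle 0 and WPD 1 coincide on noise-free forward fields", {
  plain <- make_jet_plane(jet_params(lumen_radius = 10, grid_spacing = 0.5,
                                     jet_radius = 5, peak_velocity = 1.2))
  expect_equal(flow_angle(plain), 0)
  expect_equal(wpd(plain), 1)
})

test_that("vmax: plug peak, zero field, tilt scaling", {
  plug <- make_jet_plane(jet_params(lumen_radius = 10, grid_spacing = 0.5,
                                    jet_radius = 5, peak_velocity = 1.9))
  expect_equal(vmax_plane(plug), 1.9)
  expect_equal(vmax_plane(make_disk_plane(vz = 0)), 0)
  # tilting keeps the through-plane profile and adds in-plane flow, so the
  # magnitude scales as peak / cos(tilt)
  tilted <- make_jet_plane(jet_params(lumen_radius = 10, grid_spacing = 0.5,
                                      jet_radius = 5, peak_velocity = 1.9,
                                      tilt_deg = 30))
  expect_equal(vmax_plane(tilted), 1.9 / cos(30 * pi / 180),
               tolerance = 1e-12)
})

test_that("grid refinement shrinks the discretization error of all metrics", {
  params <- function(h) jet_params(lumen_radius = 10, grid_spacing = h,
                                   jet_center_offset = c(4, 0),
                                   jet_radius = 4, peak_velocity = 1.5,
                                   tilt_deg = 20)
  coarse <- make_jet_plane(params(1))
  fine <- make_jet_plane(params(0.5))
  err <- function(plane) c(abs(nfd(plane) - 0.2),
                           abs(flow_angle(plane) - 20))
  expect_true(all(err(fine) <= err(coarse)))
})

test_that("flow_metrics bundles the four statistics consistently", {
  plane <- random_plane(9L)
  m <- flow_metrics(plane)
  expect_named(m, c("nfd", "wpd", "angle_deg", "vmax_mps"))
  expect_equal(m$nfd, nfd(plane))
  expect_equal(m$vmax_mps, vmax_plane(plane))
})
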