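test_that("medium amplitude has Beer-Lambert magnitude and k d phase", {
  k <- wavenumber_from_energy(20)
  d <- 0.25
  a <- amplitude_factor(c(0, d), c(0, 0), "vacuum", k)
  expect_equal(Mod(a), 1 / d, tolerance = 1e-12)
  expect_equal(Arg(a) %% (2 * pi), (k * d) %% (2 * pi), tolerance = 1e-4)
  # in a medium: |A|^2 d^2 = exp(-mu d)
  d2 <- 2e-3
  am <- amplitude_factor(c(0, d2), c(0, 0), "Si", k)
  expect_equal(Mod(am)^2 * d2^2, exp(-mu_at("Si", 20) * d2), tolerance = 1e-10)
  expect_error(amplitude_factor(c(0, 0), c(0, 0), "vacuum", k))
})

test_that("phase additivity holds over split segments", {
  k <- wavenumber_from_energy(17)
  r0 <- c(0, 0); r1 <- c(5e-4, 1)
  whole <- amplitude_factor(r1, r0, "air", k)
  d <- sqrt(sum((r1 - r0)^2))
  # splitting at a co-linear midpoint: the phases add, the 1/d norms
  # compose up to the known distance-product correction
  rmid <- r0 + 0.37 * (r1 - r0)
  parts <- amplitude_factor(rmid, r0, "air", k) * amplitude_factor(r1, rmid, "air", k)
  dd1 <- 0.37 * d; dd2 <- 0.63 * d
  # the accumulated optical phase is ~1e11 rad over a metre; double
  # precision carries it to ~2e-5 rad only, which bounds the agreement
  expect_equal(parts * dd1 * dd2 / d, whole, tolerance = 1e-4)
})

test_that("Snell refraction preserves the tangential component and round trips", {
  set.seed(11)
  for (i in 1:50) {
    th <- runif(1, 0, 0.2)
    u <- c(sin(th), cos(th))
    nA <- 1; nB <- 1 - runif(1, 1e-7, 1e-5)
    s <- snell_refract(u[1], u[2], 0, -1, nA, nB)
    expect_equal(nA * u[1], nB * s$ux, tolerance = 1e-12)
    expect_equal(s$tau, 1)
    back <- snell_refract(s$ux, s$uz, 0, -1, nB, nA)
    expect_equal(back$ux, u[1], tolerance = 1e-12)
    expect_equal(back$uz, u[2], tolerance = 1e-12)
  }
})

test_that("normal incidence and equal indices leave the direction unchanged", {
  s <- snell_refract(0, 1, 0, -1, 1, 1 - 1e-6)
  expect_equal(c(s$ux, s$uz), c(0, 1))
  s2 <- snell_refract(0.3, sqrt(1 - 0.09), 0, -1, 1.0, 1.0)
  expect_equal(s2$ux, 0.3, tolerance = 1e-14)
})

test_that("grazing incidence below the critical angle reflects totally", {
  delta <- delta_at("Si", 17)
  thc <- sqrt(2 * delta)                 # critical grazing angle
  graze <- thc * 0.5                     # below critical -> total reflection
  # surface in the y-z plane (normal along x); ray almost parallel to it
  u <- c(sin(graze), cos(graze))
  s <- snell_refract(u[1], u[2], -1, 0, 1, 1 - delta)
  expect_equal(s$tau, -1)
  # above critical: transmitted
  graze2 <- thc * 2
  u2 <- c(sin(graze2), cos(graze2))
  s2 <- snell_refract(u2[1], u2[2], -1, 0, 1, 1 - delta)
  expect_equal(s2$tau, 1)
})

test_that("single-path tracer classifies events and applies 1/r and chords", {
  k <- wavenumber_from_energy(20)
  geom <- gi_geometry(x_range = c(-1e-3, 1e-3), z_range = c(-0.1, 2))
  p <- path_batch(x = 0, z = 0, k = k)
  r <- trace_to_next_boundary(p, geom, detector_z = 0.5)
  expect_equal(r$event, "detector-plane")
  expect_equal(Mod(r$path$w), 1 / 0.5)
  # aimed outside the lateral bounds -> escape
  p2 <- path_batch(x = 0, z = 0, ux = 0.9, uz = 0.1, k = k)
  r2 <- trace_to_next_boundary(p2, geom, detector_z = 0.5)
  expect_equal(r2$event, "escape")
})

test_that("a silicon cylinder chord attenuates by exp(-mu c / 2)", {
  k <- wavenumber_from_energy(20)
  R <- 0.87e-3; xoff <- 0.4e-3
  geom <- gi_geometry(list(region_cylinder(0, 0.01, R, "Si")))
  b <- path_batch(x = xoff, z = 0, k = k)
  b2 <- propagate_to_plane(b, 0.02, geom, keep_r_norm = FALSE, snell = FALSE)
  chord <- 2 * sqrt(R^2 - xoff^2)
  expect_equal(Mod(b2$w), exp(-mu_at("Si", 20) * chord / 2), tolerance = 1e-9)
  # off-cylinder path is untouched in magnitude
  b3 <- propagate_to_plane(path_batch(x = 2e-3, z = 0, k = k), 0.02, geom)
  expect_equal(Mod(b3$w), 1)
})

test_that("medium amplitude reduces to the vacuum form for delta, beta -> 0", {
  k <- wavenumber_from_energy(25)
  d <- 0.3
  a_vac <- amplitude_factor(c(0, d), c(0, 0), "vacuum", k)
  a_air <- amplitude_factor(c(0, d), c(0, 0), "air", k)
  # air over 30 cm attenuates by its own Beer-Lambert factor
  expect_equal(Mod(a_air), Mod(a_vac) * exp(-mu_at("air", 25) * d / 2),
               tolerance = 1e-9)
  m <- gi_material("air"); m$delta_ref <- 0
  m$mu_total <- m$mu_total * 0
  a0 <- amplitude_factor(c(0, d), c(0, 0), m, k)
  expect_equal(a0, a_vac, tolerance = 1e-12)
})
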