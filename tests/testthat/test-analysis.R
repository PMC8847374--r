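test_that("analytic slit profiles have the right extrema and zeros", {
  x <- seq(-40e-6, 40e-6, by = 0.1e-6)
  I2 <- analytic_double_slit(x, a = 0.2e-6, b = 2.2e-6, E = 17, d = 0.1)
  expect_equal(which.max(I2), which.min(abs(x)))
  lam <- wavelength_from_energy(17)
  # envelope zero at the single-slit diffraction angle lambda/a
  x0 <- lam * 0.1 / 0.2e-6
  I1 <- analytic_single <- analytic_double_slit(c(x0, x0 / 2), a = 0.2e-6,
                                                b = NULL, E = 17, d = 0.1)
  expect_lt(I1[1] * 1e6, I1[2])
  expect_equal(sum(I2), 1)
  # against the Fresnel oracle of the same geometry: plane-wave double slit
  # in the far field correlates > 0.999 with the Fraunhofer form
  a <- 0.2e-6; b <- 2.2e-6; d <- 0.1
  dx <- 0.02e-6; width <- 409.6e-6
  f <- plane_wave_field(width, dx, 17)
  xx <- f$x - width / 2
  f$amp <- as.complex((abs(xx - b / 2) < a / 2) | (abs(xx + b / 2) < a / 2))
  fz <- fresnel_propagate(f, d)
  Iw <- field_intensity(fz)
  sel <- abs(xx) < 35e-6
  Ia <- analytic_double_slit(xx[sel], a = a, b = b, E = 17, d = d)
  expect_gt(pearson(Iw[sel], Ia), 0.999)
})

test_that("cylinder transmission and DPC match their closed forms", {
  mu <- mu_at("Si", 20)
  R <- 0.87e-3
  expect_equal(beer_lambert_cylinder(0, R, mu), exp(-2 * mu * R))
  expect_equal(beer_lambert_cylinder(c(-R, R, 2 * R), R, mu), c(1, 1, 1))
  k <- wavenumber_from_energy(20)
  delta <- delta_at("Si", 20)
  g <- analytic_dpc_cylinder(c(-0.3e-3, 0, 0.3e-3), R, delta, k)
  expect_equal(g[2], 0)
  expect_equal(g[1], -g[3])                       # antisymmetric
  # finite differences of the phase projection
  phi <- function(x) -k * delta * 2 * sqrt(R^2 - x^2)
  h <- 1e-9
  for (x0 in c(0.2e-3, 0.5e-3, 0.8e-3)) {
    fd <- (phi(x0 + h) - phi(x0 - h)) / (2 * h)
    expect_equal(analytic_dpc_cylinder(x0, R, delta, k), fd,
                 tolerance = 1e-5)
  }
  expect_error(analytic_dpc_cylinder(numeric(0), R, delta, k, d = 0.02))
})

test_that("fractional Talbot distances reproduce the printed anchors", {
  expect_equal(fractional_talbot_distance(4e-6, 20, 1), 3.23e-2,
               tolerance = 2e-3)
  expect_equal(fractional_talbot_distance(2e-6, 20, 3), 2.42e-2,
               tolerance = 2e-3)
  expect_equal(fractional_talbot_distance(8e-6, 20, 1) /
                 fractional_talbot_distance(4e-6, 20, 1), 4)  # p^2 scaling
  expect_error(fractional_talbot_distance(4e-6, 20, 2))
})

test_that("phase stepping of synthetic fringes retrieves exactly", {
  p2 <- 1e-6
  x <- seq(0, 100e-6 - p2 / 64, by = p2 / 64)
  mk <- function(A, v, shift) A * (1 + v * cos(2 * pi * (x - shift) / p2))
  ref <- phase_step(x, mk(1, 0.6, 0), p2, n_steps = 8, pixel_size = 10e-6)
  # flat input -> flat stepping curve
  flat <- phase_step(x, rep(1, length(x)), p2, n_steps = 8, pixel_size = 10e-6)
  expect_lt(diff(range(flat$curve)), 1e-12)
  # shifting by one full period reproduces the curve
  per <- phase_step(x, mk(1, 0.6, p2), p2, n_steps = 8, pixel_size = 10e-6)
  expect_equal(per$curve, ref$curve, tolerance = 1e-9)
  # retrieval identity and linearity
  r_id <- retrieve_signals(ref, ref)
  expect_equal(r_id$absorption, rep(1, nrow(r_id)))
  expect_equal(r_id$dpc, rep(0, nrow(r_id)))
  half <- phase_step(x, 0.5 * mk(1, 0.6, 0), p2, n_steps = 8,
                     pixel_size = 10e-6)
  r_half <- retrieve_signals(half, ref)
  expect_equal(r_half$absorption, rep(0.5, nrow(r_half)), tolerance = 1e-10)
  expect_equal(r_half$dpc, rep(0, nrow(r_half)), tolerance = 1e-10)
  # a known injected fringe shift appears as -2 pi shift / period
  for (sh in c(0.1e-6, 0.27e-6, -0.2e-6)) {
    smp <- phase_step(x, mk(0.8, 0.6, sh), p2, n_steps = 8,
                      pixel_size = 10e-6)
    r <- retrieve_signals(smp, ref)
    expect_equal(r$dpc, rep(-2 * pi * sh / p2, nrow(r)), tolerance = 1e-6)
    expect_equal(r$absorption, rep(0.8, nrow(r)), tolerance = 1e-10)
  }
})

test_that("visibility estimator matches closed forms and is scale invariant", {
  p <- 3e-6
  x <- seq(0, 60e-6 - p / 32, by = p / 32)
  I <- 1 + 0.5 * cos(2 * pi * x / p)
  expect_equal(visibility(x, I, p), 0.5, tolerance = 1e-10)
  expect_equal(visibility(x, 7.3 * I, p), 0.5, tolerance = 1e-10)
  expect_equal(visibility(x + 1.234e-6, I, p), 0.5, tolerance = 1e-10)
  expect_equal(visibility(x, rep(2, length(x)), p), 0)
  expect_error(visibility(x, rep(0, length(x)), p))
  expect_error(visibility(x[1:5], I[1:5], p))
})

test_that("the analyzer visibility correction behaves at its limits", {
  # perfect absorber -> 1
  thick <- 1e-3
  expect_equal(visibility_correction(21, thick), 1, tolerance = 1e-5)
  # equal transmissions -> 0
  expect_equal(visibility_correction(21, 30e-6, absorber = "Si"), 0)
  # 30 um Au/Si analyzer at 21 keV
  expect_equal(visibility_correction(21, 30e-6), 0.96, tolerance = 0.01)
})

test_that("rmse conventions and pearson behave", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  expect_equal(rmse(a, b, normalize = "mean"), 0)
  expect_equal(rmse(a, b, normalize = "sum"), 0)
  expect_gt(rmse(a, b, normalize = "none"), 0)
  expect_equal(pearson(a, b), 1)
})
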