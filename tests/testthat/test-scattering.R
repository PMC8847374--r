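test_that("Compton kinematics follow the closed-form energy relation", {
  set.seed(51)
  cs <- compton_sample(rep(20, 20000))
  expect_true(all(cs$E_out <= 20 + 1e-12))
  expect_true(all(cs$E_out >= 20 / (1 + 2 * 20 / 510.99895) - 1e-12))
  # E'(theta) identity on the samples
  expect_equal(cs$E_out,
               20 / (1 + 20 / 510.99895 * (1 - cos(cs$theta))),
               tolerance = 1e-12)
  # mean scattered energy vs 1-D quadrature of Klein-Nishina
  kn <- function(ct, E) {
    r <- 1 / (1 + E / 510.99895 * (1 - ct))
    r^2 * (r + 1 / r - (1 - ct^2))
  }
  w <- integrate(function(ct) kn(ct, 20), -1, 1)$value
  m <- integrate(function(ct) kn(ct, 20) * 20 / (1 + 20 / 510.99895 * (1 - ct)),
                 -1, 1)$value / w
  expect_equal(mean(cs$E_out), m, tolerance = 0.01 * m)
})

test_that("Rayleigh angles follow the Thomson distribution", {
  set.seed(52)
  th <- rayleigh_sample_angle(40000)
  ct <- cos(th)
  # E[cos^2] of (1+c^2)/2 density over [-1,1] is (1/3 + 1/5)/(4/3) = 2/5
  expect_equal(mean(ct^2), 0.4, tolerance = 0.01)
  expect_equal(mean(ct), 0, tolerance = 0.02)
})

test_that("interaction sites follow the Beer-Lambert law", {
  set.seed(53)
  mu <- mu_at("Si", 20)
  L <- 1e-3
  s <- sample_interaction_site(rep(L, 40000), "Si", 20)
  expect_equal(mean(s$interacts), 1 - exp(-mu * L), tolerance = 0.01)
  expect_equal(mean(s$s, na.rm = TRUE),
               (1 / mu) - L * exp(-mu * L) / (1 - exp(-mu * L)),
               tolerance = 0.02)
  expect_false(any(sample_interaction_site(rep(1, 100), "vacuum", 20)$interacts))
})

test_that("channel selection matches the partial coefficients", {
  set.seed(54)
  ch <- select_channel(rep(21, 50000), "Au")
  frac <- tabulate(ch, 3) / 50000
  mu_tot <- mu_at("Au", 21)
  expect_equal(frac[1], mu_at("Au", 21, "photo") / mu_tot, tolerance = 0.01)
  expect_equal(frac[2], mu_at("Au", 21, "incoh") / mu_tot, tolerance = 0.01)
  expect_gt(frac[1], 0.5)    # photoelectric dominates in gold at 21 keV
})

test_that("interaction handling keeps the interference clone and books energy", {
  set.seed(55)
  b <- path_batch(x = c(0, 1e-4, 2e-4), z = 0.1, k = wavenumber_from_energy(20),
                  w = 0.5 + 0.5i, sw = 0.25, hist = 1:3)
  r <- handle_interaction(b, channel = c(1L, 2L, 3L))
  # clones continue unchanged except for the ray-trace-only flag
  expect_equal(r$clones$w, b$w)
  expect_equal(r$clones$mode, rep(1L, 3))
  # photo deposits the full energy times the statistical weight
  expect_equal(r$deposit[1], 20 * 0.25)
  # Compton deposits the transfer and pushes a secondary with weight sw
  expect_equal(n_paths(r$secondaries), 1)
  expect_equal(r$secondaries$sw, 0.25)
  expect_equal(r$deposit[2] + r$secondaries$k[1] *
                 1.23984193e-9 / (2 * pi) * 0.25, 20 * 0.25, tolerance = 1e-9)
  # Rayleigh continues as interfering primary, once only
  expect_equal(r$rayleigh_primaries$mode, 0L)
  expect_equal(r$rayleigh_primaries$nray, 1L)
  b2 <- r$rayleigh_primaries
  r2 <- handle_interaction(b2, channel = 3L)
  expect_equal(r2$rayleigh_primaries$mode, 2L)   # demoted after the second
  expect_error(handle_interaction(r$clones, channel = c(1L, 1L, 1L)))
})

test_that("conventional transport: vacuum passes, thick absorbers stop", {
  set.seed(56)
  led <- gi_ledger("slab")
  led$emitted <- 100 * 20
  geom <- gi_geometry(background = "vacuum", x_range = c(-1, 1),
                      z_range = c(-0.1, 1))
  r <- run_conventional_transport(x = runif(100, -1e-3, 1e-3), z = rep(0, 100),
                                  ux = rep(0, 100), uz = rep(1, 100),
                                  E = rep(20, 100), sw = rep(1, 100),
                                  geom = geom, ledger = led, detector_z = 0.5)
  expect_equal(unname(r$ledger$dep[["leave_at_D"]]), 100 * 20)
  # infinite absorber slab: everything deposited inside
  led2 <- gi_ledger("slab")
  led2$emitted <- 100 * 20
  geom2 <- gi_geometry(list(region_slab(0.1, 0.4, material = "Au",
                                        label = "slab")),
                       background = "vacuum", x_range = c(-1, 1),
                       z_range = c(-0.1, 1))
  r2 <- run_conventional_transport(x = runif(100, -1e-3, 1e-3),
                                   z = rep(0, 100),
                                   ux = rep(0, 100), uz = rep(1, 100),
                                   E = rep(20, 100), sw = rep(1, 100),
                                   geom = geom2, ledger = led2,
                                   detector_z = 0.5)
  fr <- ledger_fractions(r2$ledger)
  expect_gt(fr[["slab"]], 95)
  expect_equal(sum(r2$ledger$dep) / r2$ledger$emitted, 1, tolerance = 1e-9)
})
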