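k20 <- wavenumber_from_energy(20)

test_that("Fourier coefficients of binary gratings match numeric quadrature", {
  quad_coeff <- function(n, p, a, ta, tb) {
    # integrate the two smooth sections separately: the profile jump at
    # x = a otherwise limits the quadrature accuracy
    seg <- function(f, lo, hi)
      integrate(f, lo, hi, subdivisions = 2000, rel.tol = 1e-12,
                abs.tol = 1e-14)$value
    re <- seg(function(x) Re(ta * exp(1i * 2 * pi * n * x / p)), 0, a) +
          seg(function(x) Re(tb * exp(1i * 2 * pi * n * x / p)), a, p)
    im <- seg(function(x) Im(ta * exp(1i * 2 * pi * n * x / p)), 0, a) +
          seg(function(x) Im(tb * exp(1i * 2 * pi * n * x / p)), a, p)
    complex(real = re, imaginary = im) / p
  }
  set.seed(21)
  for (i in 1:5) {
    duty <- runif(1, 0.2, 0.8)
    ta <- complex(real = runif(1, -1, 1), imaginary = runif(1, -1, 1))
    tb <- complex(real = runif(1, -1, 1), imaginary = runif(1, -1, 1))
    p <- 4e-6
    g <- gi_grating(z = 0, period = p, duty = duty, tau_a = ta, tau_b = tb)
    cn <- g1_fourier_coeffs(g, k20, N = 3)
    for (n in -3:3)
      expect_equal(cn[[as.character(n)]],
                   quad_coeff(n, p, duty * p, ta, tb), tolerance = 1e-10)
  }
})

test_that("duty-0.5 pi grating has vanishing even orders and |c1| = 2/pi", {
  g <- gi_grating(z = 0, period = 4e-6, duty = 0.5, tau_a = 1, tau_b = -1)
  cn <- g1_fourier_coeffs(g, k20, N = 4)
  expect_equal(Mod(cn[["0"]]), 0, tolerance = 1e-14)
  expect_equal(Mod(cn[["2"]]), 0, tolerance = 1e-14)
  expect_equal(Mod(cn[["4"]]), 0, tolerance = 1e-14)
  expect_equal(Mod(cn[["1"]]), 2 / pi, tolerance = 1e-12)
  expect_equal(Mod(cn[["-3"]]), 2 / (3 * pi), tolerance = 1e-12)
})

test_that("classical mask transmits slits and absorbs bars", {
  g <- gi_grating(z = 0, period = 2e-6, duty = 0.5)
  expect_true(g0_classical_mask(0.5e-6, g))       # slit centre
  expect_false(g0_classical_mask(1.5e-6, g))      # absorber centre
  set.seed(3)
  x <- runif(20000, -1e-4, 1e-4)
  expect_equal(mean(g0_classical_mask(x, g)), 0.5, tolerance = 0.02)
  # slit restriction
  g2 <- gi_grating(z = 0, period = 2e-6, duty = 0.5, slits = 0L)
  expect_true(g0_classical_mask(0.5e-6, g2))
  expect_false(g0_classical_mask(2.5e-6, g2))     # open section of period 1
})

test_that("every splitting operation conserves summed |z|^2", {
  set.seed(22)
  b <- path_batch(x = runif(7, -2e-6, 2e-6), z = 0, k = k20, hist = 1:7)
  # huygens
  gh <- gi_grating(z = 0, period = 4e-6, duty = 0.5, tau_a = 1, tau_b = 1i,
                   mode = "huygens", n_split = 33, angular_range = 1e-3)
  bh <- huygens_split(b, gh)
  s <- rowsum(Mod(bh$w)^2, bh$hist)[, 1]
  expect_equal(unname(s), Mod(grating_tau(gh, b$x, k20))^2, tolerance = 1e-12)
  # phase grating orders (unit-modulus tau: exact unity)
  gp <- gi_grating(z = 0, period = 4e-6, duty = 0.5, tau_a = 1, tau_b = -1,
                   n_split = 11)
  bp <- g1_split(b, gp)
  expect_equal(unname(rowsum(Mod(bp$w)^2, bp$hist)[, 1]), rep(1, 7),
               tolerance = 1e-12)
  # absorption grating Fourier splitting
  ga <- gi_grating(z = 0, period = 4e-6, duty = 0.5, n_q = 32)
  keep <- g0_classical_mask(b$x, ga)
  ba <- g0_fourier_split(b, ga)
  expect_equal(unname(rowsum(Mod(ba$w)^2, ba$hist)[, 1]),
               rep(1, sum(keep)), tolerance = 1e-12)
})

test_that("huygens splitting fans uniformly and keeps cohort statistics", {
  b <- path_batch(x = 0, z = 0, k = k20)
  g <- gi_grating(z = 0, period = 4e-6, duty = 0.5, tau_a = 1, tau_b = 1,
                  mode = "huygens", n_split = 5, angular_range = 2e-3)
  s <- huygens_split(b, g)
  expect_equal(n_paths(s), 5)
  th <- atan2(s$ux, s$uz)
  expect_equal(diff(th), rep(5e-4, 4), tolerance = 1e-12)
  expect_equal(Mod(s$w), rep(1 / sqrt(5), 5))
  # N = 1: parent unchanged up to normalization
  g1 <- gi_grating(z = 0, period = 4e-6, duty = 0.5, tau_a = 1, tau_b = 1,
                   mode = "huygens", n_split = 1)
  s1 <- huygens_split(b, g1)
  expect_equal(s1$ux, b$ux); expect_equal(s1$w, b$w)
})

test_that("absorption-grating Fourier weights follow the sinc envelope in +/- pairs", {
  set.seed(23)
  g <- gi_grating(z = 0, period = 2.2e-6, duty = 0.2 / 2.2, n_q = 64,
                  x0 = -0.1e-6)
  b <- path_batch(x = 0, z = 0, k = wavenumber_from_energy(17))
  s <- g0_fourier_split(b, g)
  expect_equal(n_paths(s), 64)
  # recover Q from the direction change, check pairing and weight ratios
  Q <- -s$ux * s$k
  expect_equal(sort(Q), sort(-Q), tolerance = 1e-6)
  expect_equal(mean(s$ux), 0, tolerance = 1e-12)   # no net drift
  a <- g$a
  w_expect <- abs(sin(Q * a / 2) / (Q / 2))
  ratio <- Mod(s$w) / w_expect
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  # |z| is maximal towards Q -> 0 (sinc maximum)
  expect_gt(cor(abs(Q), Mod(s$w)), -1)
  expect_true(which.max(Mod(s$w)) %in% which(abs(Q) == min(abs(Q))))
})

test_that("phase-grating splitting honours order kinematics and x-dependent phases", {
  g <- gi_grating(z = 0, period = 4e-6, duty = 0.5, tau_a = 1, tau_b = -1,
                  n_split = 3)
  b <- path_batch(x = 1.234e-6, z = 0, k = k20)
  s <- g1_split(b, g, drop_zero = FALSE)
  expect_equal(n_paths(s), 7)
  kx <- s$k * s$ux
  expect_equal(sort(unique(round(kx / (2 * pi / 4e-6)))), -3:3)
  expect_equal(s$k, rep(k20, 7))                 # |k| conserved
  expect_equal(sqrt(s$ux^2 + s$uz^2), rep(1, 7), tolerance = 1e-12)
  # n = 0 path of a duty-0.5 pi grating carries zero weight
  n0 <- which(abs(kx) < 1)
  expect_equal(Mod(s$w[n0]), 0, tolerance = 1e-14)
  # transparent element with N = 0: single unchanged path
  gt <- gi_grating(z = 0, period = 4e-6, duty = 0.5, tau_a = 1, tau_b = 1,
                   n_split = 0)
  st <- g1_split(path_batch(x = 0, z = 0, k = k20), gt, drop_zero = FALSE)
  expect_equal(n_paths(st), 1)
  expect_equal(Mod(st$w), 1, tolerance = 1e-12)
  expect_equal(st$ux, 0)
})

test_that("implicit attenuation deposits the squared-weight deficit", {
  g <- gi_grating(z = 0, period = 2e-6, duty = 0.5, mode = "implicit",
                  tau_a = 1, tau_b = 0)
  b <- path_batch(x = c(0.5e-6, 1.5e-6), z = 0, k = k20, hist = 1:2)
  r <- implicit_attenuation(b, g)
  expect_equal(attr(r, "deposit_sw"), c(0, 1))
  expect_equal(Mod(r$w), c(1, 0))
  # |tau| = 1 everywhere: no deposit
  g1 <- gi_grating(z = 0, period = 2e-6, duty = 0.5, mode = "implicit",
                   tau_a = 1, tau_b = -1)
  r1 <- implicit_attenuation(b, g1)
  expect_equal(attr(r1, "deposit_sw"), c(0, 0))
  # duty-0.5 absorber under uniform illumination deposits half the energy
  set.seed(4)
  bu <- path_batch(x = runif(20000, 0, 1e-4), z = 0, k = k20, hist = 1:20000)
  ru <- implicit_attenuation(bu, g)
  expect_equal(mean(attr(ru, "deposit_sw")), 0.5, tolerance = 0.02)
})

test_that("physical-thickness gratings derive tau from material constants", {
  t_pi <- pi_phase_thickness("Si", 20)
  g <- gi_grating(z = 0, period = 4e-6, duty = 0.5, material = "Si",
                  thickness = t_pi)
  tau_b <- grating_tau(g, 3e-6, k20)    # absorber-section value
  expect_equal(abs(Arg(tau_b)), pi, tolerance = 1e-9)  # pi shift of the wall
  expect_equal(Mod(tau_b), exp(-mu_at("Si", 20) * t_pi / 2), tolerance = 1e-9)
  expect_equal(grating_tau(g, 1e-6, k20), 1 + 0i)   # slit
})
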