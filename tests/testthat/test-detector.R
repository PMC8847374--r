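k17 <- wavenumber_from_energy(17)

mk_det <- function(nb = 10, bw = 1e-6)
  detector_grid(z = 1, x_min = 0, x_max = nb * bw, bin_width = bw)

test_that("coherent accumulation adds fields, squares on close", {
  det <- mk_det()
  b <- path_batch(x = 1.5e-6, z = 1, k = k17, w = 0.5 + 0i)
  det <- det_accumulate(det, b)
  det <- close_cohort(det)
  expect_equal(det$intensity[2], 0.25)
  # two equal in-phase paths -> 4x the single-path intensity
  det2 <- mk_det()
  b2 <- path_batch(x = rep(1.5e-6, 2), z = 1, k = k17, w = 0.5 + 0i, hist = 1:2)
  det2 <- close_cohort(det_accumulate(det2, b2))
  expect_equal(det2$intensity[2], 1)
  # opposite phases cancel
  det3 <- mk_det()
  b3 <- path_batch(x = rep(1.5e-6, 2), z = 1, k = k17,
                   w = c(0.5 + 0i, -0.5 + 0i), hist = 1:2)
  det3 <- close_cohort(det_accumulate(det3, b3))
  expect_equal(det3$intensity[2], 0)
})

test_that("paths-squared normalization makes n identical paths equal one", {
  det <- mk_det()
  b1 <- path_batch(x = 4.5e-6, z = 1, k = k17, w = 1 + 0i)
  det <- close_cohort(det_accumulate(det, b1), "per-bin-paths-squared")
  i1 <- det$intensity[5]
  detn <- mk_det()
  bn <- path_batch(x = rep(4.5e-6, 7), z = 1, k = k17, w = 1 + 0i, hist = 1:7)
  detn <- close_cohort(det_accumulate(detn, bn), "per-bin-paths-squared")
  expect_equal(detn$intensity[5], i1)
})

test_that("endpoints outside the range escape; scatter channel is incoherent", {
  det <- mk_det()
  b <- path_batch(x = c(-5e-6, 2.5e-6, 50e-6), z = 1, k = k17, hist = 1:3)
  det <- det_accumulate(det, b)
  expect_equal(det$n_escaped, 2)
  bs <- path_batch(x = rep(2.5e-6, 2), z = 1, k = k17,
                   w = c(1 + 0i, -1 + 0i), sw = 0.5, hist = 1:2, mode = 2L)
  det <- det_accumulate(det, bs)
  expect_equal(det$scatter[3], 1)          # probabilities add, no cancellation
  expect_true(all(det$scatter >= 0))
})

test_that("empty cohorts close as no-ops", {
  det <- mk_det()
  det2 <- close_cohort(det)
  expect_equal(det2$intensity, det$intensity)
})

test_that("pixel rebinning conserves totals and drops the remainder", {
  det <- detector_grid(z = 1, x_min = 0, x_max = 10e-6, bin_width = 1e-6,
                       pixel_size = 3e-6)
  det$intensity <- rep(2, det$n_bins)
  px <- rebin_to_pixels(det)
  expect_equal(length(px$primary), 3)       # 10 bins -> 3 pixels of 3 bins
  expect_equal(px$primary, rep(6, 3))       # flat stays flat
  expect_equal(sum(px$primary), sum(det$intensity[1:9]))
  expect_error(rebin_to_pixels(det, pixel_size = 2.5e-6))
  # 0.5 cm field of view at 75 um pixels -> 66 whole pixels
  det2 <- detector_grid(z = 1, x_min = 0, x_max = 0.5e-2, bin_width = 75e-6 / 16,
                        pixel_size = 75e-6)
  det2$intensity <- rep(1, det2$n_bins)
  expect_equal(length(rebin_to_pixels(det2)$primary), 66)
})

test_that("coherent intensity is quadratic in the weights, cohorts add", {
  set.seed(31)
  x <- runif(200, 0, 10e-6)
  det_a <- close_cohort(det_accumulate(mk_det(), path_batch(
    x = x, z = 1, k = k17, w = 1 + 0i, hist = 1:200)))
  det_b <- close_cohort(det_accumulate(mk_det(), path_batch(
    x = x, z = 1, k = k17, w = 2 + 0i, hist = 1:200)))
  expect_equal(det_b$intensity, 4 * det_a$intensity)
  # incoherent additivity of separately closed subsets
  det_1 <- close_cohort(det_accumulate(mk_det(), path_batch(
    x = x[1:100], z = 1, k = k17, hist = 1:100)))
  det_2 <- close_cohort(det_accumulate(mk_det(), path_batch(
    x = x[101:200], z = 1, k = k17, hist = 1:100)))
  det_12 <- det_accumulate(mk_det(), path_batch(
    x = x[1:100], z = 1, k = k17, hist = 1:100))
  det_12 <- close_cohort(det_12)
  det_12 <- det_accumulate(det_12, path_batch(
    x = x[101:200], z = 1, k = k17, hist = 1:100))
  det_12 <- close_cohort(det_12)
  expect_equal(det_12$intensity, det_1$intensity + det_2$intensity)
})
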