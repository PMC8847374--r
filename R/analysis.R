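# Analytic reference signals, phase-stepping retrieval and metrics.

#' Analytic double-slit / single-slit intensity
#'
#' Fraunhofer pattern for a point source at distance `l` before the slits and
#' a detector at distance `d` behind them. For an on-axis source the fringe
#' and envelope scales are set by the slit-detector distance:
#' `I(x) = cos^2(pi b x / (lambda d)) * sinc^2(pi a x / (lambda d))`
#' (the `cos^2` factor is dropped for a single slit). `b` is the
#' centre-to-centre slit separation. Profiles are normalized to unit sum.
#'
#' @param x detector positions in metres (relative to the pattern centre)
#' @param a slit width in metres
#' @param b centre-to-centre slit separation in metres (`NULL` or missing for
#'   a single slit)
#' @param E photon energy in keV
#' @param d slit-to-detector distance in metres
#' @param l source-to-slit distance in metres (kept for the interface; the
#'   on-axis Fraunhofer scales do not involve it)
#' @return normalized intensity profile
#' @export
analytic_double_slit <- function(x, a, b = NULL, E, d, l = NULL) {
  lam <- wavelength_from_energy(E)
  u <- pi * a * x / (lam * d)
  env <- ifelse(u == 0, 1, (sin(u) / u)^2)
  I <- if (is.null(b)) env else {
    stopifnot(a < b)
    env * cos(pi * b * x / (lam * d))^2
  }
  I / sum(I)
}

#' Beer-Lambert transmission of a cylinder
#'
#' `T(x) = exp(-mu * 2 sqrt(R^2 - x^2))` inside `|x| < R`, 1 outside.
#'
#' @param x lateral positions relative to the cylinder axis (m)
#' @param R cylinder radius (m)
#' @param mu linear attenuation coefficient (1/m)
#' @export
beer_lambert_cylinder <- function(x, R, mu) {
  stopifnot(R > 0)
  ifelse(abs(x) < R, exp(-mu * 2 * sqrt(pmax(R^2 - x^2, 0))), 1)
}

#' Analytic differential-phase signal of a cylinder
#'
#' The object phase is `phi(x) = -k delta 2 sqrt(R^2 - x^2)`; its transverse
#' derivative `dphi/dx = 2 k delta x / sqrt(R^2 - x^2)` corresponds to a
#' refraction angle `alpha = (1/k) dphi/dx` and hence a measured
#' phase-stepping signal `2 pi d alpha / p2` for an analyzer (fringe) period
#' `p2` and an object-to-detector distance `d`. With `wrap = TRUE` the signal
#' is wrapped to `(-pi, pi]` like the measured one.
#'
#' @param x lateral positions relative to the axis (m); `|x| >= R` gives 0
#'   (outside) but positions on the divergent border are the caller's burden
#' @param R cylinder radius (m)
#' @param delta refractive-index decrement of the cylinder medium
#' @param k wavenumber (1/m)
#' @param d object-to-detector distance (m); `NULL` returns `dphi/dx` in
#'   rad/m instead of the setup-mapped signal
#' @param p2 analyzer / fringe period (m)
#' @param wrap wrap the mapped signal to `(-pi, pi]`
#' @export
analytic_dpc_cylinder <- function(x, R, delta, k, d = NULL, p2 = NULL,
                                  wrap = TRUE) {
  inside <- abs(x) < R
  g <- numeric(length(x))
  g[inside] <- 2 * k * delta * x[inside] / sqrt(R^2 - x[inside]^2)
  if (is.null(d)) return(g)
  stopifnot(!is.null(p2))
  # sign convention: a fringe displacement towards +x appears as a negative
  # first-harmonic phase of the stepping curve (see retrieve_signals)
  s <- -2 * pi * d * (g / k) / p2
  if (wrap) s <- .wrap_pi(s)
  s
}

.wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

#' Fractional Talbot distance of a pi-shifting grating
#'
#' For plane-wave illumination of a pi grating of period p the intensity
#' fringes of period p/2 repeat at odd multiples of `p^2 / (8 lambda)`.
#'
#' @param p grating period (m)
#' @param E photon energy in keV
#' @param order odd positive integer
#' @return distance in metres
#' @export
#' @examples
#' fractional_talbot_distance(4e-6, 20, 1)  # 3.23 cm
fractional_talbot_distance <- function(p, E, order = 1) {
  if (order %% 2 == 0 || order < 1)
    stop("fractional Talbot distances of a pi grating occur at odd orders")
  order * p^2 / (8 * wavelength_from_energy(E))
}

#' Phase stepping with a binary mask
#'
#' Simulates analyzer-grating phase stepping as post processing: for each of
#' `n_steps` lateral mask positions, the fine-bin signal is multiplied by a
#' binary comb (open fraction `duty`, period `mask_period`) and summed into
#' pixels.
#'
#' @param x fine bin centres (m), equally spaced
#' @param signal fine-bin intensities
#' @param mask_period analyzer period (m)
#' @param n_steps number of phase steps over one period
#' @param duty open fraction of the mask
#' @param pixel_size pixel size (m), an integer multiple of the bin width
#' @return object of class `gi_stepping`: list with `pixels` (pixel centres)
#'   and `curve` (matrix pixels x steps)
#' @export
phase_step <- function(x, signal, mask_period, n_steps = 8, duty = 0.5,
                       pixel_size) {
  stopifnot(n_steps >= 3, length(x) == length(signal))
  dxb <- x[2] - x[1]
  m <- pixel_size / dxb
  if (abs(m - round(m)) > 1e-6)
    stop("pixel size must be an integer multiple of the bin width")
  m <- round(m)
  npix <- length(x) %/% m
  take <- seq_len(npix * m)
  pix_idx <- rep(seq_len(npix), each = m)
  curve <- matrix(0, npix, n_steps)
  for (s in seq_len(n_steps)) {
    shift <- (s - 1) * mask_period / n_steps
    frac <- ((x[take] - shift) / mask_period) %% 1
    # a bin centred exactly on a mask edge is half open; an explicit edge
    # tolerance keeps the classification consistent across steps (plain
    # comparison would resolve edge bins by floating-point accidents)
    tol <- 1e-7
    open <- as.numeric(frac < duty)
    open[abs(frac - duty) < tol | frac < tol | frac > 1 - tol] <- 0.5
    curve[, s] <- rowsum(signal[take] * open, pix_idx)[, 1]
  }
  structure(list(pixels = x[take][seq(1, npix * m, by = m)] + (m - 1) * dxb / 2,
                 curve = curve, mask_period = mask_period,
                 n_steps = n_steps, duty = duty),
            class = "gi_stepping")
}

#' Retrieve absorption and differential phase from stepping curves
#'
#' Per pixel, the stepping curves are reduced to their zeroth and first
#' Fourier components over the steps: absorption is the ratio of means
#' (sample / reference), DPC the first-harmonic phase difference wrapped to
#' `(-pi, pi]`, and visibility `2 |c1| / c0` is returned for both curves.
#'
#' @param sample,reference `gi_stepping` objects on the same grid
#' @return data frame with `x`, `absorption`, `dpc`, `vis_sample`,
#'   `vis_reference`
#' @export
retrieve_signals <- function(sample, reference) {
  stopifnot(ncol(sample$curve) == ncol(reference$curve),
            nrow(sample$curve) == nrow(reference$curve))
  fc <- function(curve) {
    n <- ncol(curve)
    ph <- 2 * pi * (seq_len(n) - 1) / n
    c0 <- rowMeans(curve)
    c1 <- curve %*% exp(-1i * ph) / n
    list(c0 = c0, c1 = as.vector(c1))
  }
  s <- fc(sample$curve); r <- fc(reference$curve)
  if (any(r$c0 == 0)) stop("zero reference mean in at least one pixel")
  data.frame(
    x = sample$pixels,
    absorption = s$c0 / r$c0,
    dpc = .wrap_pi(Arg(s$c1) - Arg(r$c1)),
    vis_sample = 2 * Mod(s$c1) / s$c0,
    vis_reference = 2 * Mod(r$c1) / r$c0
  )
}

#' Fringe visibility of a periodic signal
#'
#' First-Fourier-component estimator `v = 2 |c1| / c0` evaluated at the given
#' fringe period; robust against bin-level MC noise (the raw max/min
#' estimator is noise dominated).
#'
#' @param x sample positions (m), equally spaced over >= 1 full period
#' @param signal intensities
#' @param period fringe period (m)
#' @return visibility in `[0, ~1]`
#' @export
visibility <- function(x, signal, period) {
  if (all(signal == 0)) stop("visibility undefined for an all-zero signal")
  span <- diff(range(x))
  if (span < period) stop("signal must cover at least one full period")
  ph <- 2 * pi * x / period
  c0 <- mean(signal)
  c1 <- mean(signal * exp(-1i * ph))
  2 * Mod(c1) / c0
}

#' Pearson correlation and root-mean-squared error metrics
#'
#' `rmse()` compares two signals after the stated normalization:
#' `"mean"` scales both to unit mean (used for carpet comparisons),
#' `"sum"` to unit sum ("equal area under the curve", used for the slit
#' profiles), `"none"` compares raw values.
#'
#' @param a,b equal-length numeric vectors
#' @param normalize `"mean"`, `"sum"` or `"none"`
#' @export
rmse <- function(a, b, normalize = c("mean", "sum", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(length(a) == length(b))
  if (normalize == "mean") { a <- a / mean(a); b <- b / mean(b) }
  if (normalize == "sum")  { a <- a / sum(a);  b <- b / sum(b) }
  sqrt(mean((a - b)^2))
}

#' @rdname rmse
#' @export
pearson <- function(a, b) stats::cor(as.vector(a), as.vector(b))

#' Analyzer-grating visibility correction factor
#'
#' Classical estimate of the visibility loss from leakage through the
#' absorbing sections of a duty-0.5 analyzer grating:
#' `c_cor = (T_sub - T_abs) / (T_sub + T_abs)` with `T = exp(-mu t)` the
#' transmissions of the substrate (slit) and absorber sections. A perfect
#' absorber gives 1; equal transmissions give 0 (no modulation).
#'
#' @param E photon energy in keV
#' @param thickness grating thickness in metres
#' @param absorber absorber material (default `"Au"`)
#' @param substrate substrate / slit material (default `"Si"`)
#' @export
#' @examples
#' visibility_correction(21, 30e-6)  # ~0.96
visibility_correction <- function(E, thickness, absorber = "Au",
                                  substrate = "Si") {
  stopifnot(thickness > 0)
  T_sub <- exp(-mu_at(substrate, E) * thickness)
  T_abs <- exp(-mu_at(absorber, E) * thickness)
  (T_sub - T_abs) / (T_sub + T_abs)
}
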