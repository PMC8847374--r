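# Independent wave-optics reference: 1-D scalar fields propagated with the
# angular-spectrum (transfer-function) Fresnel method under periodic boundary
# conditions. Used to validate the Monte Carlo Talbot patterns; deliberately
# shares no code with the transport modules.

#' Create a 1-D complex field
#'
#' @param amplitude complex vector of samples (length should be even; powers
#'   of two give the fastest FFTs)
#' @param dx sample spacing in metres
#' @param wavelength wavelength in metres
#' @return object of class `gi_field`
#' @export
complex_field <- function(amplitude, dx, wavelength) {
  stopifnot(dx > 0, wavelength > 0, length(amplitude) >= 2)
  structure(list(amp = as.complex(amplitude), dx = dx, wavelength = wavelength,
                 x = (seq_along(amplitude) - 1) * dx),
            class = "gi_field")
}

#' Plane-wave field sampled over a window
#'
#' @param width window width in metres (periodic)
#' @param dx sample spacing in metres
#' @param E photon energy in keV
#' @export
plane_wave_field <- function(width, dx, E) {
  n <- round(width / dx)
  complex_field(rep(1 + 0i, n), dx, wavelength_from_energy(E))
}

#' Apply a thin optical element to a field
#'
#' Pointwise multiplication with the element's complex transmission function
#' `tau(x, k)`.
#'
#' @param field a `gi_field`
#' @param grating a `gi_grating` (see [gi_grating()])
#' @return the transmitted `gi_field`
#' @export
apply_element <- function(field, grating) {
  k <- 2 * pi / field$wavelength
  field$amp <- field$amp * grating_tau(grating, field$x, k)
  field
}

#' Fresnel propagation by the angular-spectrum transfer function
#'
#' Applies `H(f) = exp(-i pi lambda z f^2)` in frequency space (paraxial
#' transfer function, global phase `exp(ikz)` dropped). Periodic boundary
#' conditions; total power is conserved exactly. Rejects propagation whose
#' maximal quadratic phase is aliased on the given grid.
#'
#' Because the window is periodic, a field whose spectrum lives on the
#' discrete window harmonics (any grating whose period divides the window) is
#' propagated exactly; the classical Nyquist criterion on the quadratic
#' transfer-function phase only matters for fields with continuous spectra
#' and can be enforced with `check = "strict"`.
#'
#' @param field a `gi_field`
#' @param distance propagation distance in metres (may be 0 or negative)
#' @param check `"periodic"` (default) trusts the discrete spectrum;
#'   `"strict"` rejects propagation whose transfer-function phase is not
#'   resolved at the band edge
#' @return the propagated `gi_field`
#' @export
fresnel_propagate <- function(field, distance, check = c("periodic", "strict")) {
  check <- match.arg(check)
  n <- length(field$amp)
  f <- (((seq_len(n) - 1) + n %/% 2) %% n - n %/% 2) / (n * field$dx)
  if (check == "strict") {
    fmax <- 1 / (2 * field$dx)
    dphi <- 2 * pi * field$wavelength * abs(distance) * fmax * (1 / (n * field$dx))
    if (dphi > pi)
      stop("angular-spectrum propagation aliased: enlarge the window or the sampling")
  }
  H <- exp(-1i * pi * field$wavelength * distance * f^2)
  field$amp <- stats::fft(stats::fft(field$amp) * H, inverse = TRUE) / n
  field
}

#' Field intensity
#' @param field a `gi_field`
#' @return numeric vector `|amp|^2`
#' @export
field_intensity <- function(field) Re(field$amp * Conj(field$amp))

#' Wave-optics Talbot carpet
#'
#' Propagates a unit plane wave through a grating to each requested distance
#' and records the intensity, each row normalized to unit mean.
#'
#' @param grating a `gi_grating`
#' @param E photon energy in keV
#' @param distances grating-to-plane distances in metres
#' @param width lateral window in metres (default 4 grating periods)
#' @param dx sample spacing (default period/64)
#' @return matrix `length(distances) x n_samples` of intensities; attributes
#'   `x` (lateral positions) and `distances`
#' @export
talbot_carpet_oracle <- function(grating, E, distances,
                                 width = 4 * grating$period,
                                 dx = grating$period / 64) {
  stopifnot(all(distances > 0))
  f0 <- apply_element(plane_wave_field(width, dx, E), grating)
  out <- t(vapply(distances, function(z) {
    I <- field_intensity(fresnel_propagate(f0, z))
    I / mean(I)
  }, numeric(length(f0$amp))))
  attr(out, "x") <- f0$x
  attr(out, "distances") <- distances
  out
}
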