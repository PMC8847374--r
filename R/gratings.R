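# Optical elements: binary gratings described by complex transmission
# functions tau(x, k), with three transport strategies through them:
#   * huygens  - uniform fan-out into N equal-weight directions,
#   * fourier  - variance-reduced splitting into momentum transfers Q
#                weighted by the element's Fourier transform
#                (random sinc-weighted +/-Q pairs for absorption gratings,
#                 the discrete Fourier-series orders for phase gratings),
#   * mask     - classical binary mask (absorption gratings: discard or pass),
#   * implicit - multiply the weight by tau and tally the squared-weight
#                deficit as locally deposited energy.

#' Construct a grating element
#'
#' A binary periodic thin element at a fixed z plane. The open (slit) section
#' of width `duty * period` has transmission `tau_a`, the complementary
#' section `tau_b`. For physical gratings give `material` and `thickness`
#' instead of `tau_b`: then `tau_b = exp(i (n-1) k t)` relative to the slit
#' medium, evaluated per wavenumber at run time.
#'
#' @param z element plane position in metres
#' @param period grating period in metres
#' @param duty open fraction of the period (default 0.5)
#' @param mode transport strategy: `"fourier"`, `"huygens"`, `"mask"` or
#'   `"implicit"`
#' @param tau_a,tau_b complex transmission values of the two sections
#'   (defaults: transparent slit, opaque absorber)
#' @param material,thickness optional physical description of the non-slit
#'   section (overrides `tau_b`)
#' @param x0 lateral offset of the period origin in metres
#' @param n_split splitting number: Fourier order cutoff N for phase
#'   gratings, path count for Huygens splitting
#' @param q_max maximal |Q| for absorption-grating Fourier splitting, in
#'   units of 1/m (default `2 * 2*pi / a`, the range used for source
#'   gratings)
#' @param n_q number of random Q samples per splitting event (made even;
#'   samples always occur in +/- pairs)
#' @param angular_range full angular range of the Huygens fan in radians
#' @param slits optional integer vector of slit indices: restricts the open
#'   sections to those periods (e.g. `c(-1, 0)` for a double slit); other
#'   positions are treated as absorber
#' @return object of class `gi_grating`
#' @export
gi_grating <- function(z, period, duty = 0.5,
                       mode = c("fourier", "huygens", "mask", "implicit"),
                       tau_a = 1 + 0i, tau_b = 0 + 0i,
                       material = NULL, thickness = NULL,
                       x0 = 0, n_split = 5, q_max = NULL, n_q = 64,
                       angular_range = NULL, slits = NULL) {
  mode <- match.arg(mode)
  stopifnot(period > 0, duty > 0, duty < 1)
  a <- duty * period
  if (is.null(q_max)) q_max <- 2 * 2 * pi / a
  structure(list(z = z, period = period, duty = duty, a = a,
                 b = period - a, mode = mode,
                 tau_a = as.complex(tau_a), tau_b = as.complex(tau_b),
                 material = if (!is.null(material)) gi_material(material),
                 thickness = thickness, x0 = x0,
                 n_split = n_split, q_max = q_max, n_q = n_q,
                 angular_range = angular_range, slits = slits),
            class = "gi_grating")
}

#' @export
print.gi_grating <- function(x, ...) {
  cat(sprintf("<gi_grating> z = %g m, p = %g um, duty = %g, mode = %s\n",
              x$z, x$period * 1e6, x$duty, x$mode))
  invisible(x)
}

# section transmissions at wavenumber k (resolves physical gratings)
.grating_taus <- function(g, k) {
  tau_b <- g$tau_b
  if (!is.null(g$material)) {
    E <- k * .gi_const$hc_keV_m / (2 * pi)
    n_rel <- refractive_index(g$material, E)  # slit medium assumed vacuum-like
    tau_b <- exp(1i * (n_rel - 1) * k * g$thickness)
  }
  list(tau_a = g$tau_a + 0i, tau_b = tau_b)
}

#' Transmission function of a grating
#'
#' Binary periodic `tau(x, k)`: `tau_a` on `[j p + x0, j p + x0 + a)`,
#' `tau_b` elsewhere. With a `slits` restriction, periods outside the listed
#' slit indices take `tau_b` (or 0 for mask gratings).
#'
#' @param grating a `gi_grating`
#' @param x lateral positions in metres (vectorized)
#' @param k wavenumber in 1/m
#' @return complex transmission values
#' @export
grating_tau <- function(grating, x, k) {
  tt <- .grating_taus(grating, k)
  ifelse(.grating_open(x, grating), tt$tau_a, tt$tau_b)
}

# Deterministic section classification.  Positions are reduced to a
# fractional period coordinate rounded to 1e-9 of a period so that points
# sitting exactly on a section edge are classified identically in every
# period and at every lateral offset; a plain floating-point comparison
# would resolve such edge points by rounding accidents, breaking the exact
# periodicity of sampled transmission profiles.  Convention: the slit is
# the half-open interval [0, duty), so an edge point at the closing edge is
# opaque and one at the opening edge transparent.
.grating_open <- function(x, grating) {
  u <- round(((x - grating$x0) / grating$period) %% 1, 9)
  u[u >= 1] <- 0
  open <- u < round(grating$a / grating$period, 9)
  if (!is.null(grating$slits)) {
    j <- floor(round((x - grating$x0) / grating$period, 9))
    open <- open & (j %in% grating$slits)
  }
  open
}

#' Classical mask decision at an absorption grating
#'
#' The photon is discarded when its classical path hits an absorbing section
#' (`tau = 0`) and transmitted otherwise.
#'
#' @param x intersection positions in metres
#' @param grating an absorption-type `gi_grating` (`tau_b = 0`)
#' @return logical vector, `TRUE` = transmit
#' @export
g0_classical_mask <- function(x, grating) {
  .grating_open(x, grating)
}

#' Fourier-series coefficients of a binary grating
#'
#' Closed form of `tau_hat(n, k) = (1/p) int_0^p tau(x,k) exp(i 2 pi n x / p) dx`
#' for the binary profile (`tau_a` on `[0, a)`, `tau_b` on `[a, p)`):
#' `tau_hat(0) = (a tau_a + b tau_b)/p` and for n != 0
#' `tau_hat(n) = (tau_a - tau_b) (exp(i 2 pi n a/p) - 1) / (i 2 pi n)`.
#'
#' @param grating a `gi_grating`
#' @param k wavenumber in 1/m
#' @param N order cutoff (defaults to the grating's `n_split`)
#' @return complex vector of coefficients for orders `-N..N`
#' @export
g1_fourier_coeffs <- function(grating, k, N = grating$n_split) {
  tt <- .grating_taus(grating, k)
  n <- -N:N
  p <- grating$period; a <- grating$a
  cn <- ifelse(n == 0,
               (a * tt$tau_a + (p - a) * tt$tau_b) / p,
               (tt$tau_a - tt$tau_b) * (exp(1i * 2 * pi * n * a / p) - 1) /
                 (1i * 2 * pi * n))
  names(cn) <- n
  cn
}

# --- path-batch splitting operations -----------------------------------------
# A path batch is a list of equal-length vectors:
#   x, z    positions (m)            ux, uz   direction components (unit)
#   k       wavenumber (1/m)         w        complex amplitude weight
#   sw      statistical weight       hist     history id (integer)
#   mode    0 = interfering primary, 1 = ray-trace-only, 2 = secondary
#   nray    number of Rayleigh events on the path

#' Construct a path batch
#'
#' Vectorized container for piecewise-straight photon paths; all MC
#' operations act on whole batches.
#'
#' @param x,z positions in metres
#' @param ux,uz direction components (normalized internally)
#' @param k wavenumber in 1/m
#' @param w complex amplitude weight
#' @param sw statistical weight
#' @param hist integer history id
#' @param mode 0 interfering primary, 1 ray-trace-only primary, 2 secondary
#' @param nray number of Rayleigh events already on the path
#' @return object of class `gi_paths`
#' @export
path_batch <- function(x, z, ux = 0, uz = 1, k, w = 1 + 0i, sw = 1,
                       hist = seq_along(x), mode = 0L, nray = 0L) {
  n <- length(x)
  nrm <- sqrt(ux^2 + uz^2)
  b <- list(x = as.numeric(x), z = rep_len(as.numeric(z), n),
            ux = rep_len(ux / nrm, n), uz = rep_len(uz / nrm, n),
            k = rep_len(as.numeric(k), n), w = rep_len(as.complex(w), n),
            sw = rep_len(as.numeric(sw), n), hist = rep_len(as.integer(hist), n),
            mode = rep_len(as.integer(mode), n), nray = rep_len(as.integer(nray), n))
  structure(b, class = "gi_paths")
}

#' Number of paths in a batch
#' @param b a `gi_paths`
#' @export
n_paths <- function(b) length(b$x)

.subset_batch <- function(b, i) {
  structure(lapply(unclass(b), `[`, i), class = "gi_paths")
}

# replicate each path m times (keeps history ids)
.rep_batch <- function(b, m) {
  i <- rep(seq_along(b$x), each = m)
  .subset_batch(b, i)
}

#' Huygens splitting at an element
#'
#' Splits every incoming path into N outgoing paths with equal starting
#' positions, statistical weights, phases and norms, directions distributed
#' uniformly on an arc of the configured angular range about the incoming
#' direction. Amplitude weights are divided by `sqrt(N)` so that the summed
#' `|z|^2` is preserved. The element's transmission value at the
#' intersection multiplies the weight first.
#'
#' @param batch a `gi_paths` at the element plane
#' @param grating a `gi_grating` in huygens mode
#' @return the split `gi_paths`
#' @export
huygens_split <- function(batch, grating) {
  N <- grating$n_split
  stopifnot(N >= 1)
  rng <- grating$angular_range
  if (is.null(rng)) rng <- pi / 2
  tau <- grating_tau(grating, batch$x, batch$k)
  batch$w <- batch$w * tau
  out <- .rep_batch(batch, N)
  th <- atan2(out$ux, out$uz)
  dth <- if (N > 1) rep(seq(-rng / 2, rng / 2, length.out = N), times = n_paths(batch)) else 0
  th <- th + dth
  out$ux <- sin(th); out$uz <- cos(th)
  out$w <- out$w / sqrt(N)
  out$sw <- out$sw / N
  out
}

#' Fourier splitting at an absorption grating
#'
#' Paths transmitted by the classical mask fork into `n_q` paths with random
#' transverse momentum transfers drawn uniformly from `(0, q_max]` and always
#' mirrored to `+/-Q` pairs (no net drift). Each outgoing path carries the
#' complex weight
#' `z = N exp(i Q (c_j - x)) sin(Q a / 2) / (Q / 2)`
#' where `c_j` is the centre of the hit slit and the normalization enforces
#' `sum |z|^2 = 1` per splitting event. Outgoing `k_x' = k_x - Q` with |k|
#' conserved. Paths hitting an absorbing section are dropped (their indices
#' are returned in the `absorbed` attribute).
#'
#' @param batch a `gi_paths` at the grating plane
#' @param grating an absorption `gi_grating` in fourier mode
#' @return the split `gi_paths`; attribute `absorbed` holds the indices of
#'   masked paths in the incoming batch
#' @export
g0_fourier_split <- function(batch, grating) {
  keep <- g0_classical_mask(batch$x, grating)
  absorbed <- which(!keep)
  batch <- .subset_batch(batch, keep)
  n_in <- n_paths(batch)
  half <- max(1L, grating$n_q %/% 2L)
  if (grating$q_max >= min(batch$k, Inf)) stop("q_max must be below the wavenumber")
  m <- 2L * half
  out <- .rep_batch(batch, m)
  Q <- stats::runif(n_in * half, min = 0, max = grating$q_max)
  Q <- as.vector(rbind(Q, -Q))           # +/- pairs, interleaved
  a <- grating$a
  # centre of the hit slit
  j <- floor((out$x - grating$x0) / grating$period)
  cj <- grating$x0 + j * grating$period + a / 2
  zj <- exp(1i * Q * (cj - out$x)) * sin(Q * a / 2) / (Q / 2)
  # normalize sum |z|^2 = 1 within each splitting event
  ev <- rep(seq_len(n_in), each = m)
  nrm <- sqrt(rowsum(Re(zj * Conj(zj)), ev)[, 1])
  zj <- zj / nrm[ev]
  out$w <- out$w * zj
  # direction change: k_x' = k_x - Q, |k| conserved
  kx <- out$k * out$ux - Q
  kz2 <- out$k^2 - kx^2
  if (any(kz2 <= 0)) stop("non-physical deflection: |k_x'| >= k")
  out$ux <- kx / out$k
  out$uz <- sqrt(kz2) / out$k
  out$sw <- out$sw * Re(zj * Conj(zj))  # statistical mass follows |z|^2
  attr(out, "absorbed") <- absorbed
  out
}

#' Fourier splitting at a phase grating
#'
#' Every incoming path forks into the `2N+1` Fourier orders of the grating:
#' order n leaves with `k_x' = k_x - 2 pi n / p` (|k| conserved) and weight
#' `z_n = tau_hat(n, k) exp(-i 2 pi n x_cl / p)` with `x_cl` the classical
#' intersection point; weights are renormalized to `sum |z_n|^2 = 1`
#' (Parseval). All paths are transported independent of where they intersect
#' the grating.
#'
#' For absorbing phase structures (|tau| < 1) the summed `|z_n|^2` equals the
#' mean squared transmission `mean |tau|^2` (Parseval, truncation
#' compensated): the amplitude then carries the grating absorption. The
#' statistical weights follow either the same deficit (`sw_mode =
#' "parseval"`, used with implicit gratings where the deficit is deposited
#' locally) or stay normalized to the parent weight (`sw_mode =
#' "normalized"`, used with explicit grating geometries whose absorption is
#' sampled as interactions).
#'
#' @param batch a `gi_paths` at the grating plane
#' @param grating a phase `gi_grating` in fourier mode
#' @param drop_zero drop orders with |z| = 0 (default TRUE; saves work for
#'   e.g. the vanishing even orders of a duty-0.5 pi grating)
#' @param sw_mode statistical-weight convention, see Details
#' @return the split `gi_paths`; attribute `absorbed_frac` holds the
#'   per-parent statistical weight removed by the grating absorption
#' @export
g1_split <- function(batch, grating, drop_zero = TRUE,
                     sw_mode = c("parseval", "normalized")) {
  sw_mode <- match.arg(sw_mode)
  N <- grating$n_split
  mono <- length(unique(batch$k)) == 1L
  ns <- -N:N
  if (mono) {
    tt <- .grating_taus(grating, batch$k[1])
    meanT2 <- grating$duty * Mod(tt$tau_a)^2 +
      (1 - grating$duty) * Mod(tt$tau_b)^2
    cn <- g1_fourier_coeffs(grating, batch$k[1])
    cn <- cn * sqrt(meanT2 / sum(Re(cn * Conj(cn))))
    if (drop_zero) {
      keep <- Mod(cn) > 1e-14
      cn <- cn[keep]; ns <- ns[keep]
    }
  }
  m <- length(ns)
  if (any(abs(2 * pi * max(abs(ns)) / grating$period) >= batch$k))
    stop("Fourier order deflection exceeds the wavenumber")
  out <- .rep_batch(batch, m)
  nn <- rep(ns, times = n_paths(batch))
  if (mono) {
    zn <- rep(cn, times = n_paths(batch))
  } else {
    # per-path coefficients (polychromatic batch): closed form of the binary
    # profile at each path's wavenumber, Parseval-scaled per splitting event
    tt <- .grating_taus(grating, out$k)
    ta <- tt$tau_a + 0 * out$k; tb <- tt$tau_b + 0 * out$k
    p <- grating$period; a <- grating$a
    meanT2_v <- grating$duty * Mod(ta)^2 + (1 - grating$duty) * Mod(tb)^2
    zn <- ifelse(nn == 0,
                 (a * ta + (p - a) * tb) / p,
                 (ta - tb) * (exp(1i * 2 * pi * nn * a / p) - 1) /
                   (1i * 2 * pi * nn))
    ev <- rep(seq_len(n_paths(batch)), each = m)
    nrm <- sqrt(rowsum(Re(zn * Conj(zn)), ev)[, 1] /
                  meanT2_v[seq(1, length(meanT2_v), by = m)])
    zn <- zn / nrm[ev]
  }
  zn <- unname(zn) *
    exp(-1i * 2 * pi * nn * (out$x - grating$x0) / grating$period)
  out$w <- out$w * zn
  kx <- out$k * out$ux - 2 * pi * nn / grating$period
  kz2 <- out$k^2 - kx^2
  out$ux <- kx / out$k
  out$uz <- sqrt(kz2) / out$k
  z2 <- Re(zn * Conj(zn))
  if (mono) {
    if (sw_mode == "parseval") {
      out$sw <- out$sw * z2
      attr(out, "absorbed_frac") <- batch$sw * (1 - meanT2)
    } else {
      out$sw <- out$sw * z2 / meanT2
      attr(out, "absorbed_frac") <- rep(0, n_paths(batch))
    }
  } else {
    meanT2_p <- meanT2_v
    if (sw_mode == "parseval") {
      out$sw <- out$sw * z2
      attr(out, "absorbed_frac") <-
        batch$sw * (1 - meanT2_p[seq(1, length(meanT2_p), by = m)])
    } else {
      out$sw <- out$sw * z2 / meanT2_p
      attr(out, "absorbed_frac") <- rep(0, n_paths(batch))
    }
  }
  out
}

#' Implicit attenuation at a grating
#'
#' Multiplies the amplitude weight by `tau(x, k)` (magnitude and phase) and
#' reduces the statistical weight by `|tau|^2`; the squared-weight deficit is
#' returned as energy fraction deposited in the element.
#'
#' @param batch a `gi_paths` at the grating plane
#' @param grating a `gi_grating` in implicit mode
#' @return the batch with updated weights; attribute `deposit_sw` holds the
#'   per-path statistical weight deposited in the grating
#' @export
implicit_attenuation <- function(batch, grating) {
  tau <- grating_tau(grating, batch$x, batch$k)
  t2 <- Re(tau * Conj(tau))
  attr(batch, "deposit_sw") <- batch$sw * (1 - t2)
  batch$w <- batch$w * tau
  batch$sw <- batch$sw * t2
  batch
}
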