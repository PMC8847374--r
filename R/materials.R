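# Material optical constants for hard X-rays.
#
# Each medium carries the refractive-index decrement delta at the 17 keV
# reference energy (scaled to other energies by the lambda^2 law) and linear
# attenuation coefficients tabulated on a 5--100 keV grid, split into
# photoelectric, incoherent (Compton) and coherent (Rayleigh) channels.
# Absorption-edge fine structure is deliberately smoothed out: all bundled
# media are used far from their K edges in the 10--40 keV window the
# simulations operate in.

#' Physical constants used throughout the package
#'
#' CODATA values. `hc_keV_m` is the photon energy-wavelength conversion
#' constant in keV*m, `r_e` the classical electron radius in m,
#' `mec2_keV` the electron rest energy in keV.
#'
#' @keywords internal
.gi_const <- list(
  hc_keV_m = 1.23984193e-9,
  r_e      = 2.8179403262e-15,
  mec2_keV = 510.99895,
  N_A      = 6.02214076e23
)

# Mass attenuation anchors, cm^2/g, on a common energy grid (keV).
# Transcribed from standard photon mass-attenuation compilations;
# log-log interpolation between nodes. Edge structure between nodes is not
# represented (see package vignette).
.gi_mu_grid_keV <- c(4, 5, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100)

.gi_mu_rho <- list(
  Si  = c(479.0, 245.3, 147.0, 64.68, 33.89, 10.03, 4.464, 1.436, 0.7012,
          0.4385, 0.3207, 0.2228, 0.1835),
  Au  = c(1380.0, 725.0, 430.0, 240.0, 113.4, 170.0, 78.83, 24.60, 10.80,
          5.840, 3.650, 1.750, 5.160),
  Ir  = c(1330.0, 700.0, 420.0, 232.0, 120.0, 165.0, 74.50, 23.60, 10.40,
          5.600, 3.500, 1.850, 3.600),
  polystyrene = c(34.3, 17.65, 10.13, 4.252, 2.219, 0.7739, 0.4364, 0.2640,
                  0.2183, 0.1986, 0.1869, 0.1724, 0.1625),
  air = c(78.2, 40.31, 23.41, 9.921, 5.120, 1.614, 0.7779, 0.3538, 0.2485,
          0.2080, 0.1875, 0.1662, 0.1541)
)

# density g/cm^3, effective Z/A (electrons per amu), effective Z for the
# binding-suppression scale of the incoherent channel, and Z^2/A-type
# coefficient of the coherent-channel power law (anchored at 10 keV).
.gi_mat_props <- list(
  Si          = list(density = 2.33,    zoa = 14 / 28.085, zeff = 14,  coh10 = 0.470),
  Au          = list(density = 19.32,   zoa = 79 / 196.97, zeff = 79,  coh10 = 2.160),
  Ir          = list(density = 22.56,   zoa = 77 / 192.22, zeff = 77,  coh10 = 2.100),
  polystyrene = list(density = 1.06,    zoa = 56 / 104.15, zeff = 5.7, coh10 = 0.193),
  air         = list(density = 1.205e-3, zoa = 0.499,      zeff = 7.3, coh10 = 0.250)
)

#' Photon wavelength from energy
#'
#' @param E photon energy in keV (vectorized, must be positive)
#' @return wavelength in metres, `lambda = hc / E`
#' @export
#' @examples
#' wavelength_from_energy(20)  # ~6.199e-11 m
wavelength_from_energy <- function(E) {
  if (any(!is.finite(E)) || any(E <= 0)) stop("photon energy must be positive")
  .gi_const$hc_keV_m / E
}

#' Photon wavenumber from energy
#'
#' @param E photon energy in keV
#' @return wavenumber `k = 2*pi/lambda` in 1/m
#' @export
wavenumber_from_energy <- function(E) 2 * pi / wavelength_from_energy(E)

# total Klein-Nishina cross section per electron, barn
.kn_total_barn <- function(E_keV) {
  eps <- E_keV / .gi_const$mec2_keV
  r_e_cm <- .gi_const$r_e * 100
  pre <- 2 * pi * r_e_cm^2 / 1e-24   # barn
  t1 <- (1 + eps) / eps^2 * (2 * (1 + eps) / (1 + 2 * eps) - log(1 + 2 * eps) / eps)
  t2 <- log(1 + 2 * eps) / (2 * eps)
  t3 <- -(1 + 3 * eps) / (1 + 2 * eps)^2
  pre * (t1 + t2 + t3)
}

# build one material's attenuation tables (1/m) on the common grid
.build_material <- function(name) {
  p <- .gi_mat_props[[name]]
  E <- .gi_mu_grid_keV
  mu_rho_tot <- .gi_mu_rho[[name]]
  # incoherent: free-electron Klein-Nishina times a smooth binding suppression
  supp <- E^2 / (E^2 + (1.2 * p$zeff^0.7)^2)
  mu_rho_incoh <- 0.60221 * p$zoa * .kn_total_barn(E) * supp
  # coherent: Z^2/A-scaled power law anchored at 10 keV
  mu_rho_coh <- p$coh10 * (10 / E)^1.9
  mu_rho_photo <- pmax(mu_rho_tot - mu_rho_incoh - mu_rho_coh, 1e-6)
  to_inv_m <- p$density * 100   # (cm^2/g)*(g/cm^3) -> 1/cm -> 1/m
  structure(list(
    name      = name,
    density   = p$density,
    delta_ref = .delta_ref(name),
    E_grid    = E,
    mu_total  = (mu_rho_photo + mu_rho_incoh + mu_rho_coh) * to_inv_m,
    mu_photo  = mu_rho_photo * to_inv_m,
    mu_incoh  = mu_rho_incoh * to_inv_m,
    mu_coh    = mu_rho_coh * to_inv_m
  ), class = "gi_material")
}

# refractive-index decrement at the 17 keV reference energy:
# delta = r_e * lambda^2 * n_e / (2 pi), with n_e from density and Z/A
.delta_ref <- function(name) {
  p <- .gi_mat_props[[name]]
  lam <- wavelength_from_energy(17)
  n_e <- p$density * 1e6 * .gi_const$N_A * p$zoa   # electrons / m^3
  .gi_const$r_e * lam^2 * n_e / (2 * pi)
}

.gi_registry <- new.env(parent = emptyenv())

#' Look up a material by name
#'
#' Registry of the bundled media: `"vacuum"`, `"air"`, `"Si"`, `"Au"`,
#' `"Ir"`, `"polystyrene"`. Pseudo-media combining the cross sections of one
#' medium with the phase shift of another are addressable as
#' `"cross-sections-of-<X>-phase-of-<Y>"` (see [phase_neutral_medium()]).
#'
#' @param name material name (case sensitive)
#' @return an object of class `gi_material`
#' @export
#' @examples
#' si <- gi_material("Si")
#' delta_at(si, 17)
gi_material <- function(name) {
  if (inherits(name, "gi_material")) return(name)
  stopifnot(is.character(name), length(name) == 1)
  if (name == "vacuum") {
    return(structure(list(
      name = "vacuum", density = 0, delta_ref = 0,
      E_grid = .gi_mu_grid_keV,
      mu_total = rep(0, length(.gi_mu_grid_keV)),
      mu_photo = rep(0, length(.gi_mu_grid_keV)),
      mu_incoh = rep(0, length(.gi_mu_grid_keV)),
      mu_coh   = rep(0, length(.gi_mu_grid_keV))
    ), class = "gi_material"))
  }
  m <- re <- regmatches(name, regexec("^cross-sections-of-(.+)-phase-of-(.+)$", name))[[1]]
  if (length(re) == 3) {
    return(phase_neutral_medium(gi_material(re[2]), gi_material(re[3])))
  }
  if (is.null(.gi_registry[[name]])) {
    if (!name %in% names(.gi_mu_rho)) stop("unknown material: ", name)
    .gi_registry[[name]] <- .build_material(name)
  }
  .gi_registry[[name]]
}

#' Names of the bundled media
#' @return character vector
#' @export
material_names <- function() c("vacuum", names(.gi_mu_rho))

#' @export
print.gi_material <- function(x, ...) {
  cat(sprintf("<gi_material> %s  (rho = %g g/cm^3, delta(17 keV) = %.4g)\n",
              x$name, x$density, x$delta_ref))
  invisible(x)
}

#' Refractive-index decrement delta at a given energy
#'
#' Scales the bundled 17 keV reference value by the lambda^2 law,
#' `delta(E) = delta_ref * (lambda(E)/lambda(17 keV))^2 = delta_ref * (17/E)^2`.
#'
#' @param material a `gi_material` or material name
#' @param E photon energy in keV
#' @return dimensionless decrement
#' @export
delta_at <- function(material, E) {
  m <- gi_material(material)
  if (any(E <= 0)) stop("photon energy must be positive")
  m$delta_ref * (17 / E)^2
}

#' Linear attenuation coefficient at a given energy
#'
#' Log-log interpolation of the bundled table. No extrapolation: energies
#' outside the table range are rejected.
#'
#' @param material a `gi_material` or material name
#' @param E photon energy in keV (vectorized)
#' @param channel one of `"total"`, `"photo"`, `"incoh"`, `"coh"`
#' @return linear attenuation coefficient in 1/m
#' @export
mu_at <- function(material, E, channel = c("total", "photo", "incoh", "coh")) {
  m <- gi_material(material)
  channel <- match.arg(channel)
  if (any(E < min(m$E_grid)) || any(E > max(m$E_grid)))
    stop("energy outside bundled attenuation table range (",
         min(m$E_grid), "-", max(m$E_grid), " keV)")
  mu <- m[[paste0("mu_", if (channel == "total") "total" else channel)]]
  if (all(mu == 0)) return(rep(0, length(E)))
  exp(stats::approx(log(m$E_grid), log(mu), xout = log(E), ties = "ordered")$y)
}

#' Imaginary part of the refractive index
#'
#' `beta = mu / (2 k)`, so that the intensity of a wave traversing a
#' thickness d decays as `exp(-mu d)` (Beer-Lambert).
#'
#' @inheritParams mu_at
#' @return dimensionless beta
#' @export
beta_at <- function(material, E) {
  mu_at(material, E) / (2 * wavenumber_from_energy(E))
}

#' Complex refractive index `n = 1 - delta + i beta`
#' @inheritParams mu_at
#' @return complex refractive index
#' @export
refractive_index <- function(material, E) {
  1 - delta_at(material, E) + 1i * beta_at(material, E)
}

#' Thickness giving a pi phase shift
#'
#' A slab of thickness t shifts the phase relative to vacuum by
#' `delta * k * t`; the pi-shift thickness is `t = lambda / (2 delta(E))`.
#'
#' @inheritParams mu_at
#' @return thickness in metres
#' @export
#' @examples
#' pi_phase_thickness("Si", 19)  # ~25 um
pi_phase_thickness <- function(material, E) {
  d <- delta_at(material, E)
  if (any(d <= 0)) stop("pi-phase thickness undefined for vacuum-like media")
  wavelength_from_energy(E) / (2 * d)
}

#' Pseudo-medium with one material's cross sections and another's phase shift
#'
#' Used to fill explicit grating geometries without double counting the phase
#' shift already applied by the grating's transmission function: the medium
#' interacts (and attenuates statistically) like `base` but shifts the phase
#' like `phase_like` (air by default).
#'
#' @param base material providing the attenuation/interaction cross sections
#' @param phase_like material providing delta (default `"air"`)
#' @return a `gi_material`
#' @export
phase_neutral_medium <- function(base, phase_like = "air") {
  b <- gi_material(base); p <- gi_material(phase_like)
  out <- b
  out$name <- paste0("cross-sections-of-", b$name, "-phase-of-", p$name)
  out$delta_ref <- p$delta_ref
  out
}
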