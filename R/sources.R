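# Photon sources: coherent plane waves (amplitudes interfere across all
# histories), coherent point sources, and incoherent polychromatic line
# sources (classical photons; amplitudes interfere only within one history's
# splitting descendants).

#' Idealized filtered triangle X-ray tube spectrum
#'
#' Piecewise-linear density rising from `cutoff_low` to the peak and falling
#' to zero at `E_max`. The default low cutoff of 4 keV makes the mean energy
#' of the (4, 19, 40) keV triangle exactly (4+19+40)/3 = 21 keV, the mean of
#' the filtered 40 kVp spectrum peaked at the 19 keV design energy.
#'
#' @param peak peak (mode) energy in keV
#' @param E_max maximal energy in keV
#' @param cutoff_low low-energy filter cutoff in keV
#' @return object of class `gi_spectrum` with a fine grid of energies and
#'   normalized weights
#' @export
triangle_spectrum <- function(peak = 19, E_max = 40, cutoff_low = 4) {
  if (!(cutoff_low < peak && peak < E_max)) stop("require cutoff_low < peak < E_max")
  E <- seq(cutoff_low, E_max, length.out = 512)
  w <- ifelse(E <= peak, (E - cutoff_low) / (peak - cutoff_low),
              (E_max - E) / (E_max - peak))
  w <- pmax(w, 0); w <- w / sum(w)
  structure(list(E = E, w = w, a = cutoff_low, m = peak, b = E_max,
                 description = sprintf("triangle %g-%g keV, peak %g keV",
                                       cutoff_low, E_max, peak)),
            class = "gi_spectrum")
}

#' Mean energy of a spectrum
#' @param sp a `gi_spectrum`
#' @export
spectrum_mean <- function(sp) sum(sp$E * sp$w)

#' Sample energies from a spectrum
#'
#' Triangular spectra are sampled by the closed-form inverse CDF; generic
#' spectra by discrete sampling of the grid weights.
#'
#' @param sp a `gi_spectrum`
#' @param n number of samples
#' @return energies in keV
#' @export
sample_spectrum <- function(sp, n) {
  if (!is.null(sp$a)) {
    u <- stats::runif(n)
    Fc <- (sp$m - sp$a) / (sp$b - sp$a)
    ifelse(u < Fc,
           sp$a + sqrt(u * (sp$b - sp$a) * (sp$m - sp$a)),
           sp$b - sqrt((1 - u) * (sp$b - sp$a) * (sp$b - sp$m)))
  } else {
    sample(sp$E, n, replace = TRUE, prob = sp$w)
  }
}

#' Source models
#'
#' * `source_plane_wave()`: coherent monochromatic plane wave realized as
#'   axial paths whose starting x positions cover `extent`; by default the
#'   positions are stratified (one jittered sample per equal sub-interval),
#'   which suppresses path-count fluctuations at the detector.
#' * `source_point()`: coherent spherical wave from a fixed point, directions
#'   collimated onto a target interval at a given plane.
#' * `source_incoherent()`: classical photons with sharply defined position
#'   and momentum: Gaussian line positions (FWHM in m), energies from a
#'   spectrum, directions collimated onto the detector aperture.
#'
#' @param extent numeric length-2, lateral extent of the source plane (m)
#' @param E photon energy in keV
#' @param n_histories number of histories
#' @param z source plane position (default 0)
#' @param stratified logical, stratify starting positions
#' @return object of class `gi_source`
#' @export
source_plane_wave <- function(extent, E, n_histories, z = 0, stratified = TRUE) {
  structure(list(type = "plane-wave", extent = extent, E = E,
                 n_histories = as.integer(n_histories), z = z,
                 stratified = stratified, coherent = TRUE),
            class = "gi_source")
}

#' @rdname source_plane_wave
#' @param position numeric length-2 (x, z) of the point source
#' @param aim_extent numeric length-2 lateral interval the fan is collimated
#'   onto
#' @param aim_z plane of the collimation target
#' @export
source_point <- function(position, E, n_histories, aim_extent, aim_z,
                         stratified = TRUE) {
  structure(list(type = "point", position = position, E = E,
                 n_histories = as.integer(n_histories),
                 aim_extent = aim_extent, aim_z = aim_z,
                 stratified = stratified, coherent = TRUE),
            class = "gi_source")
}

#' @rdname source_plane_wave
#' @param spectrum a `gi_spectrum` (or single energy in keV)
#' @param fwhm full width at half maximum of the Gaussian line source (m)
#' @export
source_incoherent <- function(spectrum, fwhm, n_histories, aim_extent, aim_z,
                              z = 0) {
  if (is.numeric(spectrum)) spectrum <- list(E = spectrum, w = 1)
  stopifnot(fwhm > 0)
  structure(list(type = "incoherent", spectrum = spectrum, fwhm = fwhm,
                 n_histories = as.integer(n_histories),
                 aim_extent = aim_extent, aim_z = aim_z, z = z,
                 coherent = FALSE),
            class = "gi_source")
}

#' @export
print.gi_source <- function(x, ...) {
  cat(sprintf("<gi_source> %s, %d histories\n", x$type, x$n_histories))
  invisible(x)
}

#' Emit a block of histories from a source
#'
#' Returns the initial `gi_paths` for histories `first..first+n-1` (unit
#' weight each; for coherent sources the amplitudes of *all* histories are
#' later added on the detector, for incoherent sources only within one
#' history).
#'
#' @param source a `gi_source`
#' @param n number of histories to emit
#' @param first index of the first history (for stratification bookkeeping)
#' @return a `gi_paths`
#' @export
emit_histories <- function(source, n = source$n_histories, first = 1L) {
  idx <- seq.int(first, length.out = n)
  if (source$type == "plane-wave") {
    x <- .strat_positions(source$extent, idx, source$n_histories,
                          source$stratified)
    path_batch(x = x, z = source$z, ux = 0, uz = 1,
               k = wavenumber_from_energy(source$E), hist = idx)
  } else if (source$type == "point") {
    xt <- .strat_positions(source$aim_extent, idx, source$n_histories,
                           source$stratified)
    dx <- xt - source$position[1]
    dz <- source$aim_z - source$position[2]
    path_batch(x = rep(source$position[1], n), z = source$position[2],
               ux = dx, uz = dz,
               k = wavenumber_from_energy(source$E), hist = idx)
  } else {
    E <- if (inherits(source$spectrum, "gi_spectrum"))
      sample_spectrum(source$spectrum, n) else rep(source$spectrum$E[1], n)
    sd <- source$fwhm / (2 * sqrt(2 * log(2)))
    x0 <- stats::rnorm(n, 0, sd)
    xt <- stats::runif(n, source$aim_extent[1], source$aim_extent[2])
    dz <- source$aim_z - source$z
    path_batch(x = x0, z = source$z, ux = xt - x0, uz = dz,
               k = wavenumber_from_energy(E), hist = idx)
  }
}

# stratified or uniform positions over an interval (length-2 vector) or a
# union of intervals (2-column matrix, one interval per row) for history
# indices idx
.strat_positions <- function(extent, idx, n_total, stratified) {
  if (is.matrix(extent)) {
    len <- extent[, 2] - extent[, 1]
    cum <- c(0, cumsum(len))
    tot <- cum[length(cum)]
    u01 <- if (stratified) (idx - stats::runif(length(idx))) / n_total
           else stats::runif(length(idx))
    s <- u01 * tot
    iv <- findInterval(s, cum, rightmost.closed = TRUE)
    iv[iv > nrow(extent)] <- nrow(extent)
    extent[iv, 1] + (s - cum[iv])
  } else if (stratified) {
    u <- stats::runif(length(idx))
    extent[1] + (idx - u) / n_total * (extent[2] - extent[1])
  } else {
    stats::runif(length(idx), extent[1], extent[2])
  }
}
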