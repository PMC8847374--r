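# Detector: fine "data point" bins accumulating complex path amplitudes,
# closed per coherence cohort into intensities, plus an incoherent scatter
# channel, then rebinned to physical pixels.

#' Create a detector grid
#'
#' @param z detector plane position in metres
#' @param x_min,x_max lateral range in metres
#' @param bin_width data-point bin width in metres (choose <= expected fringe
#'   period / 8; scenario builders default to period/16)
#' @param pixel_size physical pixel size in metres (integer multiple of
#'   `bin_width`; default 16 bins)
#' @return object of class `gi_detector`
#' @export
detector_grid <- function(z, x_min, x_max, bin_width, pixel_size = 16 * bin_width) {
  stopifnot(x_max > x_min, bin_width > 0)
  n <- floor((x_max - x_min) / bin_width + 1e-9)
  structure(list(
    z = z, x_min = x_min, bin_width = bin_width, n_bins = n,
    pixel_size = pixel_size,
    x = x_min + (seq_len(n) - 0.5) * bin_width,
    f_re = numeric(n), f_im = numeric(n),   # open-cohort complex field
    counts = numeric(n),                    # open-cohort path counts
    intensity = numeric(n),                 # closed (primary) intensity
    scatter = numeric(n),                   # incoherent scatter channel
    n_escaped = 0
  ), class = "gi_detector")
}

#' @export
print.gi_detector <- function(x, ...) {
  cat(sprintf("<gi_detector> z = %g m, %d bins of %g um, pixel %g um\n",
              x$z, x$n_bins, x$bin_width * 1e6, x$pixel_size * 1e6))
  invisible(x)
}

# bin index for positions (NA outside)
.det_bin <- function(det, x) {
  i <- floor((x - det$x_min) / det$bin_width) + 1
  i[i < 1 | i > det$n_bins] <- NA_integer_
  as.integer(i)
}

#' Accumulate paths on the detector
#'
#' Interfering paths (`mode < 2`) add their complex weights coherently to the
#' open cohort's field; scattered/secondary paths (`mode == 2`) add
#' `|w|^2 * sw` to the separate incoherent scatter channel. Endpoints outside
#' the lateral range count as escaped.
#'
#' @param det a `gi_detector`
#' @param batch a `gi_paths` whose endpoints lie on the detector plane
#' @return the updated `gi_detector`
#' @export
det_accumulate <- function(det, batch) {
  i <- .det_bin(det, batch$x)
  ok <- !is.na(i)
  det$n_escaped <- det$n_escaped + sum(!ok)
  coh <- ok & batch$mode < 2L
  if (any(coh)) {
    ii <- i[coh]
    det$f_re <- det$f_re + .bin_sum(Re(batch$w[coh]), ii, det$n_bins)
    det$f_im <- det$f_im + .bin_sum(Im(batch$w[coh]), ii, det$n_bins)
    det$counts <- det$counts + .bin_sum(rep(1, sum(coh)), ii, det$n_bins)
  }
  sc <- ok & batch$mode == 2L
  if (any(sc)) {
    w2 <- Re(batch$w[sc] * Conj(batch$w[sc])) * batch$sw[sc]
    det$scatter <- det$scatter + .bin_sum(w2, i[sc], det$n_bins)
  }
  det
}

.bin_sum <- function(v, idx, n) {
  out <- numeric(n)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Close a coherence cohort
#'
#' Squares the accumulated complex field into intensity and clears it.
#' With `normalization = "per-bin-paths-squared"` each data point is divided
#' by its path count squared before being added (used to suppress
#' path-count fluctuations in coherent-source runs).
#'
#' @param det a `gi_detector`
#' @param normalization `"none"` or `"per-bin-paths-squared"`
#' @return the updated `gi_detector`
#' @export
close_cohort <- function(det, normalization = c("none", "per-bin-paths-squared")) {
  normalization <- match.arg(normalization)
  if (all(det$counts == 0) && all(det$f_re == 0) && all(det$f_im == 0)) {
    return(det)   # empty cohort: no-op
  }
  I <- det$f_re^2 + det$f_im^2
  if (normalization == "per-bin-paths-squared") {
    nz <- det$counts > 0
    I[nz] <- I[nz] / det$counts[nz]^2
    I[!nz] <- 0
  }
  det$intensity <- det$intensity + I
  det$f_re[] <- 0; det$f_im[] <- 0; det$counts[] <- 0
  det
}

#' Rebin data points to pixels
#'
#' Sums bin intensities per pixel (primary and scatter channels separately
#' and combined). The pixel size must be a whole number of bins; a trailing
#' remainder of bins is dropped.
#'
#' @param det a `gi_detector` (cohorts closed)
#' @param pixel_size pixel size in metres (default from the grid)
#' @return list with `x` (pixel centres), `primary`, `scatter`, `signal`
#' @export
rebin_to_pixels <- function(det, pixel_size = det$pixel_size) {
  m <- pixel_size / det$bin_width
  if (abs(m - round(m)) > 1e-6)
    stop("pixel size must be an integer multiple of the bin width")
  m <- round(m)
  npix <- det$n_bins %/% m
  idx <- rep(seq_len(npix), each = m)
  take <- seq_len(npix * m)
  primary <- unname(rowsum(det$intensity[take], idx)[, 1])
  scatter <- unname(rowsum(det$scatter[take], idx)[, 1])
  list(x = det$x_min + (seq_len(npix) - 0.5) * pixel_size,
       primary = primary, scatter = scatter, signal = primary + scatter)
}
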