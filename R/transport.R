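# Piecewise-straight photon transport in the (x, z) plane.
#
# Paths advance from one z plane to the next through a region geometry
# (background medium plus axis-aligned slabs and y-axis cylinders); over each
# traversed segment the complex weight is multiplied by the medium amplitude
# exp(i n_m k d) (and optionally the geometric 1/r norm), and directions
# refract at cylinder surfaces via Snell's law with the total-reflection
# branch.  Grating lines run along y, so all deflections are in-plane.

#' Medium transition amplitude between two points
#'
#' `A_m(r, r') = exp(i n_m k |r - r'|) / |r - r'|` with
#' `n_m = 1 - delta + i beta`; the imaginary part yields the Beer-Lambert
#' magnitude `exp(-mu d / 2) / d`.
#'
#' @param r,r_prime numeric length-2 vectors (x, z) or 2-column matrices, m
#' @param medium a `gi_material` or name
#' @param k wavenumber in 1/m
#' @return complex amplitude(s)
#' @export
amplitude_factor <- function(r, r_prime, medium, k) {
  r <- rbind(r); r_prime <- rbind(r_prime)
  d <- unname(sqrt(rowSums((r - r_prime)^2)))
  if (any(d <= 0)) stop("zero-length segment")
  E <- k * .gi_const$hc_keV_m / (2 * pi)
  n_m <- refractive_index(medium, E)
  exp(1i * n_m * k * d) / d
}

#' Snell refraction at a planar piece of interface
#'
#' Refracts unit directions across an interface with normal `nrm`
#' (any orientation) from real index `nA` into `nB`; preserves the
#' tangential component (`nA sin thA = nB sin thB`). Where `sin thB` would
#' exceed 1, specular total reflection is returned with `tau = -1`,
#' otherwise `tau = 1`.
#'
#' @param ux,uz incoming unit direction components (vectorized)
#' @param nx,nz interface normal components (vectorized, unit)
#' @param nA,nB real refractive indices of the incidence / transmission media
#' @return list with `ux`, `uz`, `tau`
#' @export
snell_refract <- function(ux, uz, nx, nz, nA, nB) {
  # orient the normal against the incoming direction
  ci <- ux * nx + uz * nz
  flip <- ci > 0
  nx <- ifelse(flip, -nx, nx); nz <- ifelse(flip, -nz, nz)
  ci <- -(ux * nx + uz * nz)                      # cos(thA) >= 0
  r <- nA / nB
  s2 <- r^2 * (1 - ci^2)                          # sin^2(thB)
  tir <- s2 > 1
  ct <- sqrt(pmax(1 - s2, 0))
  # transmitted: r*u + (r*ci - ct)*n ; reflected: u + 2*ci*n
  tx <- r * ux + (r * ci - ct) * nx
  tz <- r * uz + (r * ci - ct) * nz
  rx <- ux + 2 * ci * nx
  rz <- uz + 2 * ci * nz
  ox <- ifelse(tir, rx, tx); oz <- ifelse(tir, rz, tz)
  nn <- sqrt(ox^2 + oz^2)
  list(ux = ox / nn, uz = oz / nn, tau = ifelse(tir, -1, 1))
}

#' Cylinder region (axis along y)
#' @param x0,z0 axis position in metres
#' @param R radius in metres
#' @param material a `gi_material` or name
#' @param label structure name for energy tallies (default: material name)
#' @export
region_cylinder <- function(x0, z0, R, material, label = NULL) {
  stopifnot(R > 0)
  material <- gi_material(material)
  structure(list(type = "cylinder", x0 = x0, z0 = z0, R = R,
                 material = material,
                 label = if (is.null(label)) material$name else label),
            class = "gi_region")
}

#' Axis-aligned slab region
#' @param zmin,zmax z extent in metres
#' @param xmin,xmax lateral extent in metres (default unbounded)
#' @param material a `gi_material` or name
#' @param label structure name for energy tallies (default: material name)
#' @export
region_slab <- function(zmin, zmax, xmin = -Inf, xmax = Inf, material,
                        label = NULL) {
  stopifnot(zmax > zmin)
  material <- gi_material(material)
  structure(list(type = "slab", zmin = zmin, zmax = zmax,
                 xmin = xmin, xmax = xmax, material = material,
                 label = if (is.null(label)) material$name else label),
            class = "gi_region")
}

#' Region geometry
#'
#' @param regions list of `gi_region` objects (first match wins where they
#'   would overlap; scenarios bundled here never overlap)
#' @param background background `gi_material` or name (default vacuum)
#' @param x_range,z_range simulation bounding box in metres
#' @export
gi_geometry <- function(regions = list(), background = "vacuum",
                        x_range = c(-Inf, Inf), z_range = c(-Inf, Inf)) {
  background <- gi_material(background)
  rm <- stats::setNames(lapply(regions, `[[`, "material"),
                        vapply(regions, `[[`, "", "label"))
  structure(list(regions = regions, background = background,
                 background_label = if (background$name == "vacuum") "leave_elsewhere" else background$name,
                 background_material = background$name,
                 region_materials = rm,
                 x_range = x_range, z_range = z_range), class = "gi_geometry")
}

# material at a point (first-match precedence)
.material_at <- function(geom, x, z) {
  for (rg in geom$regions) {
    inside <- if (rg$type == "cylinder") {
      (x - rg$x0)^2 + (z - rg$z0)^2 < rg$R^2
    } else {
      z >= rg$zmin & z < rg$zmax & x >= rg$xmin & x < rg$xmax
    }
    if (inside) return(rg$material)
  }
  geom$background
}

# intersection parameters t (distance along the ray) with a region boundary;
# returns sorted positive t values (possibly length 0)
.region_hits <- function(rg, x, z, ux, uz) {
  if (rg$type == "cylinder") {
    dx <- x - rg$x0; dz <- z - rg$z0
    bq <- dx * ux + dz * uz
    cq <- dx^2 + dz^2 - rg$R^2
    disc <- bq^2 - cq
    if (disc <= 0) return(numeric(0))
    t <- c(-bq - sqrt(disc), -bq + sqrt(disc))
  } else {
    t <- numeric(0)
    if (uz != 0) t <- c(t, (rg$zmin - z) / uz, (rg$zmax - z) / uz)
    if (ux != 0) t <- c(t, (rg$xmin - x) / ux, (rg$xmax - x) / ux)
    # keep only hits on the actual boundary of the box
    keep <- vapply(t, function(tt) {
      xx <- x + tt * ux; zz <- z + tt * uz
      zz >= rg$zmin - 1e-12 && zz <= rg$zmax + 1e-12 &&
        xx >= rg$xmin - 1e-12 && xx <= rg$xmax + 1e-12
    }, logical(1))
    t <- t[keep]
  }
  sort(t[t > 1e-12])
}

#' Advance a single path to the next boundary
#'
#' Scalar reference tracer used for inspection and testing: advances the
#' path to the nearest region boundary, element plane, detector plane or
#' bounding box along its direction, multiplying the weight by the medium
#' amplitude of the traversed segment (with the 1/r norm).
#'
#' @param path a single-path `gi_paths`
#' @param geometry a `gi_geometry`
#' @param element_z z positions of optical elements (optional)
#' @param detector_z detector plane z (optional)
#' @return list with the advanced `path` and `event` (one of `"element"`,
#'   `"interface"`, `"detector-plane"`, `"escape"`)
#' @export
trace_to_next_boundary <- function(path, geometry, element_z = numeric(0),
                                   detector_z = NULL) {
  stopifnot(n_paths(path) == 1)
  x <- path$x; z <- path$z; ux <- path$ux; uz <- path$uz
  cand <- data.frame(t = numeric(0), ev = character(0))
  for (rg in geometry$regions) {
    th <- .region_hits(rg, x, z, ux, uz)
    if (length(th)) cand <- rbind(cand, data.frame(t = th[1], ev = "interface"))
  }
  if (uz != 0) {
    for (ez in element_z) {
      t <- (ez - z) / uz
      if (t > 1e-12) cand <- rbind(cand, data.frame(t = t, ev = "element"))
    }
    if (!is.null(detector_z)) {
      t <- (detector_z - z) / uz
      if (t > 1e-12) cand <- rbind(cand, data.frame(t = t, ev = "detector-plane"))
    }
  }
  # bounding box
  for (lim in list(c(geometry$x_range[1], NA), c(geometry$x_range[2], NA))) {
    if (is.finite(lim[1]) && ux != 0) {
      t <- (lim[1] - x) / ux
      if (t > 1e-12) cand <- rbind(cand, data.frame(t = t, ev = "escape"))
    }
  }
  for (lim in geometry$z_range) {
    if (is.finite(lim) && uz != 0) {
      t <- (lim - z) / uz
      if (t > 1e-12) cand <- rbind(cand, data.frame(t = t, ev = "escape"))
    }
  }
  if (nrow(cand) == 0) return(list(path = path, event = "escape"))
  i <- which.min(cand$t)
  t <- cand$t[i]
  med <- .material_at(geometry, x + 0.5 * t * ux, z + 0.5 * t * uz)
  r0 <- c(x, z); r1 <- c(x + t * ux, z + t * uz)
  path$w <- path$w * amplitude_factor(r1, r0, med, path$k)
  path$x <- r1[1]; path$z <- r1[2]
  # lateral escape while elements remain ahead
  ev <- cand$ev[i]
  if (ev != "escape" && (r1[1] < geometry$x_range[1] || r1[1] > geometry$x_range[2]))
    ev <- "escape"
  list(path = path, event = ev)
}

# --- vectorized plane-to-plane propagation -----------------------------------

#' Propagate a path batch to a z plane
#'
#' Vectorized tracer for the forward geometry used by the scenarios: advances
#' every path in a batch from its current plane to `z_target`, accumulating
#' phase `n k d` and Beer-Lambert amplitude through the background and any
#' cylinder/slab regions crossed, applying Snell refraction at cylinder
#' surfaces (slab faces are normal to z; their sub-microradian refraction is
#' neglected). The geometric `1/r` norm is applied when `keep_r_norm` is
#' TRUE (point-like and incoherent sources); plane-wave scenarios drop it.
#'
#' @param batch a `gi_paths`
#' @param z_target target plane (must be ahead of every path)
#' @param geom a `gi_geometry`
#' @param keep_r_norm logical, apply the 1/r amplitude norm
#' @param snell logical, refract at cylinder surfaces
#' @return the advanced `gi_paths`; attribute `segments` holds per-path
#'   total chord lengths in each region (for interaction sampling)
#' @export
propagate_to_plane <- function(batch, z_target, geom, keep_r_norm = FALSE,
                               snell = TRUE) {
  n <- n_paths(batch)
  if (n == 0) return(batch)
  E <- batch$k * .gi_const$hc_keV_m / (2 * pi)   # per-path energies, keV
  phase <- numeric(n)      # accumulated n*k*d phase (real part)
  att <- numeric(n)        # accumulated mu*d/2
  dist <- numeric(n)       # accumulated geometric length
  x <- batch$x; z <- batch$z; ux <- batch$ux; uz <- batch$uz
  k <- batch$k
  seglist <- list()
  for (rg in geom$regions) {
    if (rg$type == "cylinder") {
      if (rg$z0 + rg$R <= min(z) || rg$z0 - rg$R >= z_target) next
      # entry intersection
      dx <- x - rg$x0; dz <- z - rg$z0
      bq <- dx * ux + dz * uz
      cq <- dx^2 + dz^2 - rg$R^2
      disc <- bq^2 - cq
      hit <- disc > 0 & (-bq - sqrt(pmax(disc, 0))) > 1e-12
      if (!any(hit)) next
      t1 <- (-bq - sqrt(pmax(disc, 0)))
      # advance hit paths to the entry point (background medium)
      d1 <- ifelse(hit, t1, 0)
      phase <- phase + .n_real(geom$background, E) * k * d1
      att <- att + mu_at(geom$background, E) * d1 / 2
      dist <- dist + d1
      x <- x + d1 * ux; z <- z + d1 * uz
      if (snell) {
        nxv <- (x - rg$x0) / rg$R; nzv <- (z - rg$z0) / rg$R
        sr <- snell_refract(ux, uz, nxv, nzv,
                            .n_real(geom$background, E), .n_real(rg$material, E))
        ux <- ifelse(hit, sr$ux, ux); uz <- ifelse(hit, sr$uz, uz)
        refl1 <- hit & sr$tau < 0
      } else refl1 <- rep(FALSE, n)
      # chord through the cylinder with the (possibly refracted) direction
      dx <- x - rg$x0; dz <- z - rg$z0
      bq <- dx * ux + dz * uz
      cq <- dx^2 + dz^2 - rg$R^2
      disc2 <- pmax(bq^2 - cq, 0)
      chord <- ifelse(hit & !refl1, -bq + sqrt(disc2), 0)
      phase <- phase + Re(refractive_index(rg$material, E)) * k * chord
      att <- att + mu_at(rg$material, E) * chord / 2
      dist <- dist + chord
      x <- x + chord * ux; z <- z + chord * uz
      if (snell) {
        inb <- hit & !refl1 & chord > 0
        nxv <- (x - rg$x0) / rg$R; nzv <- (z - rg$z0) / rg$R
        sr <- snell_refract(ux, uz, nxv, nzv,
                            .n_real(rg$material, E), .n_real(geom$background, E))
        ux <- ifelse(inb, sr$ux, ux); uz <- ifelse(inb, sr$uz, uz)
      }
      seglist[[length(seglist) + 1]] <-
        list(material = rg$material, length = chord, region = rg)
    } else {
      if (rg$zmax <= min(z) || rg$zmin >= z_target) next
      # paraxial slab crossing: chord = thickness/|uz| for paths inside the
      # lateral extent at the slab midplane
      tmid <- (0.5 * (rg$zmin + rg$zmax) - z) / uz
      xm <- x + tmid * ux
      inx <- xm >= rg$xmin & xm < rg$xmax & tmid > 0
      chord <- ifelse(inx, (rg$zmax - pmax(rg$zmin, z)) / uz, 0)
      chord <- pmax(chord, 0)
      dn <- Re(refractive_index(rg$material, E)) - .n_real(geom$background, E)
      phase <- phase + dn * k * chord     # relative to background (added below)
      att <- att + (mu_at(rg$material, E) - mu_at(geom$background, E)) * chord / 2
      seglist[[length(seglist) + 1]] <-
        list(material = rg$material, length = chord, region = rg)
    }
  }
  # remaining straight flight in the background medium to the target plane
  drest <- (z_target - z) / uz
  if (any(drest < -1e-9)) stop("propagate_to_plane: target plane behind a path")
  drest <- pmax(drest, 0)
  phase <- phase + .n_real(geom$background, E) * k * drest
  att <- att + mu_at(geom$background, E) * drest / 2
  dist <- dist + drest
  x <- x + drest * ux
  batch$x <- x; batch$z <- rep(z_target, n)
  batch$ux <- ux; batch$uz <- uz
  amp <- exp(-att) * exp(1i * (phase %% (2 * pi)))
  if (keep_r_norm) amp <- amp / dist
  batch$w <- batch$w * amp
  attr(batch, "segments") <- seglist
  attr(batch, "flight") <- dist
  batch
}

.n_real <- function(material, E) 1 - delta_at(material, E)
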