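# Explicit interaction sampling (photoelectric, Compton, Rayleigh) coupled
# to the ray tracing, conventional-MC transport for secondaries, and
# energy-deposition ledgers.  Electron transport is not performed: all
# energy transferred to charged particles is deposited locally.  Transport
# is in the (x, z) plane, so sampled polar scattering angles deflect
# in-plane with a random sign.

#' Sample interaction sites along segments
#'
#' Free path lengths are exponential with rate `mu_total(E)` (Beer-Lambert);
#' a segment yields an interaction when the sampled distance is shorter than
#' the segment.
#'
#' @param len segment lengths in metres (vectorized)
#' @param material a `gi_material` or name (single material for the batch)
#' @param E photon energies in keV (scalar or vector)
#' @return list with logical `interacts` and the distances `s` into the
#'   segment (NA where no interaction)
#' @export
sample_interaction_site <- function(len, material, E) {
  mu <- mu_at(material, E)
  n <- length(len)
  if (all(mu == 0)) return(list(interacts = rep(FALSE, n), s = rep(NA_real_, n)))
  s <- stats::rexp(n, rate = pmax(mu, 1e-300))
  hit <- s < len & mu > 0
  s[!hit] <- NA_real_
  list(interacts = hit, s = s)
}

#' Select the interaction channel
#'
#' Channels are drawn with probabilities proportional to the partial
#' attenuation coefficients `mu_photo`, `mu_incoh`, `mu_coh` at the photon
#' energy.
#'
#' @param E photon energies in keV
#' @param material a `gi_material` or name
#' @return integer vector: 1 = photoelectric, 2 = Compton, 3 = Rayleigh
#' @export
select_channel <- function(E, material) {
  p <- mu_at(material, E, "photo")
  c_ <- mu_at(material, E, "incoh")
  r <- mu_at(material, E, "coh")
  tot <- p + c_ + r
  u <- stats::runif(length(E)) * tot
  ifelse(u < p, 1L, ifelse(u < p + c_, 2L, 3L))
}

#' Sample a Compton scattering event (free-electron Klein-Nishina)
#'
#' Polar angles are drawn by rejection from the Klein-Nishina differential
#' cross section; the scattered energy follows the Compton relation
#' `E' = E / (1 + (E / m_e c^2)(1 - cos theta))`. The energy difference is
#' transferred to the electron (deposited locally by the callers).
#'
#' @param E photon energies in keV (vectorized)
#' @return list with `E_out` (keV) and `theta` (rad)
#' @export
compton_sample <- function(E) {
  n <- length(E)
  eps <- E / .gi_const$mec2_keV
  theta <- numeric(n)
  todo <- seq_len(n)
  # d(sigma)/d(cos theta) ~ (E'/E)^2 (E/E' + E'/E - sin^2 theta); bounded by
  # its theta = 0 value of 2
  while (length(todo)) {
    ct <- stats::runif(length(todo), -1, 1)
    r <- 1 / (1 + eps[todo] * (1 - ct))       # E'/E
    f <- r^2 * (r + 1 / r - (1 - ct^2))
    acc <- stats::runif(length(todo)) * 2 < f
    theta[todo[acc]] <- acos(ct[acc])
    todo <- todo[!acc]
  }
  ct <- cos(theta)
  E_out <- E / (1 + eps * (1 - ct))
  list(E_out = E_out, theta = theta)
}

#' Sample a Rayleigh (Thomson) scattering angle
#'
#' Thomson angular distribution `(1 + cos^2 theta) / 2` (no atomic form
#' factors; a form-factor hook can replace this sampler).
#'
#' @param n number of samples
#' @return polar angles in rad
#' @export
rayleigh_sample_angle <- function(n) {
  theta <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    ct <- stats::runif(length(todo), -1, 1)
    acc <- stats::runif(length(todo)) < (1 + ct^2) / 2
    theta[todo[acc]] <- acos(ct[acc])
    todo <- todo[!acc]
  }
  theta
}

# rotate in-plane directions by theta with a random sign
.deflect <- function(ux, uz, theta) {
  s <- sample(c(-1, 1), length(ux), replace = TRUE)
  th <- atan2(ux, uz) + s * theta
  list(ux = sin(th), uz = cos(th))
}

#' Create an energy ledger
#'
#' Named accumulator of deposited energy (keV x statistical weight) per
#' structure plus the two escape categories.
#'
#' @param structures character vector of structure names
#' @return object of class `gi_ledger`
#' @export
gi_ledger <- function(structures) {
  v <- stats::setNames(numeric(length(structures) + 2),
                       c(structures, "leave_at_D", "leave_elsewhere"))
  structure(list(dep = v, emitted = 0), class = "gi_ledger")
}

ledger_add <- function(led, name, amount) {
  led$dep[name] <- led$dep[name] + sum(amount)
  led
}

#' Ledger fractions
#' @param led a `gi_ledger`
#' @return named numeric vector of deposited-energy fractions (percent)
#' @export
ledger_fractions <- function(led) 100 * led$dep / led$emitted

#' @export
print.gi_ledger <- function(x, ...) {
  fr <- ledger_fractions(x)
  cat("<gi_ledger> emitted:", x$emitted, "keV; fractions (%):\n")
  print(round(fr, 3))
  cat("total:", round(sum(fr), 6), "%\n")
  invisible(x)
}

#' Outcome of explicit interactions on interfering primary paths
#'
#' Implements the coupling contract between interaction sampling and the
#' ray tracing: for every interacting path (1) a clone continues unchanged in
#' ray-trace-only mode so that no primary path is lost for the interference
#' pattern; (2) photoelectric events deposit the full photon energy times the
#' path's statistical weight; Compton events deposit the transferred energy
#' and push the scattered photon as a conventional secondary whose
#' statistical weight carries the accumulated `|z|^2` splitting factors;
#' Rayleigh events scatter elastically and continue as interfering primaries
#' -- restricted to one such event per path, after which they are demoted to
#' conventional transport.
#'
#' @param batch interacting paths (`gi_paths`, all in interfering-primary
#'   mode)
#' @param channel integer vector: 1 photoelectric, 2 Compton, 3 Rayleigh
#' @return list with `clones` (ray-trace-only continuations), `secondaries`
#'   (conventional photons), `rayleigh_primaries` (interfering
#'   continuations) and `deposit` (energy deposited locally, keV x weight)
#' @export
handle_interaction <- function(batch, channel) {
  if (any(batch$mode != 0L))
    stop("handle_interaction requires interfering-primary paths")
  stopifnot(length(channel) == n_paths(batch))
  E <- batch$k * .gi_const$hc_keV_m / (2 * pi)
  clones <- batch
  clones$mode <- rep(1L, n_paths(batch))
  deposit <- numeric(n_paths(batch))
  ph <- channel == 1L
  deposit[ph] <- E[ph] * batch$sw[ph]
  sec <- NULL
  cm <- channel == 2L
  if (any(cm)) {
    cs <- compton_sample(E[cm])
    deposit[cm] <- (E[cm] - cs$E_out) * batch$sw[cm]
    d <- .deflect(batch$ux[cm], batch$uz[cm], cs$theta)
    sec <- path_batch(x = batch$x[cm], z = batch$z[cm], ux = d$ux, uz = d$uz,
                      k = wavenumber_from_energy(cs$E_out), w = 1 + 0i,
                      sw = batch$sw[cm], hist = batch$hist[cm], mode = 2L)
  }
  ray <- NULL
  ry <- channel == 3L
  if (any(ry)) {
    d <- .deflect(batch$ux[ry], batch$uz[ry], rayleigh_sample_angle(sum(ry)))
    ray <- .subset_batch(batch, ry)
    ray$ux <- d$ux; ray$uz <- d$uz
    ray$nray <- ray$nray + 1L
    demote <- ray$nray > 1L          # at most one coherent scatter per path
    ray$mode[demote] <- 2L
  }
  list(clones = clones, secondaries = sec, rayleigh_primaries = ray,
       deposit = deposit)
}

# --- conventional straight-line MC transport ---------------------------------

# vectorized material/structure lookup at points
.structure_at <- function(geom, x, z) {
  out <- rep("background", length(x))
  for (rg in rev(geom$regions)) {  # reversed so earlier regions win
    inside <- if (rg$type == "cylinder") {
      (x - rg$x0)^2 + (z - rg$z0)^2 < rg$R^2
    } else {
      z >= rg$zmin & z < rg$zmax & x >= rg$xmin & x < rg$xmax
    }
    if (!is.null(rg$grating)) {
      # periodic grating slab: only the absorber sections are material
      # (section chosen by lateral position; section side walls are not
      # tracked as boundaries)
      u <- (x - rg$grating$x0) %% rg$grating$period
      inside <- inside & u >= rg$grating$duty * rg$grating$period
    }
    out[inside] <- rg$label
  }
  out
}

# vectorized distance to the nearest boundary (region surfaces, detector
# plane, bounding box) along the current directions
.next_boundary <- function(geom, x, z, ux, uz, detector_z) {
  n <- length(x)
  tb <- rep(Inf, n); ev <- rep("none", n)
  upd <- function(t, what) {
    ok <- !is.na(t) & t > 1e-9 & t < tb
    tb[ok] <<- t[ok]; ev[ok] <<- what
  }
  for (rg in geom$regions) {
    if (rg$type == "cylinder") {
      dx <- x - rg$x0; dz <- z - rg$z0
      bq <- dx * ux + dz * uz
      cq <- dx^2 + dz^2 - rg$R^2
      disc <- bq^2 - cq
      sq <- sqrt(pmax(disc, 0))
      t1 <- -bq - sq; t2 <- -bq + sq
      t1[disc <= 0] <- NA; t2[disc <= 0] <- NA
      upd(ifelse(t1 > 1e-9, t1, t2), "interface")
    } else {
      for (zp in c(rg$zmin, rg$zmax)) {
        t <- (zp - z) / uz
        xx <- x + t * ux
        t[!(xx >= rg$xmin & xx < rg$xmax)] <- NA
        upd(t, "interface")
      }
      if (is.finite(rg$xmin) || is.finite(rg$xmax)) {
        for (xp in c(rg$xmin, rg$xmax)) {
          if (!is.finite(xp)) next
          t <- (xp - x) / ux
          zz <- z + t * uz
          t[!(zz >= rg$zmin & zz < rg$zmax)] <- NA
          upd(t, "interface")
        }
      }
    }
  }
  if (!is.null(detector_z)) upd((detector_z - z) / uz, "detector")
  upd((geom$z_range[1] - z) / uz, "escape")
  upd((geom$z_range[2] - z) / uz, "escape")
  upd((geom$x_range[1] - x) / ux, "escape")
  upd((geom$x_range[2] - x) / ux, "escape")
  list(t = tb, event = ev)
}

#' Conventional Monte Carlo photon transport
#'
#' Classical straight-line transport without splitting, phase or refraction:
#' photons fly between sampled interaction sites, interact via the bundled
#' partial cross sections, and deposit energy per structure. Used both as
#' the reference mode for deposited-energy comparisons and for secondary
#' (scattered) particles inside the semi-classical runs.
#'
#' @param x,z,ux,uz,E,sw initial photon states (vectors)
#' @param geom a `gi_geometry` whose regions carry `label`s (implicit-mode
#'   gratings are not allowed here: conventional transport needs explicit
#'   geometry)
#' @param ledger a `gi_ledger`
#' @param detector_z detector plane (crossing it tallies `leave_at_D`)
#' @param det optional `gi_detector`: photons crossing the plane are also
#'   accumulated in the incoherent scatter channel with weight `sw`
#' @param E_cut photons below this energy (keV) deposit locally (the bundled
#'   tables start at 5 keV)
#' @param max_steps safety cap on transport iterations
#' @return list with the updated `ledger` and `det`
#' @export
run_conventional_transport <- function(x, z, ux, uz, E, sw, geom, ledger,
                                       detector_z, det = NULL, E_cut = 5,
                                       max_steps = 200) {
  for (step in seq_len(max_steps)) {
    n <- length(x)
    if (n == 0) break
    # photons below the table cutoff deposit locally
    low <- E < E_cut
    if (any(low)) {
      st <- .structure_at(geom, x[low], z[low])
      for (s in unique(st)) {
        nm <- if (s == "background") geom$background_label else s
        ledger <- ledger_add(ledger, nm, E[low][st == s] * sw[low][st == s])
      }
      keep <- !low
      x <- x[keep]; z <- z[keep]; ux <- ux[keep]; uz <- uz[keep]
      E <- E[keep]; sw <- sw[keep]
      if (!length(x)) break
    }
    nb <- .next_boundary(geom, x, z, ux, uz, detector_z)
    # material of the current cell (sampled at a nudged midpoint)
    tmid <- pmin(nb$t, 1e6) / 2
    st <- .structure_at(geom, x + tmid * ux, z + tmid * uz)
    matname <- ifelse(st == "background", geom$background_material, st)
    s_int <- rep(Inf, n)
    for (mn in unique(matname)) {
      i <- matname == mn
      mat <- if (mn %in% names(geom$region_materials))
        geom$region_materials[[mn]] else gi_material(mn)
      mu <- mu_at(mat, E[i])
      si <- rep(Inf, sum(i))
      pos <- mu > 0
      si[pos] <- stats::rexp(sum(pos), rate = mu[pos])
      s_int[i] <- si
    }
    interact <- s_int < nb$t & is.finite(s_int)
    # move everyone
    tmove <- ifelse(interact, s_int, nb$t)
    tmove[!is.finite(tmove)] <- 0
    x <- x + tmove * ux; z <- z + tmove * uz
    # terminal boundary events
    done_D <- !interact & nb$event == "detector"
    done_E <- !interact & (nb$event == "escape" | nb$event == "none" |
                             !is.finite(nb$t))
    if (any(done_D)) {
      ledger <- ledger_add(ledger, "leave_at_D", E[done_D] * sw[done_D])
      if (!is.null(det)) {
        b <- path_batch(x = x[done_D], z = detector_z, ux = ux[done_D],
                        uz = uz[done_D], k = wavenumber_from_energy(E[done_D]),
                        w = 1 + 0i, sw = sw[done_D], mode = 2L)
        det <- det_accumulate(det, b)
      }
    }
    if (any(done_E))
      ledger <- ledger_add(ledger, "leave_elsewhere", E[done_E] * sw[done_E])
    # interactions
    if (any(interact)) {
      ii <- which(interact)
      sti <- .structure_at(geom, x[ii], z[ii])
      lab <- ifelse(sti == "background", geom$background_label, sti)
      matn <- ifelse(sti == "background", geom$background_material, sti)
      chan <- rep(NA_integer_, length(ii))
      for (mn in unique(matn)) {
        j <- matn == mn
        mat <- if (mn %in% names(geom$region_materials))
          geom$region_materials[[mn]] else gi_material(mn)
        chan[j] <- select_channel(E[ii][j], mat)
      }
      # photoelectric: full local deposit
      ph <- chan == 1L
      if (any(ph)) for (l in unique(lab[ph]))
        ledger <- ledger_add(ledger, l, E[ii][ph][lab[ph] == l] * sw[ii][ph][lab[ph] == l])
      # Compton: local electron deposit, photon continues degraded
      cm <- chan == 2L
      if (any(cm)) {
        cs <- compton_sample(E[ii][cm])
        dE <- (E[ii][cm] - cs$E_out) * sw[ii][cm]
        for (l in unique(lab[cm]))
          ledger <- ledger_add(ledger, l, dE[lab[cm] == l])
        d <- .deflect(ux[ii[cm]], uz[ii[cm]], cs$theta)
        ux[ii[cm]] <- d$ux; uz[ii[cm]] <- d$uz
        E[ii[cm]] <- cs$E_out
      }
      # Rayleigh: elastic deflection
      ry <- chan == 3L
      if (any(ry)) {
        d <- .deflect(ux[ii[ry]], uz[ii[ry]], rayleigh_sample_angle(sum(ry)))
        ux[ii[ry]] <- d$ux; uz[ii[ry]] <- d$uz
      }
      keep_i <- ii[!ph]
    } else keep_i <- integer(0)
    # survivors: non-photo interactions plus interface crossers (nudged past
    # the boundary so the next step sees the far side)
    cross <- which(!interact & nb$event == "interface")
    x[cross] <- x[cross] + 1e-9 * ux[cross]
    z[cross] <- z[cross] + 1e-9 * uz[cross]
    keep <- sort(c(keep_i, cross))
    x <- x[keep]; z <- z[keep]; ux <- ux[keep]; uz <- uz[keep]
    E <- E[keep]; sw <- sw[keep]
  }
  if (length(x)) {
    # safety cap reached: deposit the remainder where it stands
    st <- .structure_at(geom, x, z)
    lab <- ifelse(st == "background", geom$background_label, st)
    for (l in unique(lab)) ledger <- ledger_add(ledger, l, E[lab == l] * sw[lab == l])
  }
  list(ledger = ledger, det = det)
}
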