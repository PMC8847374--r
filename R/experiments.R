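# Bundled scenarios and their runners.
#
# Each runner composes the module operations (sources -> transport ->
# gratings -> detector -> analysis) into one vectorized simulation.  All
# runs are deterministic given the seed stored in the scenario.

#' Bundled scenarios
#'
#' Constructors for the five experiment families. Every printed geometric
#' and physical parameter of the corresponding experiment is transcribed in
#' the defaults; `scale` divides the number of histories for desk-scale
#' runs (1 = full scale).
#'
#' @param scale history divisor (desk runs use `scale < 1`)
#' @param seed RNG seed stored with the scenario
#' @return a `gi_scenario`
#' @export
scenario_double_slit <- function(blocked = FALSE, scale = 1, seed = 1) {
  structure(list(
    type = "double_slit", blocked = blocked,
    a = 0.2e-6, b = 2.2e-6,           # slit width / centre-to-centre spacing
    l = 1.10, d = 0.10,               # source-slit and slit-detector distance
    E = 17, n_histories = round(1e5 * scale),
    n_q = 64,                          # Q samples per splitting event
    au_thickness = 0.1e-3, au_gap = 10e-6,
    fov = 80e-6,                       # detector field of view (centred)
    seed = seed), class = "gi_scenario")
}

#' @rdname scenario_double_slit
#' @param n_split Fourier order cutoff (or Huygens path count)
#' @param mode `"fourier"` or `"huygens"` splitting at the phase grating
#' @param distances grating-to-detector distances (default: 25 planes
#'   between the first and third fractional Talbot distances)
#' @export
scenario_talbot_carpet <- function(n_split = 41, mode = "fourier",
                                   distances = NULL, n_histories = 8e6,
                                   scale = 1, seed = 1) {
  E <- 20; p <- 4e-6
  d1 <- fractional_talbot_distance(p, E, 1)
  if (is.null(distances)) distances <- seq(d1, 3 * d1, length.out = 25)
  structure(list(
    type = "talbot_carpet", E = E, period = p, duty = 0.5,
    mode = mode, n_split = n_split,
    distances = distances,
    n_histories = round(n_histories * scale),
    fov_periods = 4, seed = seed), class = "gi_scenario")
}

#' @rdname scenario_double_slit
#' @param material cylinder material of the simulated row (`"Si"` or
#'   `"polystyrene"`; the physical cylinder is half silicon, half
#'   polystyrene along its axis)
#' @export
scenario_cylinder <- function(material = "Si", scale = 1/50, seed = 1) {
  E <- 20; p <- 2e-6
  structure(list(
    type = "cylinder", E = E, period = p, duty = 0.5, n_split = 5,
    R = 0.87e-3, material = material,
    gap = 0.9e-3,                      # cylinder axis to grating plane
    d_det = fractional_talbot_distance(p, E, 3),   # 2.42 cm
    n_histories = round(5e8 * scale),
    fov = 2.1e-3, pixel = 15e-6, n_steps = 8,
    seed = seed), class = "gi_scenario")
}

#' @rdname scenario_double_slit
#' @param grating_mode `"implicit"` (transmission function only),
#'   `"explicit"` (splitting plane plus a grating geometry filled with a
#'   phase-neutral silicon medium) or `"conventional"` (classical MC, no
#'   splitting/phase/refraction)
#' @export
scenario_deposited_energy <- function(grating_mode = "implicit",
                                      material = "Si",
                                      scale = 1/1000, seed = 1) {
  E <- 20; p <- 2e-6
  structure(list(
    type = "deposited_energy", E = E, period = p, duty = 0.5, n_split = 5,
    grating_mode = grating_mode, material = material,
    R = 0.87e-3,
    wafer_thickness = 250e-6,          # grating substrate
    gap = 0.9e-3,                      # wafer exit to cylinder axis
    d_det = fractional_talbot_distance(p, E, 3),
    beam_half_width = 1.2e-3,
    n_histories = round(5e8 * scale),
    seed = seed), class = "gi_scenario")
}

#' @rdname scenario_double_slit
#' @param n_q_g0 number of Q samples at the source grating (the full-scale
#'   study splits each path into 1.2e6; desk runs use far fewer)
#' @export
scenario_lab_talbot_lau <- function(gratings = TRUE, scale = 1,
                                    n_q_g0 = 1e4, fov = 0.5e-2, seed = 1) {
  structure(list(
    type = "lab_talbot_lau", gratings = gratings,
    p0 = 1e-6, p1 = 1.5e-6, p2 = 3e-6,
    d01 = 0.201, d12 = 0.603,
    z_g0 = 0.1,                        # source to G0
    fwhm = 10e-6, design_E = 19,
    spectrum = triangle_spectrum(19, 40, 4),
    n_g1 = 9,                          # Fourier orders +/-9 at G1
    n_q_g0 = n_q_g0,                   # desk default; full scale uses
    paper_n_q_g0 = 1.2e6,              # 1.2e6 splits per G0 event
    n_histories = round(2.5e5 * scale),
    fov = fov, pixel = 75e-6,
    seed = seed), class = "gi_scenario")
}

#' @export
print.gi_scenario <- function(x, ...) {
  cat(sprintf("<gi_scenario> %s (%g histories, seed %d)\n",
              x$type, x$n_histories, x$seed))
  invisible(x)
}

#' All bundled scenarios at desk scale
#' @return named list of `gi_scenario` objects
#' @export
bundled_scenarios <- function(seed = 1) {
  list(
    doubleslit         = scenario_double_slit(FALSE, seed = seed),
    doubleslit_blocked = scenario_double_slit(TRUE, seed = seed),
    talbot_carpet      = scenario_talbot_carpet(seed = seed),
    cylinder_dpc       = scenario_cylinder(seed = seed),
    deposited_energy   = scenario_deposited_energy(seed = seed),
    lab_talbot_lau     = scenario_lab_talbot_lau(seed = seed)
  )
}

#' Run a scenario
#'
#' Dispatches to the scenario-specific runner.
#' @param scn a `gi_scenario`
#' @param ... passed on to the runner
#' @export
run_scenario <- function(scn, ...) {
  switch(scn$type,
         double_slit      = run_double_slit(scn, ...),
         talbot_carpet    = run_talbot_carpet(scn, ...),
         cylinder         = run_cylinder_projection(scn, ...),
         deposited_energy = run_deposited_energy(scn, ...),
         lab_talbot_lau   = run_lab_talbot_lau(scn, ...),
         stop("unknown scenario type: ", scn$type))
}

# ---------------------------------------------------------------------------
# Double slit

#' Run the double-slit experiment
#'
#' Coherent point source collimated onto two slits, Fourier splitting at the
#' two-slit element, coherent accumulation across all histories with
#' per-data-point paths-squared renormalization, compared against the
#' analytic Fraunhofer profile (unit-sum normalized). The blocked variant
#' places a gold slab behind the +x slit and compares against the analytic
#' single-slit profile at its projected centre.
#'
#' @param scn scenario from [scenario_double_slit()]
#' @param chunk histories per processing chunk
#' @return list with the detector profile, the analytic reference and the
#'   rmse of the unit-sum normalized profiles
#' @export
run_double_slit <- function(scn, chunk = 2e4) {
  set.seed(scn$seed)
  a <- scn$a; b <- scn$b; l <- scn$l; d <- scn$d
  k <- wavenumber_from_energy(scn$E)
  lam <- 2 * pi / k
  # two-slit element: period b, slit width a, slits centred at +/- b/2
  g <- gi_grating(z = l, period = b, duty = a / b, mode = "fourier",
                  x0 = -b / 2 - a / 2, slits = c(0L, 1L), n_q = scn$n_q)
  slit_iv <- rbind(c(-b / 2 - a / 2, -b / 2 + a / 2),
                   c(b / 2 - a / 2, b / 2 + a / 2))
  src <- source_point(position = c(0, 0), E = scn$E,
                      n_histories = scn$n_histories,
                      aim_extent = slit_iv, aim_z = l)
  geom <- if (scn$blocked) {
    gi_geometry(list(region_slab(l + scn$au_gap,
                                 l + scn$au_gap + scn$au_thickness,
                                 xmin = 0, xmax = Inf, material = "Au")),
                background = "vacuum")
  } else gi_geometry()
  fringe <- lam * d / b
  det <- detector_grid(z = l + d, x_min = -scn$fov / 2, x_max = scn$fov / 2,
                       bin_width = fringe / 16)
  nh <- scn$n_histories
  done <- 0L
  while (done < nh) {
    nb <- min(chunk, nh - done)
    batch <- emit_histories(src, nb, first = done + 1L)
    batch <- propagate_to_plane(batch, l, geom, keep_r_norm = TRUE)
    batch <- g0_fourier_split(batch, g)
    batch <- propagate_to_plane(batch, l + d, geom, keep_r_norm = TRUE)
    # accumulate relative to the known spherical reference wavefront: the
    # diverging beam's quadratic phase k x^2/(2d) would otherwise vary by
    # several radians across one data point at the pattern edge and wash
    # out the coherent per-bin sum
    ref <- (batch$k * (sqrt(d^2 + batch$x^2) - d)) %% (2 * pi)
    batch$w <- batch$w * exp(-1i * ref)
    det <- det_accumulate(det, batch)
    done <- done + nb
  }
  det <- close_cohort(det, "per-bin-paths-squared")
  mc <- det$intensity / sum(det$intensity)
  if (scn$blocked) {
    centre <- -(b / 2) * (l + d) / l   # projected centre of the open slit
    ref <- analytic_double_slit(det$x - centre, a = a, b = NULL,
                                E = scn$E, d = d, l = l)
  } else {
    ref <- analytic_double_slit(det$x, a = a, b = b, E = scn$E, d = d, l = l)
  }
  list(x = det$x, mc = mc, analytic = ref,
       rmse = rmse(mc, ref, normalize = "sum"),
       detector = det, scenario = scn)
}

# ---------------------------------------------------------------------------
# Talbot carpet

#' Run the Talbot-carpet experiment
#'
#' Plane wave through a pi-phase grating; for each grating-to-detector
#' distance the coherent field of all histories is accumulated with
#' per-data-point paths-squared renormalization and normalized to unit mean.
#' The same grid is evaluated with the Fresnel wave-optics oracle for the
#' Pearson/rmse comparison.
#'
#' @param scn scenario from [scenario_talbot_carpet()]
#' @param chunk maximal number of paths per processing chunk
#' @return list with the MC carpet, oracle carpet, `pearson` and `rmse`
#' @export
run_talbot_carpet <- function(scn, chunk = 4e6) {
  set.seed(scn$seed)
  p <- scn$period
  k <- wavenumber_from_energy(scn$E)
  # Huygens fan range: covers the same transverse momenta as a 41-order
  # Fourier expansion, with some margin
  hrange <- scn$angular_range %||% (2.2 * 41 * 2 * pi / (p * k))
  g <- gi_grating(z = 0, period = p, duty = scn$duty, mode = scn$mode,
                  tau_a = 1, tau_b = -1, n_split = scn$n_split,
                  angular_range = if (scn$mode == "huygens") hrange else NULL)
  fov <- scn$fov_periods * p
  # comparison grid: 8 intensity points per p/2 fringe (the fringe-resolving
  # floor); the coherent accumulation itself uses much finer data points so
  # that the field phase is constant within a data point
  dx <- p / 16
  dxf <- p / 256
  zmax <- max(scn$distances)
  n_orders <- if (scn$mode == "fourier") 2 * scn$n_split + 1 else scn$n_split
  margin <- if (scn$mode == "fourier")
    zmax * (2 * pi * scn$n_split / p) / k else zmax * (g$angular_range / 2)
  extent <- c(-margin - dxf / 2, fov + margin - dxf / 2)
  nh <- scn$n_histories
  nbc <- round(fov / dx)
  mc <- matrix(0, length(scn$distances), nbc)
  for (iz in seq_along(scn$distances)) {
    z <- scn$distances[iz]
    det <- detector_grid(z = z, x_min = -dxf / 2, x_max = fov - dxf / 2,
                         bin_width = dxf)
    src <- source_plane_wave(extent, scn$E, nh, z = 0)
    per_hist <- n_orders
    hchunk <- max(1L, floor(chunk / per_hist))
    done <- 0L
    while (done < nh) {
      nb <- min(hchunk, nh - done)
      batch <- emit_histories(src, nb, first = done + 1L)
      batch <- if (scn$mode == "fourier") g1_split(batch, g)
               else huygens_split(batch, g)
      batch <- .fly_free(batch, z)
      det <- det_accumulate(det, batch)
      done <- done + nb
    }
    det <- close_cohort(det, "per-bin-paths-squared")
    # intensity-average the fine data points onto the comparison grid
    binc <- (floor((det$x + dx / 2) / dx) %% nbc) + 1
    I <- rowsum(det$intensity, binc)[, 1] / (dx / dxf)
    mc[iz, ] <- I / mean(I)
  }
  # oracle on the same fine grid, intensity-averaged identically
  oracle_f <- talbot_carpet_oracle(g, scn$E, scn$distances,
                                   width = fov, dx = dxf)
  xo <- attr(oracle_f, "x")
  bin <- (floor((xo + dx / 2) / dx) %% nbc) + 1
  oracle <- t(apply(oracle_f, 1, function(r) rowsum(r, bin)[, 1] / (dx / dxf)))
  oracle <- oracle / rowMeans(oracle)
  attr(oracle, "x") <- (seq_len(nbc) - 1) * dx
  list(mc = mc, oracle = oracle, x = attr(oracle, "x"),
       distances = scn$distances,
       pearson = pearson(mc, oracle),
       rmse = rmse(as.vector(mc), as.vector(oracle), normalize = "none"),
       scenario = scn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# straight vacuum flight to a plane at distance z ahead of the batch plane
# (plane-wave convention: no 1/r norm, exact path-length phase)
.fly_free <- function(batch, z_ahead) {
  dz <- z_ahead
  dl <- dz / batch$uz
  batch$x <- batch$x + dl * batch$ux
  batch$z <- batch$z + dz
  batch$w <- batch$w * exp(1i * ((batch$k * dl) %% (2 * pi)))
  batch
}

# ---------------------------------------------------------------------------
# Cylinder projection (absorption + DPC)

#' Run the cylinder projection experiment
#'
#' Plane wave, cylinder (one material row of the two-material cylinder)
#' just before a pi-phase grating, detector at the third fractional Talbot
#' distance. Sample and reference runs are phase stepped with a binary
#' mask in post processing; absorption and DPC line profiles are retrieved
#' per pixel and compared with the Beer-Lambert and analytic
#' differential-phase profiles.
#'
#' @param scn scenario from [scenario_cylinder()]
#' @param chunk maximal paths per chunk
#' @return list with retrieval data frame, analytic references, and the two
#'   rmse values
#' @export
run_cylinder_projection <- function(scn, chunk = 4e6) {
  set.seed(scn$seed)
  p <- scn$period
  k <- wavenumber_from_energy(scn$E)
  z_g <- 0
  z_c <- z_g - scn$gap
  z_det <- z_g + scn$d_det
  z_src <- z_c - scn$R - 0.2e-3
  g <- gi_grating(z = z_g, period = p, duty = scn$duty, mode = "fourier",
                  tau_a = 1, tau_b = -1, n_split = scn$n_split)
  fringe <- p / 2
  margin <- 10e-6 + scn$d_det * (2 * pi * scn$n_split / p) / k
  det_run <- function(with_cylinder) {
    geom <- if (with_cylinder)
      gi_geometry(list(region_cylinder(0, z_c, scn$R, scn$material)))
    else gi_geometry()
    det <- detector_grid(z = z_det, x_min = -scn$fov / 2, x_max = scn$fov / 2,
                         bin_width = fringe / 16, pixel_size = scn$pixel)
    src <- source_plane_wave(c(-scn$fov / 2 - margin, scn$fov / 2 + margin),
                             scn$E, scn$n_histories, z = z_src)
    per_hist <- 2 * scn$n_split + 1
    hchunk <- max(1L, floor(chunk / per_hist))
    done <- 0L
    while (done < scn$n_histories) {
      nb <- min(hchunk, scn$n_histories - done)
      batch <- emit_histories(src, nb, first = done + 1L)
      batch <- propagate_to_plane(batch, z_g, geom, keep_r_norm = FALSE)
      batch <- g1_split(batch, g)
      batch <- .fly_free(batch, z_det - z_g)
      det <- det_accumulate(det, batch)
      done <- done + nb
    }
    close_cohort(det, "per-bin-paths-squared")
  }
  det_s <- det_run(TRUE)
  det_r <- det_run(FALSE)
  step_s <- phase_step(det_s$x, det_s$intensity, mask_period = fringe,
                       n_steps = scn$n_steps, pixel_size = scn$pixel)
  step_r <- phase_step(det_r$x, det_r$intensity, mask_period = fringe,
                       n_steps = scn$n_steps, pixel_size = scn$pixel)
  ret <- retrieve_signals(step_s, step_r)
  mu <- mu_at(scn$material, scn$E)
  delta <- delta_at(scn$material, scn$E)
  ref_abs <- beer_lambert_cylinder(ret$x, scn$R, mu)
  ref_dpc <- analytic_dpc_cylinder(ret$x, scn$R, delta, k,
                                   d = z_det - z_c, p2 = fringe, wrap = TRUE)
  list(retrieval = ret,
       ref_absorption = ref_abs, ref_dpc = ref_dpc,
       rmse_absorption = rmse(ret$absorption, ref_abs, normalize = "none"),
       rmse_dpc = rmse(ret$dpc, ref_dpc, normalize = "none"),
       scenario = scn)
}

# ---------------------------------------------------------------------------
# Deposited energy

#' Run the deposited-energy experiment
#'
#' Inverted cylinder geometry (sample behind the grating): plane wave onto
#' the pi grating, silicon wafer substrate, two-material cylinder 0.9 mm
#' behind the wafer, surrounded by air. Three modes: semi-classical with an
#' implicit grating (attenuation via the transmission function, deficit
#' tallied in the grating), semi-classical with an explicit grating geometry
#' (interactions inside the grating sections of a phase-neutral silicon
#' medium), and conventional classical MC. Energy is conserved exactly by
#' construction; the per-structure fractions of the modes are compared in
#' the validation suite.
#'
#' @param scn scenario from [scenario_deposited_energy()]
#' @param chunk histories per chunk
#' @return list with the `gi_ledger`, its fractions, and the pixel signal
#' @export
run_deposited_energy <- function(scn, chunk = 5e4) {
  set.seed(scn$seed)
  E0 <- scn$E
  k <- wavenumber_from_energy(E0)
  p <- scn$period
  t_pi <- pi_phase_thickness("Si", E0)
  z_g <- 0
  z_w0 <- z_g + t_pi + 5e-6
  z_w1 <- z_w0 + scn$wafer_thickness
  z_c <- z_w1 + scn$gap
  z_det <- z_g + scn$d_det
  bw <- scn$beam_half_width
  structures <- c("air", "wafer", "G1", "cylinder")
  led <- gi_ledger(structures)
  regions <- list(
    region_slab(z_w0, z_w1, material = "Si", label = "wafer"),
    region_cylinder(0, z_c, scn$R, scn$material, label = "cylinder"))
  g1_region <- region_slab(z_g, z_g + t_pi, material = "Si", label = "G1")
  g1_region$grating <- list(period = p, duty = scn$duty, x0 = 0)
  conv_regions <- c(list(g1_region), regions)
  geom_conv <- gi_geometry(conv_regions, background = "air",
                           x_range = c(-2e-2, 2e-2),
                           z_range = c(z_g - 1e-3, z_det))
  det <- detector_grid(z = z_det, x_min = -bw, x_max = bw,
                       bin_width = p / 32)
  g <- gi_grating(z = z_g, period = p, duty = scn$duty, mode = "fourier",
                  material = "Si", thickness = t_pi, n_split = scn$n_split)
  nh <- scn$n_histories
  led$emitted <- nh * E0
  if (scn$grating_mode == "conventional") {
    # classical straight-line MC through the full explicit geometry
    done <- 0L
    while (done < nh) {
      nb <- min(chunk, nh - done)
      x0 <- .strat_positions(c(-bw, bw), seq.int(done + 1L, done + nb), nh, TRUE)
      res <- run_conventional_transport(
        x = x0, z = rep(z_g - 0.5e-3, nb), ux = rep(0, nb), uz = rep(1, nb),
        E = rep(E0, nb), sw = rep(1, nb),
        geom = geom_conv, ledger = led, detector_z = z_det, det = det)
      led <- res$ledger; det <- res$det
      done <- done + nb
    }
  } else {
    implicit <- scn$grating_mode == "implicit"
    geom_amp <- gi_geometry(regions, background = "air",
                            x_range = c(-2e-2, 2e-2),
                            z_range = c(z_g - 1e-3, z_det))
    done <- 0L
    while (done < nh) {
      nb <- min(chunk, nh - done)
      x0 <- .strat_positions(c(-bw, bw), seq.int(done + 1L, done + nb), nh, TRUE)
      batch <- path_batch(x = x0, z = z_g, k = k, hist = seq.int(done + 1L, done + nb))
      res <- .semiclassical_leg_run(batch, g, geom_amp, geom_conv, led, det,
                                    implicit = implicit,
                                    z_w0 = z_w0, z_w1 = z_w1, z_c = z_c,
                                    z_det = z_det, scn = scn, t_pi = t_pi)
      led <- res$ledger; det <- res$det
      done <- done + nb
    }
  }
  det <- close_cohort(det, "per-bin-paths-squared")
  list(ledger = led, fractions = ledger_fractions(led),
       detector = det, scenario = scn)
}

# semi-classical transport of one chunk through the inverted-cylinder
# geometry, with explicit interaction sampling on the interfering primaries
.semiclassical_leg_run <- function(batch, g, geom_amp, geom_conv, led, det,
                                   implicit, z_w0, z_w1, z_c, z_det, scn,
                                   t_pi) {
  E0 <- scn$E
  # --- grating plane: Fourier splitting -------------------------------------
  if (implicit) {
    batch <- g1_split(batch, g, sw_mode = "parseval")
    # left-over statistical weight is energy deposited in the grating
    led <- ledger_add(led, "G1", attr(batch, "absorbed_frac") * E0)
  } else {
    batch <- g1_split(batch, g, sw_mode = "normalized")
    # explicit grating geometry: interactions inside the absorber sections
    # (phase handled by the transmission function; the section medium is
    # phase neutral)
    open <- g0_classical_mask(batch$x, g)
    chord_g <- ifelse(open, 0, t_pi / batch$uz)
    int1 <- sample_interaction_site(chord_g, "Si", E0)
    hit <- int1$interacts
    led_det <- .primary_interactions(batch, which(hit), "G1", "Si",
                                     led, det, geom_conv, z_det,
                                     s_along = int1$s[hit])
    led <- led_det$ledger; det <- led_det$det
    batch$mode[hit] <- 1L
  }
  ux <- batch$ux; uz <- batch$uz
  # --- wafer substrate ------------------------------------------------------
  off_w <- (z_w0 - batch$z) / uz
  chord_w <- (z_w1 - z_w0) / uz
  intw <- sample_interaction_site(chord_w, "Si", E0)
  hit <- intw$interacts & batch$mode == 0L
  led_det <- .primary_interactions(batch, which(hit), "wafer", "Si",
                                   led, det, geom_conv, z_det,
                                   s_along = (off_w + intw$s)[hit])
  led <- led_det$ledger; det <- led_det$det
  batch$mode[hit] <- 1L
  # --- cylinder (straight-ray chord; the microradian refraction shift is
  # irrelevant for interaction sampling) -------------------------------------
  bq <- ux * (batch$x - 0) + uz * (batch$z - z_c)
  cq <- (batch$x - 0)^2 + (batch$z - z_c)^2 - scn$R^2
  disc <- bq^2 - cq
  t_entry <- -bq - sqrt(pmax(disc, 0))
  chord_c <- ifelse(disc > 0 & t_entry > 0, 2 * sqrt(pmax(disc, 0)), 0)
  intc <- sample_interaction_site(chord_c, scn$material, E0)
  hit <- intc$interacts & batch$mode == 0L
  led_det <- .primary_interactions(batch, which(hit), "cylinder",
                                   scn$material, led, det, geom_conv, z_det,
                                   s_along = (t_entry + intc$s)[hit])
  led <- led_det$ledger; det <- led_det$det
  batch$mode[hit] <- 1L
  # --- surrounding air (one pooled segment; sites are placed on the long
  # stretch behind the cylinder, where almost all of the air path lies) ------
  air_len <- pmax((z_det - batch$z) / uz - chord_c - chord_w -
                    (if (implicit) 0 else
                       ifelse(g0_classical_mask(batch$x, g), 0, t_pi / uz)), 0)
  inta <- sample_interaction_site(air_len, "air", E0)
  hit <- inta$interacts & batch$mode == 0L
  off_a <- pmax(t_entry + chord_c, (z_w1 - batch$z) / uz)
  led_det <- .primary_interactions(batch, which(hit), "air", "air",
                                   led, det, geom_conv, z_det,
                                   s_along = pmin(off_a + inta$s,
                                                  0.99 * (z_det - batch$z) / uz)[hit])
  led <- led_det$ledger; det <- led_det$det
  batch$mode[hit] <- 1L
  # --- amplitude transport to the detector ----------------------------------
  batch <- propagate_to_plane(batch, z_det, geom_amp, keep_r_norm = FALSE)
  # energy of never-interacted primaries leaves through the detector plane
  alive <- batch$mode == 0L
  led <- ledger_add(led, "leave_at_D", E0 * batch$sw[alive])
  det <- det_accumulate(det, batch)
  list(ledger = led, det = det)
}

# statistical outcome of interactions on interfering primaries: channel
# selection, local deposits, Compton/Rayleigh-scattered photons into
# conventional transport; the interfering clone is handled by the caller
# (mode flag).  s_along gives the distance from the path's current position
# to the interaction site.
.primary_interactions <- function(batch, idx, label, matname, led, det,
                                  geom_conv, z_det, s_along) {
  if (!length(idx)) return(list(ledger = led, det = det))
  E <- batch$k[idx] * .gi_const$hc_keV_m / (2 * pi)
  sw <- batch$sw[idx]
  xs <- batch$x[idx] + s_along * batch$ux[idx]
  zs <- batch$z[idx] + s_along * batch$uz[idx]
  chan <- select_channel(E, matname)
  ph <- chan == 1L
  if (any(ph)) led <- ledger_add(led, label, E[ph] * sw[ph])
  cm <- chan == 2L
  if (any(cm)) {
    cs <- compton_sample(E[cm])
    led <- ledger_add(led, label, (E[cm] - cs$E_out) * sw[cm])
    d <- .deflect(batch$ux[idx][cm], batch$uz[idx][cm], cs$theta)
    res <- run_conventional_transport(
      x = xs[cm], z = zs[cm],
      ux = d$ux, uz = d$uz, E = cs$E_out, sw = sw[cm],
      geom = geom_conv, ledger = led, detector_z = z_det, det = det)
    led <- res$ledger; det <- res$det
  }
  ry <- chan == 3L
  if (any(ry)) {
    # Rayleigh-scattered paths keep their full energy; the Thomson angles
    # are far outside the paraxial pipeline, so they continue as classical
    # particles (see vignette)
    d <- .deflect(batch$ux[idx][ry], batch$uz[idx][ry],
                  rayleigh_sample_angle(sum(ry)))
    res <- run_conventional_transport(
      x = xs[ry], z = zs[ry],
      ux = d$ux, uz = d$uz, E = E[ry], sw = sw[ry],
      geom = geom_conv, ledger = led, detector_z = z_det, det = det)
    led <- res$ledger; det <- res$det
  }
  list(ledger = led, det = det)
}

# ---------------------------------------------------------------------------
# Laboratory Talbot-Lau setup

#' Run the table-top Talbot-Lau experiment
#'
#' Incoherent Gaussian line source with the filtered triangle spectrum,
#' collimated onto the detector field of view; classical mask plus Fourier
#' splitting at the source grating G0, Fourier orders at the silicon phase
#' grating G1; no analyzer: the detector records the fringes directly,
#' phase stepping is applied in post processing. Amplitudes interfere only
#' within one history (one classical photon).
#'
#' @param scn scenario from [scenario_lab_talbot_lau()]
#' @param chunk histories per chunk
#' @return list with fine-bin signal, path-count bookkeeping and scenario
#' @export
run_lab_talbot_lau <- function(scn, chunk = 50) {
  set.seed(scn$seed)
  z_g0 <- scn$z_g0
  z_g1 <- z_g0 + scn$d01
  z_det <- z_g1 + scn$d12
  g0 <- gi_grating(z = z_g0, period = scn$p0, duty = 0.5, mode = "fourier",
                   n_q = scn$n_q_g0)
  t_pi <- pi_phase_thickness("Si", scn$design_E)
  g1 <- gi_grating(z = z_g1, period = scn$p1, duty = 0.5, mode = "fourier",
                   material = "Si", thickness = t_pi, n_split = scn$n_g1)
  fringe <- scn$p2
  det <- detector_grid(z = z_det, x_min = -scn$fov / 2, x_max = scn$fov / 2,
                       bin_width = fringe / 16, pixel_size = scn$pixel)
  src <- source_incoherent(scn$spectrum, scn$fwhm, scn$n_histories,
                           aim_extent = c(-scn$fov / 2, scn$fov / 2),
                           aim_z = z_det, z = 0)
  geom <- gi_geometry()
  nh <- scn$n_histories
  done <- 0L
  emitted_w <- 0; arrived_w <- 0
  while (done < nh) {
    nb <- min(chunk, nh - done)
    batch <- emit_histories(src, nb, first = done + 1L)
    emitted_w <- emitted_w + sum(batch$sw)
    batch <- propagate_to_plane(batch, z_g0, geom, keep_r_norm = TRUE)
    if (scn$gratings) {
      batch <- g0_fourier_split(batch, g0)
      batch <- propagate_to_plane(batch, z_g1, geom, keep_r_norm = TRUE)
      batch <- g1_split(batch, g1)
    } else {
      batch <- propagate_to_plane(batch, z_g1, geom, keep_r_norm = TRUE)
    }
    batch <- propagate_to_plane(batch, z_det, geom, keep_r_norm = TRUE)
    # accumulate relative to the spherical reference wavefront of the source
    # plane (the residual per-history curvature is negligible within a bin)
    ref <- (batch$k * (sqrt(z_det^2 + batch$x^2) - z_det)) %% (2 * pi)
    batch$w <- batch$w * exp(-1i * ref)
    # per-history coherent cohorts within this chunk
    det <- .accumulate_per_history(det, batch)
    done <- done + nb
  }
  list(x = det$x, intensity = det$intensity, detector = det,
       emitted = emitted_w, scenario = scn)
}

# add |field|^2 per history to the detector intensity (incoherent source:
# coherence only within one history's descendants)
.accumulate_per_history <- function(det, batch) {
  i <- .det_bin(det, batch$x)
  ok <- !is.na(i) & batch$mode < 2L
  if (!any(ok)) return(det)
  hid <- match(batch$hist[ok], unique(batch$hist[ok]))
  key <- (hid - 1) * det$n_bins + i[ok]
  fre <- rowsum(Re(batch$w[ok]), key)
  fim <- rowsum(Im(batch$w[ok]), key)
  I <- fre[, 1]^2 + fim[, 1]^2
  bin <- (as.integer(rownames(fre)) - 1) %% det$n_bins + 1
  det$intensity <- det$intensity + .bin_sum(I, bin, det$n_bins)
  det
}
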