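---
title: "Semi-classical Monte Carlo simulation of X-ray grating interferometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-classical Monte Carlo simulation of X-ray grating interferometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

X-ray grating interferometry measures absorption, differential phase and
small-angle scattering of a sample by reading out the interference fringes
that one or more periodic gratings imprint on the beam.  Classical Monte
Carlo photon transport cannot produce these fringes — interference requires
amplitudes, not probabilities.  Full wave-optics propagation, on the other
hand, does not mix naturally with the stochastic interaction physics
(photoelectric absorption, Compton and Rayleigh scattering, energy
deposition) that a dosimetric or scatter study needs.

`giray` implements the semi-classical middle ground: each photon history is
transported along *piecewise-straight classical paths*, but every path
carries a complex amplitude.  Over a free segment of length $d$ through a
medium of refractive index $n = 1-\delta+i\beta$ the amplitude is
multiplied by

$$A = \frac{e^{\,i\,n\,k\,d}}{d},$$

so the real part of $n$ accumulates optical phase, the imaginary part
produces Beer–Lambert amplitude decay ($\mu = 2k\beta$), and the $1/d$
factor is the spherical-wave norm (omitted for collimated, plane-wave
cohorts).  At the detector the amplitudes of all paths that belong to one
coherent cohort are summed *within fine spatial data points*, and the
intensity is $|\sum A|^2$, renormalised per data point by the squared
number of contributing paths.  For a fully coherent source the cohort is
the whole run; for an incoherent source it is one history together with
all paths split off it.

## Splitting at gratings

A thin periodic element with complex transmission $\tau(x,k)$ multiplies
the field by $\tau$.  In path language this is realised by *splitting*:

* **Huygens splitting** fans a path into $N$ equal-weight directions
  ($w/\sqrt N$ each) spread uniformly over a configured angular range —
  faithful to the Huygens–Fresnel principle but wasteful.
* **Fourier splitting of a phase grating** replaces the fan by the
  discrete diffraction orders $n \in [-N, N]$ with amplitudes given by the
  Fourier coefficients $\hat\tau_n$ of the binary profile (closed form for
  a binary grating), each order deflecting the transverse wavenumber by
  $2\pi n/p$.  The position-dependent phase $e^{-i2\pi n x/p}$ keeps the
  exact lateral register of the grating.
* **Fourier splitting of an absorption grating** first applies the
  classical binary mask (paths hitting an absorbing section are removed;
  with an implicit grating their statistical weight is tallied as locally
  deposited energy) and then samples random momentum transfers $\pm Q$
  with sinc-shaped slit weights, $Q \in (0,\, 2\cdot 2\pi/a]$ for slit
  width $a$.

Each splitting event conserves the statistical weight exactly:
$\sum_j |z_j|^2 = 1$ over the descendants of one path (Parseval).  For
phase gratings with absorbing substance the package offers two
conventions, selected by `sw_mode` in `g1_split()`: `"parseval"` keeps the
deficit $1 - \langle|\tau|^2\rangle$ as energy deposited at the grating
plane (implicit grating), `"normalized"` renormalises the statistical
weights to one so that an explicit grating geometry can sample the
interactions instead.

## Refraction and scattering

At smooth material boundaries (cylinder surfaces) the classical directions
are refracted by Snell's law with the real indices $1-\delta$; below the
critical grazing angle $\sqrt{2\delta}$ the path is totally reflected.
Interaction sites along a segment are sampled from the Beer–Lambert law
with the total attenuation coefficient; channels (photoelectric, Compton,
Rayleigh) are selected proportionally to the partial coefficients.
Compton angles come from a Klein–Nishina rejection sampler, Rayleigh
angles from the Thomson distribution.  Energy transferred to electrons is
deposited locally (KERMA-style, no electron transport).  To preserve the
interference pattern, an interacted history also continues as a
*ray-trace-only clone* whose amplitude still interferes but which can no
longer deposit; the scattered photons are handed to a conventional
classical transport loop and accumulate in an incoherent detector channel.
A Rayleigh-scattered path keeps interfering once (elastic, coherent); from
the second Rayleigh event on it is demoted to the classical channel — an
approximation that avoids unbounded coherent path trees and is harmless at
the per-mille Rayleigh probabilities involved.

All deposits are booked in a `gi_ledger` per named structure; every run
conserves `emitted = sum(deposits)` to $10^{-9}$ relative by construction,
which the test suite asserts.

# Numerical choices

**Reference-sphere accumulation.**  For point-like or incoherent sources
the wavefront at the detector is spherical; across one fine data point the
quadratic phase $k x^2/2d$ can vary by radians, which would wash out the
per-bin coherent sum — a pure binning artefact.  The runners therefore
subtract the known reference phase $k(\sqrt{d^2+x^2}-d)$ from every path
before binning.  This is a change of reference frame, not of physics: the
binned intensity pattern is unchanged, only its representation within a
bin becomes band limited.

**Data-point sizes.**  Coherent accumulation uses data points fine enough
that the field phase is essentially constant inside one bin (period/256
for the Talbot carpet, fringe/16 for stepping-based retrieval, where the
retrieval is first-harmonic based and thus robust).  Carpet comparisons
against the wave-optics oracle are made on a fixed grid of 8 intensity
points per half-period fringe — the resolution floor at which a fringe is
still well resolved — with the fine coherent accumulation underneath
averaged (in intensity) onto that grid.  The reported carpet rmse is
sensitive to this convention because the $N=41$ Fourier truncation rings
at sharper resolutions; the package states its convention and applies it
uniformly.

**Wave-optics oracle.**  `fresnel_propagate()` implements the
angular-spectrum propagator $H(f) = e^{-i\pi\lambda z f^2}$ with periodic
boundary conditions.  Binary gratings need dense sampling: the bundled
`talbot_carpet_oracle()` samples at period/256; coarser grids alias the
profile edges and ring.  A `check = "strict"` mode rejects propagations
whose transfer-function phase is unresolved.

**Edge determinism.**  Sampled binary profiles (grating sections, stepping
masks) classify points that sit exactly on a section edge by an explicit
rounding rule (half-open slit $[0, \text{duty})$, fractional coordinate
rounded to $10^{-9}$ periods; stepping-mask edge bins count half).
Without this, floating-point accidents break the exact periodicity of the
sampled profiles and the exactness of synthetic-fringe retrieval.

**Material data.**  Bundled media (Si, Au, Ir, polystyrene, air) carry
hand-transcribed total mass-attenuation anchors on a 4–100 keV grid with
log–log interpolation, split into photoelectric/incoherent/coherent
channels by a Klein–Nishina-based parameterisation; $\delta$ comes from
the electron-density formula at a 17 keV reference and scales with
$\lambda^2$.  Absorption-edge fine structure is not represented; all
bundled experiments operate far from the K edges of the media involved.
Derived anchors are tested: the $\pi$-shift thickness of silicon at
20 keV ($\approx 24.4\,\mu$m vs the quoted $25\,\mu$m), opacity of 0.1 mm
gold, and the analyzer visibility correction factor 0.96 at 21 keV.

# Bundled experiments and desk sizes

The five bundled scenarios reproduce published benchmark setups of the
semi-classical scheme.  The default `scale` arguments are the package's
own desk-scale choices: sizes at which the respective comparison is no
longer statistics limited on a single CPU within minutes.

* `scenario_double_slit()` — 17 keV point source, slits $a=0.2\,\mu$m at
  $b=2.2\,\mu$m, $l=1.1$ m, $d=0.1$ m, $10^5$ histories; rmse vs the
  analytic Fraunhofer forms (two-slit, and single-slit with a gold block).
* `scenario_talbot_carpet()` — 20 keV plane wave, $p=4\,\mu$m $\pi$
  grating, 25 planes between the first and third fractional Talbot
  distances (3.23–9.68 cm); Pearson/rmse vs the Fresnel oracle.  The
  carpet residual is resolution limited already at $2\times10^5$
  histories per plane.
* `scenario_cylinder()` — $R=0.87$ mm cylinder in front of a $2\,\mu$m
  $\pi$ grating, detector at the third fractional distance (2.42 cm),
  phase stepping in post processing, $10^7$ histories (a 1/50 desk scale
  of the full-size study).
* `scenario_deposited_energy()` — inverted geometry (grating first, then
  wafer, cylinder, air), three modes: implicit, explicit and conventional
  transport; per-structure energy fractions.  Note that this 2-D row
  models an all-silicon cylinder; a 3-D cylinder that is half silicon and
  half polystyrene along its axis halves the silicon-related fractions.
* `scenario_lab_talbot_lau()` — incoherent Gaussian line source
  (FWHM $10\,\mu$m), filtered triangle spectrum (4–40 keV, peak 19 keV,
  mean 21 keV), $p_{0,1,2} = 1/1.5/3\,\mu$m, distances 20.1/60.3 cm.  The
  full-size study splits each path into $1.2\times10^6$ at the source
  grating; the desk default is a configurable $10^4$ (`n_q_g0`), enough
  to demonstrate the 3 µm fringe periodicity, while the fringe visibility
  remains splitting-noise limited below the full-scale value.

# Limitations

* 2-D transverse geometry (one lateral coordinate); cylinder rows model
  3-D cylinders only per-row.
* Paraxial splitting kinematics; Rayleigh/Compton-scattered photons leave
  the coherent pipeline (see above) and cannot re-interfere.
* No electron transport (KERMA-style deposition), no polarization, no
  reflection gratings, no partial Fresnel reflectivity (only total
  reflection at grazing incidence).
* Attenuation tables are smooth interpolations without edge structure;
  energies outside 4–100 keV are rejected rather than extrapolated.
* The wave-optics oracle assumes periodic boundary conditions and thin
  elements; it is a reference for free propagation after a thin grating,
  not a general beamline simulator.
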