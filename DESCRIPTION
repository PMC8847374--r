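Package: giray
Title: Semi-Classical Monte Carlo Simulation of X-Ray Grating Interferometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Ray-traced Monte Carlo photon transport with complex path
    amplitudes for X-ray grating interferometry. Photon paths carry a complex
    weight accumulated through media via the complex refractive index, fork at
    gratings either by Huygens-type uniform splitting or by Fourier-splitting
    variance reduction (sinc-weighted momentum transfers at absorption
    gratings, Fourier-series orders at phase gratings), refract at medium
    interfaces via Snell's law, and are summed coherently in fine detector
    bins. Inelastic (photoelectric, Compton) and Rayleigh scattering are
    coupled to the ray tracing with energy-deposition ledgers. Includes an
    independent angular-spectrum Fresnel propagator used as a wave-optics
    reference, analytic interference formulas, phase-stepping retrieval of
    absorption and differential phase contrast, and bundled scenarios for
    double-slit diffraction, Talbot self-imaging, cylinder projections,
    deposited energy and a table-top Talbot-Lau setup.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
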