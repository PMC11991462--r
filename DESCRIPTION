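Package: radiopeek
Title: Photon Attenuation and X-Ray Imaging Performance of Radiopaque PEEK Composites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating polymer-matrix implant materials for X-ray
    radiopacity over the diagnostic energy range (20-120 keV). Provides a
    parameterized per-element photoatomic model with K-edge discontinuities,
    material-level photon interaction parameters (mass and linear attenuation
    coefficients, half value layer, effective atomic number and electron
    density), a Monte Carlo photon transport simulator with energy-deposition
    tallies and projection imaging, image-quality statistics (signal-to-noise
    ratio, energy-deposition fluctuation metrics), and a one-command study
    pipeline comparing polyetheretherketone (PEEK) against composites filled
    with barium sulfate, tantalum, bismuth oxide, and hydroxyapatite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
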