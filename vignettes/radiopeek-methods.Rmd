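---
title: "Methods: photon physics, transport and imaging metrics in radiopeek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon physics, transport and imaging metrics in radiopeek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiopeek)
```

`radiopeek` evaluates polymer-matrix implant materials for X-ray
radiopacity. This vignette documents the physical model, the choices behind
its parameters, the numerical conventions, and the limits of what the
package's tests demonstrate.

## Materials

A material is an elemental composition (weight fractions summing to 1
within 1e-9) plus a bulk density. Compositions come from chemical formulas
(`parse_formula()` handles symbols, counts and parenthesised groups) or
from explicit weight fractions (cortical bone uses the ICRP elemental
composition: H 3.4, C 15.5, N 4.2, O 43.5, Na 0.1, Mg 0.2, P 10.3, S 0.3,
Ca 22.5 wt%, density 1.92 g/cm^3). PEEK is modelled from its repeat unit,
taken as C19H12O3 — three phenylene rings joined by two ether oxygens and
one carbonyl — at 1.32 g/cm^3.

The four composites carry a 20 wt% filler loading of BaSO4, Ta, Bi2O3 or
hydroxyapatite Ca10(PO4)6(OH)2. Their bulk densities (1.52, 4.65, 3.84 and
1.68 g/cm^3) are tabulated study inputs carried verbatim: they do not all
agree with the linear rule of mixtures
\(\rho = f\rho_f + (1-f)\rho_m\) (20 wt% Ta on PEEK gives 4.386, not
4.65), having been obtained from extrapolated composite trends rather than
from that rule. The package exposes `mixture_density()` as a utility but
deliberately does not reverse-engineer the tabulated values; density only
rescales \(\mu/\rho\) to \(\mu\), so all mass-coefficient comparisons are
unaffected.

## Photoatomic model

Per-element coefficients (cm^2/g, energies in keV, valid on 10–150 keV)
are the sum of three terms:

* **Photoelectric**: a two-branch power law \(a\,E^{-p}\) with an upward
  discontinuity at the K-edge. Branch coefficients are derived at load time
  from anchor constants (two energies and values per branch) frozen in
  `extdata/photoatomic_anchors.csv`. The anchors were generated from a
  screened-hydrogenic-style amplitude law \(\sigma \propto Z^4 E^{-3.1}\)
  calibrated against light-element reference values (carbon and oxygen at
  30 keV), with a Z-dependent slope \(p(Z) = 3.30 - 0.010Z\) (floored at
  2.40) mimicking the flattening of the photoelectric cross-section for
  heavy elements, and K-shell jump ratios 5.6 (Ba), 4.7 (Ta) and 4.3 (Bi).
  Hand checks against standard photoatomic tabulations put the model within
  a few tens of percent across the grid (e.g. tantalum at 100 keV: model
  2.7, reference ≈ 1.9 cm^2/g) — adequate for the comparative and
  property-based analyses here, and not a substitute for evaluated data
  libraries when absolute coefficients matter.
* **Incoherent**: the free-electron Klein–Nishina cross-section times
  \(Z/A \cdot N_A\). Neglecting the incoherent scattering function is the
  model's main simplification; it overestimates Compton attenuation below
  ~50 keV for high-Z elements.
* **Coherent**: a per-element power law \(\sigma \propto Z^{2.5} E^{-1.9}\)
  calibrated the same way, included by default and toggleable everywhere
  (`include_coherent`). The transport simulator consumes the same
  per-process coefficients, so analytic and Monte Carlo results are
  self-consistent whatever the toggle.

K-edges inside the diagnostic window are embedded per element: Ba 37.4,
Ta 67.4, Bi 90.526 keV; elements with edges below the grid store 0.
Tables generated by `build_default_library()` duplicate the grid node at
each in-range edge, carrying the below-edge and above-edge values at the
same energy; `interpolate_log_log()` works in (ln E, ln coefficient), is
exact on power laws, refuses to extrapolate, and returns the above-edge
branch for a query exactly at the edge (the convention the locator and the
attenuation curves rely on).

## Attenuation parameters

`mixture_mu_m()` applies the weight-fraction mixture rule;
`total_atomic_cross_section()` divides by atoms per gram
\(N_A\sum_i w_i/A_i\); the electronic cross-section uses the standard
atom-fraction form \(\sigma_{t,el} = N_A^{-1}\sum_i f_i (A_i/Z_i)
(\mu/\rho)_i\) (the common typographically mangled variants of this
formula collapse to nonsense; the form here is validated by the
pure-element identities \(Z_\mathrm{eff} = Z\) and
\(N_\mathrm{eff} = N_A Z/A\), which the tests enforce to 1e-9 for every
library element across the grid). The default reporting grid is 20–120 keV
at 0.1 keV with duplicated edge nodes.

`locate_k_edge()` reports the energy of the largest upward jump between
adjacent grid points, requires a step of at most 0.1 keV, and returns `NA`
when no jump exceeds a 5% relative threshold — pure PEEK, bone and the HA
composite have no edge in the window, and a threshold well below the
smallest real composite jump (the 20 wt% BaSO4 curve roughly triples at
37.4 keV) but well above the grid-to-grid variation of a smooth curve makes
the decision unambiguous.

## Monte Carlo transport

The experiment mirrors a radiographic set-up: a 100 × 100 cm planar source
at Z = −50 cm emits photons along +Z, positions uniform over the plate and
energies uniform on 20–120 keV (1e6 events by default; runs with fewer are
flagged `scaled_down` in the study manifest). The phantom dimensions are a
package choice, since only the source geometry is fixed by the study
design: six 5 cm cubes (bone, PEEK, four composites) sit side by side
along X with 2 cm gaps, front faces at Z = 0, in vacuum. Photons are
tracked analytically through vacuum (ray–box intersection by the slab
method, with 1e-9 cm nudges across boundaries) and stochastically inside
volumes (exponential free paths, process selection proportional to the
partial linear coefficients).

Interactions: photoelectric absorption deposits the full photon energy
locally and terminates the photon — no fluorescence or Auger relaxation is
modelled, a documented simplification that matters most for tantalum,
whose K fluorescence would carry ~57 keV out of small volumes. Compton
scattering samples the polar angle from the Klein–Nishina density by
rejection with a uniform-in-\(\cos\theta\) envelope (the forward Thomson
value bounds the density; sampled histograms pass goodness-of-fit against
the analytic density at n = 1e5), deposits the recoil-electron energy
locally and redirects the photon. Rayleigh scattering deflects with a
Thomson-shaped \(1+\cos^2\theta\) angular law and no energy loss. Photons
falling below 10 keV (the library floor) inside a volume are terminated
with a local deposit — their mean free path in every study material is
well under a millimetre there. Global energy conservation (deposits plus
escapes equal emissions) holds to better than 1e-6 relative per run and is
asserted by the tests.

Charged particles are not transported; the per-volume "track length" is a
proxy, \(R = 0.0143\,(E/100)^{1.7}/\rho\) cm per deposited electron
energy, i.e. a continuous-slowing-down-style range scaled by inverse
density. It preserves ordering and scaling behaviour but is not comparable
to condensed-history track-length tallies in absolute terms.

Randomness: one seeded R stream per run, consumed in a fixed internal
batching order, so a given seed, configuration and batch size reproduce
every tally bit for bit. Per-event substreams (reproducibility independent
of batching) were considered and rejected: they would force an event loop
where the vectorized implementation gains two orders of magnitude.

Deposits accumulate per event, per volume and on a voxel grid (default
100^3 over the tight bounding box of all volumes). Projections sum the
grid along one axis; per-material SNR is computed over each volume's
footprint — the projection of the volume-restricted subgrid — because the
YZ plane sums along the material axis and whole-plane masks there would
not separate materials. Whole-image SNR is reported alongside. SNR uses
the sample (n−1) standard deviation; a zero-variance footprint is flagged
and reported as infinite. Per-event statistics use the population RMS
(root mean squared deviation over all source events, zero-deposit events
included), and the fluctuation metric is \(100 \cdot \mathrm{RMS} /
\mathrm{mean}\), optionally scaled by \(\sqrt{E_0}\) with \(E_0\) the mean
source energy of the run — the natural reading of "initial energy" for a
uniform spectrum.

## Synthetic surfaces and parameter recovery

`make_test_image()` draws i.i.d. pixels with stated moments (truncated
normal by default, so the SNR expectation `mean/std` is closed-form and
the truncation rate is reported; a Poisson mode is available).
`transmission_experiment()` plus `mu_recovery()` close the loop between
the package's two halves: transport-sampled free paths generate
transmission counts, a log-linear least-squares fit (with intercept)
recovers \(\mu\), and the true library value falls inside the 99%
confidence interval — exactly for noiseless counts, statistically for
Monte Carlo counts.

## What the tests show — and what they do not

The test suite and the analysis drivers run at reduced scale (1e4–1e5
photons or events; the full study default is 1e6), with fixed seeds chosen
up front. Statistical assertions use 3-sigma bands of the relevant
sampling distribution. Passing them demonstrates internal consistency
(Monte Carlo versus closed form on the same library, estimator identities,
conservation laws, determinism) and the comparative physics of the six
materials. It does **not** demonstrate agreement with evaluated photon
data libraries, condensed-history electron transport, detector response or
polychromatic tube spectra — none of which are modelled.

Two comparative claims from the motivating study deserve flags. First, the
bismuth-oxide composite is *not* the strongest attenuator at every energy:
between the Ta K-edge (67.4 keV) and the Bi K-edge (90.5 keV) the 20 wt%
Ta composite attenuates more, because tantalum is above its K-shell
threshold there while bismuth is still below its own. This crossing is
real physics, visible in reference cross-section data, and the package
reports it rather than suppressing it. Second, with equal-size,
equally-irradiated volumes the mean per-event deposit of the Ta composite
(density 4.65, the highest linear coefficient at nearly all energies)
cannot fall below that of the much lighter BaSO4 composite; the simulator
accordingly ranks Ta above BaSO4, while reproducing the rest of the
ordering (heavy composites above bone, above the HA composite, above
PEEK). Fluorescence escape from tantalum, or a different unreported
geometry, could produce the opposite ranking; neither is modelled here.

## Known limitations

* Photoelectric amplitudes are accurate to tens of percent, not evaluated-
  library grade; absolute \(\mu/\rho\), HVL and SNR values inherit that.
* Free-electron Compton and parameterized Rayleigh terms distort low-energy
  high-Z totals.
* No fluorescence, Auger cascades, electron transport, pair production
  (irrelevant below 1022 keV), buildup factors or detector modelling.
* The transport grid is limited to 10–150 keV; sources outside 20–120 keV
  are untested territory.
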