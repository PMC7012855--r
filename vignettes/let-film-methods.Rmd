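---
title: "Methods: LET averaging and film relative efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LET averaging and film relative efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(letfilm)
```

# The problem

Radiochromic films darken through radiation-induced polymerisation of their
active layer. How much darkening (net optical density, netOD) a given
absorbed dose produces depends on the beam quality: soft x rays need several
times less dose than Co-60 gammas to produce the same netOD. The working
hypothesis this package operationalises is that the relevant physical
variable is not the photon energy but the ionisation density — the linear
energy transfer (LET) — of the electron fluence the photons set in motion
inside the sensitive layer, and in particular of its secondary-electron (SE)
component, the electrons born in electron–electron collisions that deposit
their energy within nanometres of their origin.

# LET averages of a binned fluence spectrum

Two non-stochastic averages summarise the LET of an electron spectrum
Φ(E) (fluence differential in energy per unit absorbed dose):

* the **track average** L~Δ,T~, a fluence-weighted mean of the restricted
  stopping power L~Δ~(E);
* the **dose average** L~Δ,D~, which weights each spectral component by its
  contribution to absorbed dose; algebraically the second moment of L~Δ~
  over its first moment, so L~Δ,D~ ≥ L~Δ,T~ always (Cauchy–Schwarz), with
  equality only for a monoenergetic spectrum.

Spectra are scored down to a floor Δ = 1 keV, below which electron cross
sections are unreliable. Electrons slowing below Δ are collected by a
**track-end term** S(Δ)Φ(Δ)Δ added to the numerator (and Φ(Δ)Δ to the
fluence integral), where S is the unrestricted stopping power and Φ(Δ) is
read from the lowest bin — the simplest unbiased estimate for histogram
data. The dose-average denominator is exactly the track-average numerator,
so the track-end bin behaves as a spectral line at LET S(Δ).

Discretisation choices (all guarded by tests):

* bins are half-open `[lo, hi)`, evaluated at the arithmetic midpoint, as
  Monte Carlo tally post-processing conventionally does;
* stopping-power tables are interpolated log-log (stopping power is close
  to a power law); both averages are stable under 10× bin refinement to
  within 0.2% for smooth tables;
* both averages are invariant under any rescaling of Φ, so the per-dose
  normalisation never enters the result;
* uncertainties come from a parametric bootstrap — each bin resampled
  `Normal(phi, sigma)` truncated at zero, both averages recomputed —
  because the estimator is a nonlinear ratio; first-order propagation is
  only used as a cross-check in tests. Bins are treated as uncorrelated,
  which is what independent-history tallies justify.

Results convert to keV/µm with the material density (mass stopping power ×
density × 0.1). The active-layer density of either film is not published;
the registry uses a typical manufacturer value of 1.20 g/cm³ and every
headline quantity in the analysis is a ratio from which it cancels.

# Stopping powers

The analytic backend is the Møller/Bethe collision stopping power for
electrons with the restricted variant counting energy transfers below Δ
(closed form in the fraction η = Δ/E, exactly equal to the unrestricted
value for Δ ≥ E/2, the kinematic maximum between identical particles), and
a Sternheimer density-effect correction parameterised from the material's
mean excitation energy and electron density (on by default; sub-percent at
these energies). Radiative losses are excluded throughout — LET is a
collision quantity. Shell corrections are omitted to keep the backend
closed-form; the analytic water values agree with the bundled reference
table to better than 1% over 10 keV–2 MeV, and a tabulated backend (simple
two/three-column text files) is the escape hatch where more accuracy is
needed. The validity floor of 1 keV matches the spectra floor.

Material composites come from the atomic compositions: the film
compositions are the manufacturer **atomic** percentages (hydrogen at
56–58% is impossible by mass for these polymers), converted to mass
fractions with standard atomic weights. The effective atomic number uses
the Mayneord power law with electron-fraction weights and exponent 2.94 —
the conventional photoelectric-regime choice, which reproduces the film
data sheet values within 1%; the exponent is exposed as a parameter since
conventions differ. Mean excitation energies follow Bragg additivity with
the standard 1.13× condensed-phase adjustment for elements gaseous in pure
form; water gets the assigned 75 eV by override so the analytic backend
matches the reference table.

# Beam quality

X-ray qualities are characterised by their first half-value layer in
aluminium: µ = ln 2 / HVL, and the effective energy is the monoenergetic
energy with that attenuation coefficient, found by log-log inversion of a
bundled aluminium µ/ρ table (total, coherent scattering included, as HVL
practice dictates; aluminium has no absorption edges in the 5–200 keV
window, so the inversion is unique). Recomputed effective energies agree
with the tabulated beam qualities within 2%. The Co-60 beam is a special
case: its tabulated equivalent energy (1044.7 keV, the mean of the two
gamma lines) is stored verbatim and used as the LET-table abscissa, while
its nominal spectrum-defined effective energy is 1250 keV.

# Relative efficiency

RE of a film under beam quality Q is the Co-60 dose over the Q dose
producing the same netOD. Calibration curves (dose, netOD, σ) are modelled
with a monotone shape-preserving cubic (`monoH.FC`) through the measured
points; inversion D(netOD) solves the forward curve by root finding, so
the round trip is exact to the root tolerance, and never extrapolates —
the quantity is only defined where both curves respond. Noise-induced
local dips within 3σ are flattened by isotonic regression before
interpolation; larger violations are validation errors.

RE is evaluated at fixed netOD levels (red channel: 0.053/0.176/0.510 for
EBT3, 0.009/0.023/0.095 for MD-V3) and combined per beam into a
**weight-averaged RE** using inverse-variance weights across levels, with
an equal-weight fallback — the published analysis does not define its
weights, so the choice is labelled; when RE is truly level-independent (a
pure dose scaling between curves, which is how the generator constructs
its ground truth) any weighting returns the same number, which is the
behaviour the experimental reports describe. RE uncertainties combine the
two inversion uncertainties in quadrature on the log scale.

# The synthetic-data generator

The analysis consumes Monte Carlo fluence tallies and film calibration
curves; neither is publicly available, so a seeded generator reproduces
their *statistical shape* — not their physics — well enough that every
pipeline stage is exercised:

* **Spectra.** The SE component is a power-law tail A/T² over
  [1 keV, E~max~/2], the free-electron close-collision transfer shape. The
  primary component adds Gaussian photopeaks (at the beam's effective
  energy for photoelectric-dominated qualities) each with a flat
  slowing-down shelf below the peak, a smoothed flat-topped Compton
  continuum ending at the Compton edge of the effective energy with a
  low-energy slowing-down tail ~T^−1.2^, and narrow K-shell lines at
  1.07/1.56/2.47/2.82 keV (Na/Al/S/Cl) with amplitudes tied to the
  medium's composition. The slowing-down shelf and tail represent
  primaries migrating down in energy; without them no flat-topped
  continuum can simultaneously satisfy the two calibration facts the
  presets are built to: the SE fraction of the total fluence is 40–90%
  across 1–10 keV for Co-60 and below 30% at 1 keV for the soft x-ray
  qualities. Bin densities are 7-point sub-sampled averages on a
  logarithmic grid (140 bins), the pair is renormalised so the TEF CEMA
  (fluence × stopping power integral) is exactly 1 Gy per Gy, and
  truncated-normal noise (default 2% per bin, matching the uncorrelated
  uncertainty model) is applied under a local seed that leaves the
  caller's RNG untouched.
* **Dose-response curves.** netOD(D) = a(1 − e^−b·s·D^) on a logarithmic
  dose grid (0.05–25 Gy, 24 points), with film-typical a and b; the
  per-beam sensitivity s acts as a pure dose scaling, so the ground-truth
  RE equals s/s~Co60~ at every level. Default netOD noise is 0.5%
  (scanner-level repeatability); parameter-recovery tests use 1%.
* **Study fixture.** For 6 beams × 2 films the generator computes the
  dose-average LET of each synthetic TEF spectrum and sets the beam's
  sensitivity through a fixed monotone map (logistic rise of amplitude 2.6
  around 5 keV/µm, width 0.8 keV/µm, plus a slow 0.03/keV·µm terminal
  slope, base 1) — flat at low LET, rapid rise, slow continued rise, the
  shape the film literature reports. Everything is written to the package
  text dialects with a ground-truth manifest; regeneration under the same
  seed is byte-identical.

What passing tests on this fixture do **not** show: fidelity of absolute
LET values to transport calculations (the synthetic Co-60 track average is
~0.2 keV/µm against ~0.5 keV/µm for real tallies), realistic correlations
between bins, or detector physics beyond a saturating response. What they
do show: the estimators are correct on known ground truth (closed forms,
refinement stability, exact scaling recovery), and the pipeline's joins,
normalisations, uncertainties and reports behave deterministically.

# Published-grid statistics

Because the original fluence tallies are not published, the LET grid
printed in the study (both films × TEF/SE × six beams, Δ = 1 keV, 0.7%
combined standard uncertainty) ships as a fixture, and `cross_statistics()`
derives the summary ratios from it: dose/track ratios per spectrum, SE/TEF
track-LET ratios per beam, per-beam ratios relative to Co-60, and min/max
summaries rounded the way such numbers are conventionally quoted (ratios to
the nearest integer, percent excess to the nearest integer, sub-100 keV
dose/track ratios to one decimal). The reference beam for relative ratios
is Co-60 when present, otherwise the hardest available beam (with a
warning), and the reference is excluded from the min/max ranges.

# Problem sizes and determinism

Default problem sizes — 140 spectrum bins, 240-point stopping tables,
200–1000 bootstrap resamples, 100 recovery replicates — were chosen so the
statistical checks are comfortably resolved (bootstrap standard errors an
order of magnitude below the tolerances they guard) while the full suite
runs in well under a minute. All randomness flows from a single root seed
split deterministically per stage; reports are byte-identical across runs
with the same inputs and seed.

# Known limitations

* The analytic stopping powers omit shell corrections; below ~5 keV the
  Born approximation degrades and absolute values there should come from a
  tabulated backend if they matter.
* `Φ(E)` is treated as fluence differential in energy (the only reading
  under which the averaging formulas are ICRU-consistent), although tally
  outputs are sometimes labelled "energy fluence"; users supplying their
  own spectra must match the declared unit.
* The generator makes no transport claims; absolute synthetic LET values
  are not comparable to published tables, only the machinery that
  processes them is.
* Effective energies derived from HVL carry the ~2–3% interpolation-level
  agreement shown in `analysis/02_beam_quality.R`, not an uncertainty
  budget.
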