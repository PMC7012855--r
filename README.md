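# letfilm

Radiochromic films (Gafchromic EBT3 and MD-V3) under-respond to low-energy
photon beams, and the usual habit of describing that under-response as a
function of photon energy hides the quantity that actually drives it: the
ionisation density — the linear energy transfer (LET) — of the electrons set
in motion inside the film's sensitive layer. `letfilm` is an analysis
toolkit for medical physicists that characterises film response in terms of
the track-average and dose-average restricted LET of electron-fluence
spectra, and relates the film's relative efficiency to both.

## What it computes

Given a binned electron fluence Φ(E) per unit absorbed dose (1 keV floor),
a restricted stopping power L<sub>Δ</sub>(E) and unrestricted S(E), with
Δ = 1 keV:

- **Track-average LET** (fluence-weighted mean, with the track-end term
  collecting electrons that slow below Δ):

  L<sub>Δ,T</sub> = [∫<sub>Δ</sub><sup>Emax</sup> L<sub>Δ</sub>(E)Φ(E)dE + S(Δ)Φ(Δ)Δ] / [∫<sub>Δ</sub><sup>Emax</sup> Φ(E)dE + Φ(Δ)Δ]

- **Dose-average LET** (second moment over first moment; always ≥ the track
  average):

  L<sub>Δ,D</sub> = [∫ L<sub>Δ</sub>²(E)Φ(E)dE + S²(Δ)Φ(Δ)Δ] / [∫ L<sub>Δ</sub>(E)Φ(E)dE + S(Δ)Φ(Δ)Δ]

- **Relative efficiency** of the film under beam quality Q, from netOD–dose
  calibration curves: RE = D<sub>Co60</sub>(netOD) / D<sub>Q</sub>(netOD),
  weight-averaged over netOD levels per beam.

Around this core the package provides: electron collision stopping powers
(Møller/Bethe with Sternheimer density effect, or tabulated) for arbitrary
elemental compositions; power-law effective atomic numbers and Bragg-rule
mean excitation energies; photon beam quality (HVL → effective energy via a
bundled aluminium attenuation table); and a seeded synthetic-data generator
that emulates Monte Carlo fluence tallies and film calibration curves so the
whole pipeline runs and is tested without a transport code or film data.

## Worked example

```r
library(letfilm)

# film composition -> effective atomic number
effective_atomic_number(load_material("EBT3_active"))
#> [1] 7.510109

# beam quality: 0.25 mm Al first HVL -> effective energy
effective_energy(0.25)
#> [1] 13.75164

# LET of a synthetic Co-60 total-electron-fluence spectrum in the EBT3
# active layer
pair <- simulate_fluence_spectrum(default_spectrum_config("Co60", "EBT3_active", seed = 42))
tab  <- build_stopping_table(load_material("EBT3_active"),
                             exp(seq(log(1), log(1250), length.out = 240)))
let_averages(pair$tef, tab, n_boot = 500, seed = 1)
#> <let_result> EBT3_active / Co60 / TEF (delta = 1 keV)
#>   L_track = 0.1967 +/- 0.00051 keV/um
#>   L_dose  = 2.564 +/- 0.029 keV/um  (ratio 13)
```

The dose average exceeds the track average by an order of magnitude for the
Co-60 spectrum — the high-LET secondary-electron tail carries little fluence
but a disproportionate share of the dose, which is exactly why the dose
average is the more informative descriptor at high photon energies.

The `analysis/` directory holds the numbered drivers of the full study:

1. `01_materials.R` — Z_eff of both films vs the manufacturer values,
2. `02_beam_quality.R` — effective energies recomputed from the HVLs,
3. `03_published_let_statistics.R` — ratio statistics over the published
   LET grid (dose/track, SE/TEF, x-ray/Co-60),
4. `04_simulate_study.R` — the synthetic 6-beam × 2-film study fixture,
5. `05_full_pipeline.R` — the end-to-end run: LET grid, SE fractions,
   D(netOD)-vs-LET and RE-vs-LET tables, with ground-truth recovery.

Each writes its tables under `results/`.

## Scope notes

The package does not re-run radiation transport: published LET tables can
be loaded for ratio analysis (`load_printed_let_grid()`), and the synthetic
generator reproduces the *statistical shape* of fluence tallies (photopeaks,
Compton continuum, power-law secondary-electron tail, K-shell lines at
1.07/1.56/2.47/2.82 keV), not transport physics. See the methods vignette
(`vignettes/let-film-methods.Rmd`) for the model, parameter choices and
limitations.
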