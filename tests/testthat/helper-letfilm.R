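# Shared fixtures built in code.

water <- load_material("water")

# A stopping table whose linear LET values at the grid energies are exactly
# `let_keV_um` (density 1 g/cm^3, mass values 10x the linear ones), for
# closed-form averaging checks.
mock_table <- function(energies, let_keV_um, S_keV_um = let_keV_um,
                       delta = 1) {
  structure(
    list(material = NA_character_, density = 1, energies = energies,
         S = 10 * S_keV_um, L_delta = 10 * let_keV_um, delta = delta,
         density_effect = FALSE),
    class = "stopping_table")
}

# Random non-negative spectrum on a fixed log grid (seeded).
random_spectrum <- function(seed, n_bins = 30, e_max = 500,
                            medium = "water", beam = "test") {
  edges <- exp(seq(log(1), log(e_max), length.out = n_bins + 1))
  phi <- letfilm:::with_seed(seed, stats::rgamma(n_bins, shape = 0.8))
  fluence_spectrum(edges, phi, 0, kind = "TEF", medium = medium, beam = beam)
}

# Saturating dose-response curve netOD = a(1 - exp(-b*s*D)) on a log grid.
make_curve <- function(film = "EBT3", beam = "Co60", s = 1, a = 0.7, b = 0.1,
                       dose = exp(seq(log(0.05), log(25), length.out = 24)),
                       noise_rel = 0, sigma_rel = 0, seed = 1) {
  clean <- a * (1 - exp(-b * s * dose))
  netod <- if (noise_rel > 0) {
    letfilm:::with_seed(seed,
      pmax(0, clean * (1 + noise_rel * stats::rnorm(length(dose)))))
  } else clean
  dose_response_curve(film, beam, "red", dose, netod,
                      sigma_netod = sigma_rel * clean)
}

water_table <- build_stopping_table(
  water, exp(seq(log(1), log(2000), length.out = 200)))
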