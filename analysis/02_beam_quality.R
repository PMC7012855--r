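#!/usr/bin/env Rscript
# Beam quality: effective energies recomputed from the first HVLs via the
# aluminium attenuation fixture, with homogeneity coefficients.
# Writes results/beam_quality.tsv.

suppressPackageStartupMessages(library(letfilm))
dir.create("results", showWarnings = FALSE)

beams <- load_beams()
xr <- !is.na(beams$hvl1_mm_al)
beams$effective_energy_recomputed <- NA_real_
beams$effective_energy_recomputed[xr] <- effective_energy(beams$hvl1_mm_al[xr])
beams$homogeneity <- NA_real_
beams$homogeneity[xr] <- homogeneity(beams$hvl1_mm_al[xr],
                                     beams$hvl2_mm_al[xr])

write.table(format(beams, digits = 6), "results/beam_quality.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Effective energy from 1st HVL vs tabulated (keV):\n")
print(beams[xr, c("name", "hvl1_mm_al", "effective_energy_keV",
                  "effective_energy_recomputed", "homogeneity")],
      row.names = FALSE, digits = 4)
dev <- with(beams[xr, ],
            abs(effective_energy_recomputed / effective_energy_keV - 1))
cat(sprintf("\nMaximum deviation from the tabulated values: %.1f%%\n",
            100 * max(dev)))
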