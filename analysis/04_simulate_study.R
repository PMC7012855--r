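#!/usr/bin/env Rscript
# Generates the synthetic study fixture: TEF/SE fluence spectra and netOD
# calibration curves for 6 beams x 2 films, with a manifest of ground-truth
# sensitivity scales.  Writes results/study/.

suppressPackageStartupMessages(library(letfilm))
dir.create("results", showWarnings = FALSE)

seed <- 20211
man <- make_study_fixture("results/study", seed = seed)
cat(sprintf("Wrote %d files to results/study (seed %d)\n",
            length(list.files("results/study")), seed))
cat("\nGround-truth sensitivity scales (RE vs Co60):\n")
print(man, row.names = FALSE, digits = 4)
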