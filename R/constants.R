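# Internal physical constants.  Energies are keV, mass stopping powers
# MeV cm^2/g, densities g/cm^3 throughout the package.

.mec2 <- 510.99895           # electron rest energy, keV (CODATA 2018)
.k_col <- 0.1535355          # 2*pi*r_e^2*m_e*c^2*N_A, MeV cm^2 / mol
.hw_coef <- 28.8159          # plasma energy = 28.8159*sqrt(rho*<Z/A>) eV
.n_avogadro <- 6.02214076e23
.mev_g_to_gy <- 1.602176634e-10  # 1 MeV/g expressed in Gy

# Energy floor: electron cross sections are unreliable below 1 keV, which is
# also the delta cut used for restricted stopping powers and spectra.
.kev_floor <- 1.0
# Validity window of the analytic stopping-power backend, keV.
.e_valid <- c(1, 1e4)

.letfilm_cache <- new.env(parent = emptyenv())
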