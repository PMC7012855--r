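#' @title Photon beam quality
#' @description Half-value-layer based characterisation of the photon beams:
#'   attenuation coefficient from the first HVL, effective (monoenergetic
#'   equivalent) energy by inverting the aluminium mass-attenuation curve,
#'   and the homogeneity coefficient.
#' @name beam_quality
NULL

.rho_al <- 2.699  # g/cm^3

#' Aluminium mass-attenuation table
#'
#' Bundled fixture of total (with coherent scattering) mass attenuation
#' coefficients of aluminium on a 5 keV - 2 MeV grid; strictly decreasing,
#' so the HVL inversion is unique.
#'
#' @return data.frame with columns `energy_keV`, `mu_over_rho_cm2_g`; the
#'   aluminium density is attached as attribute `density`.
#' @export
al_attenuation <- function() {
  if (is.null(.letfilm_cache$al_mu)) {
    tab <- utils::read.delim(extdata_path("al_mu_over_rho.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
    attr(tab, "density") <- .rho_al
    .letfilm_cache$al_mu <- tab
  }
  .letfilm_cache$al_mu
}

#' Linear attenuation coefficient from an HVL
#'
#' @param hvl_mm half-value layer in mm (> 0).
#' @return mu in cm^-1 (`= ln 2 / (hvl/10)`).
#' @export
mu_from_hvl <- function(hvl_mm) {
  if (any(!is.finite(hvl_mm)) || any(hvl_mm <= 0)) stop("hvl must be > 0")
  log(2) / (hvl_mm / 10)
}

#' Effective energy from the first HVL
#'
#' Solves `mu/rho_Al(E) = mu_from_hvl(hvl1)/rho_Al` by monotone log-log
#' interpolation of the aluminium attenuation table.
#'
#' @param hvl1_mm first HVL in mm Al.
#' @param table attenuation table (default the bundled aluminium fixture).
#' @return effective energy in keV.
#' @export
effective_energy <- function(hvl1_mm, table = al_attenuation()) {
  mu_rho <- mu_from_hvl(hvl1_mm) / attr(table, "density")
  rng <- range(table$mu_over_rho_cm2_g)
  if (any(mu_rho < rng[1]) || any(mu_rho > rng[2])) {
    stop(sprintf("mu/rho = %.4g cm^2/g outside the table range [%.4g, %.4g]",
                 mu_rho[mu_rho < rng[1] | mu_rho > rng[2]][1],
                 rng[1], rng[2]))
  }
  # mu/rho decreases with E: interpolate log(E) on decreasing log(mu/rho)
  exp(stats::approx(log(table$mu_over_rho_cm2_g), log(table$energy_keV),
                    xout = log(mu_rho))$y)
}

#' HVL implied by a photon energy
#'
#' Inverse companion of [effective_energy()] (round-trip check).
#'
#' @param energy_keV photon energy in keV within the table grid.
#' @inheritParams effective_energy
#' @return HVL in mm Al.
#' @export
hvl_for_energy <- function(energy_keV, table = al_attenuation()) {
  rng <- range(table$energy_keV)
  if (any(energy_keV < rng[1]) || any(energy_keV > rng[2])) {
    stop("energy outside the attenuation table range")
  }
  mu_rho <- exp(stats::approx(log(table$energy_keV),
                              log(table$mu_over_rho_cm2_g),
                              xout = log(energy_keV))$y)
  mu <- mu_rho * attr(table, "density")
  10 * log(2) / mu
}

#' Homogeneity coefficient
#'
#' @param hvl1,hvl2 first and second HVL (same units, > 0).
#' @return `hvl1/hvl2` (<= 1 for hardening beams).
#' @export
homogeneity <- function(hvl1, hvl2) {
  if (any(!is.finite(c(hvl1, hvl2))) || any(c(hvl1, hvl2) <= 0)) {
    stop("HVLs must be positive")
  }
  hvl1 / hvl2
}

#' Bundled beam-quality registry
#'
#' The six photon beams of the film study: tube potential, added filtration,
#' first and second HVL (mm Al), effective energy, and the tabulated
#' equivalent energy used as the LET-table abscissa (for Co-60 the mean of
#' the two gamma lines, stored verbatim).
#'
#' @return data.frame, one row per beam.
#' @export
load_beams <- function() {
  utils::read.delim(extdata_path("beams.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
}
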