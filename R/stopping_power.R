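#' @title Electron collision stopping powers
#' @description Analytic Moller/Bethe evaluation of the unrestricted and
#'   restricted collision mass stopping power of electrons in any material,
#'   with an optional Sternheimer density-effect correction, plus tabulated
#'   backends read from simple two/three-column text files.  Radiative losses
#'   are excluded throughout: LET is a collision quantity.
#' @name stopping_power
NULL

check_energy_window <- function(E) {
  if (any(!is.finite(E)) || any(E < .e_valid[1]) || any(E > .e_valid[2])) {
    stop(sprintf("energy outside analytic validity window [%g, %g] keV",
                 .e_valid[1], .e_valid[2]))
  }
}

# Sternheimer density-effect correction delta(beta*gamma) from the general
# prescription: parameters derived from I (eV) and the plasma energy.
density_effect_delta <- function(mat, E) {
  I <- mean_excitation_energy(mat)
  hwp <- .hw_coef * sqrt(mat$density * mean_z_over_a(mat))  # eV
  Cbar <- 2 * log(I / hwp) + 1
  if (I < 100) {
    x1 <- 2.0
    x0 <- if (Cbar < 3.681) 0.2 else 0.326 * Cbar - 1.0
  } else {
    x1 <- 3.0
    x0 <- if (Cbar < 5.215) 0.2 else 0.326 * Cbar - 1.5
  }
  a <- (Cbar - 2 * log(10) * x0) / (x1 - x0)^3
  tau <- E / .mec2
  x <- log10(sqrt(tau * (tau + 2)))
  delta <- ifelse(x >= x1, 2 * log(10) * x - Cbar,
           ifelse(x >= x0, 2 * log(10) * x - Cbar + a * (x1 - x)^3, 0))
  pmax(delta, 0)
}

moller_bracket <- function(mat, E) {
  I_keV <- mean_excitation_energy(mat) * 1e-3
  tau <- E / .mec2
  beta2 <- tau * (tau + 2) / (tau + 1)^2
  lead <- log(tau^2 * (tau + 2) / (2 * (I_keV / .mec2)^2))
  list(tau = tau, beta2 = beta2, lead = lead)
}

#' Unrestricted collision mass stopping power
#'
#' Bethe stopping power with the Moller close-collision term for electrons,
#' `S/rho = k (Z/A)/beta^2 [ln(tau^2(tau+2)/2(I/mc^2)^2) + F(tau) - delta]`
#' with `F(tau) = 1 - beta^2 + (tau^2/8 - (2tau+1) ln 2)/(tau+1)^2`.
#' Shell corrections are omitted (the tabulated backend is the escape hatch
#' for higher accuracy below ~10 keV).
#'
#' @param mat a `material`.
#' @param E electron kinetic energy in keV (vectorised); valid 1 keV-10 MeV.
#' @param density_effect apply the Sternheimer correction (on by default).
#' @return MeV cm^2/g.
#' @export
collision_stopping_power <- function(mat, E, density_effect = TRUE) {
  stopifnot(inherits(mat, "material"))
  check_energy_window(E)
  if (mean_excitation_energy(mat) <= 0) stop("non-positive I")
  b <- moller_bracket(mat, E)
  Fterm <- 1 - b$beta2 +
    (b$tau^2 / 8 - (2 * b$tau + 1) * log(2)) / (b$tau + 1)^2
  delta <- if (density_effect) density_effect_delta(mat, E) else 0
  .k_col * mean_z_over_a(mat) / b$beta2 * (b$lead + Fterm - delta)
}

#' Restricted collision mass stopping power
#'
#' Moller-restricted stopping power counting only energy transfers below the
#' cut `delta` (keV).  Because the maximum transfer between identical
#' particles is E/2, `delta >= E/2` returns the unrestricted value exactly.
#'
#' @inheritParams collision_stopping_power
#' @param delta restriction cut in keV (> 0).
#' @return MeV cm^2/g, `<=` the unrestricted value.
#' @export
restricted_stopping_power <- function(mat, E, delta, density_effect = TRUE) {
  stopifnot(inherits(mat, "material"))
  if (any(delta <= 0)) stop("delta must be > 0")
  check_energy_window(E)
  b <- moller_bracket(mat, E)
  eta <- pmin(delta / E, 0.5)
  Gterm <- -1 - b$beta2 + log(4 * (1 - eta) * eta) + 1 / (1 - eta) +
    (1 - b$beta2) * (b$tau^2 * eta^2 / 2 + (2 * b$tau + 1) * log(1 - eta))
  dcor <- if (density_effect) density_effect_delta(mat, E) else 0
  .k_col * mean_z_over_a(mat) / b$beta2 * (b$lead + Gterm - dcor)
}

#' Mass stopping power to linear LET
#'
#' @param mass_stopping MeV cm^2/g (> 0).
#' @param density g/cm^3 (> 0).
#' @return keV/um (`= mass_stopping * density * 0.1`).
#' @export
linear_let <- function(mass_stopping, density) {
  if (any(!is.finite(mass_stopping)) || any(mass_stopping <= 0)) {
    stop("mass stopping power must be positive")
  }
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  mass_stopping * density * 0.1
}

#' Build a stopping-power table
#'
#' Evaluates unrestricted S(E) and restricted L_delta(E) on an energy grid;
#' lookups between grid points use log-log linear interpolation (stopping
#' power is near power-law).
#'
#' @param mat a `material`.
#' @param grid strictly increasing energies in keV inside the validity window.
#' @param delta restriction cut in keV.
#' @param density_effect apply the Sternheimer correction.
#' @return object of class `stopping_table`.
#' @export
build_stopping_table <- function(mat, grid, delta = 1.0,
                                 density_effect = TRUE) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  check_energy_window(grid)
  S <- collision_stopping_power(mat, grid, density_effect)
  L <- restricted_stopping_power(mat, grid, delta, density_effect)
  structure(
    list(material = mat$name, density = mat$density, energies = grid,
         S = S, L_delta = L, delta = delta,
         density_effect = density_effect),
    class = "stopping_table")
}

#' Look up a stopping-power table
#'
#' @param table a `stopping_table`.
#' @param E energies in keV (must lie within the table grid).
#' @param quantity `"L"` for the restricted, `"S"` for the unrestricted value.
#' @return MeV cm^2/g.
#' @export
lookup_stopping <- function(table, E, quantity = c("L", "S")) {
  stopifnot(inherits(table, "stopping_table"))
  quantity <- match.arg(quantity)
  y <- if (quantity == "L") table$L_delta else table$S
  if (is.null(y)) stop("table has no restricted-stopping-power column")
  rng <- range(table$energies)
  if (any(E < rng[1] * (1 - 1e-12)) || any(E > rng[2] * (1 + 1e-12))) {
    stop(sprintf("lookup energy outside table range [%g, %g] keV",
                 rng[1], rng[2]))
  }
  E <- pmin(pmax(E, rng[1]), rng[2])
  exp(stats::approx(log(table$energies), log(y), xout = log(E))$y)
}

#' Read a tabulated stopping-power backend
#'
#' Fixture dialect: `#`-prefixed header lines (`# material:`, `# delta_keV:`),
#' then whitespace-delimited rows `energy_keV  S_MeVcm2g  [Ldelta_MeVcm2g]`.
#' When the restricted column is absent the table only answers `"S"` lookups.
#'
#' @param path file path.
#' @param density density in g/cm^3 to attach (for linear conversions).
#' @return a `stopping_table`.
#' @export
read_stopping_table <- function(path, density = NA_real_) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  get_key <- function(key) {
    m <- grep(paste0("^\\s*#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(m) == 0L) return(NA_character_)
    trimws(sub(paste0("^\\s*#\\s*", key, "\\s*:"), "", m[1]))
  }
  dat <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  dat <- dat[!grepl("^[a-zA-Z]", trimws(dat))]  # skip a column-name row
  fields <- strsplit(trimws(dat), "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || !(ncol %in% 2:3)) {
    stop("stopping-power fixture must have 2 or 3 numeric columns")
  }
  num <- matrix(as.numeric(unlist(fields)), ncol = ncol, byrow = TRUE)
  if (anyNA(num)) stop("non-numeric entry in stopping-power fixture")
  if (any(diff(num[, 1]) <= 0)) stop("fixture energies must be increasing")
  delta <- suppressWarnings(as.numeric(get_key("delta_keV")))
  structure(
    list(material = get_key("material"), density = density,
         energies = num[, 1], S = num[, 2],
         L_delta = if (ncol == 3) num[, 3] else NULL,
         delta = delta, density_effect = NA),
    class = "stopping_table")
}
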