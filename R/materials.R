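#' @title Materials by elemental composition
#' @description Film and reference media are represented by their atomic
#'   composition; composite quantities (mass fractions, electron fractions,
#'   effective atomic number, mean excitation energy, electron density) are
#'   derived from a bundled elemental data fixture (Z, atomic weight, I).
#' @name materials
NULL

extdata_path <- function(file) {
  system.file("extdata", file, package = "letfilm", mustWork = TRUE)
}

#' Elemental data table
#'
#' Bundled fixture with atomic number, standard atomic weight and ICRU-37
#' mean excitation energies.
#'
#' @return data.frame with columns `symbol`, `Z`, `A`, `I_eV`, `gas`.
#' @export
element_table <- function() {
  if (is.null(.letfilm_cache$elements)) {
    .letfilm_cache$elements <- utils::read.delim(
      extdata_path("elements.tsv"), comment.char = "#",
      stringsAsFactors = FALSE)
  }
  .letfilm_cache$elements
}

element_info <- function(symbols) {
  tab <- element_table()
  idx <- match(symbols, tab$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(symbols[is.na(idx)], collapse = ", "))
  }
  tab[idx, , drop = FALSE]
}

normalize_composition <- function(composition) {
  if (length(composition) == 0L) stop("composition is empty")
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named numeric vector of atomic fractions")
  }
  if (any(!is.finite(composition)) || any(composition < 0)) {
    stop("atomic fractions must be finite and >= 0")
  }
  # merge duplicate element entries, drop exact zeros
  merged <- tapply(composition, names(composition), sum)
  merged <- merged[merged > 0]
  if (length(merged) == 0L) stop("composition has no positive fractions")
  element_info(names(merged))  # validates symbols
  out <- as.numeric(merged) / sum(merged)
  names(out) <- names(merged)
  out
}

#' Construct a material
#'
#' @param name identifier.
#' @param composition named numeric vector of atomic fractions (any positive
#'   scale; normalised to sum 1).
#' @param density bulk density in g/cm^3.
#' @param I_override mean excitation energy in eV, bypassing Bragg additivity
#'   (NA to derive it from the composition).
#' @return object of class `material`.
#' @export
material <- function(name, composition, density, I_override = NA_real_) {
  comp <- normalize_composition(composition)
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("density must be a single positive finite number (g/cm^3)")
  }
  if (!is.na(I_override) && I_override <= 0) stop("I_override must be > 0 eV")
  structure(
    list(name = as.character(name), composition = comp,
         density = as.numeric(density), I_override = as.numeric(I_override)),
    class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  (rho = %.4g g/cm^3)\n", x$name, x$density))
  w <- atomic_to_mass_fractions(x$composition)
  cat(sprintf("  Z_eff = %.3f   I = %.1f eV   <Z/A> = %.4f\n",
              effective_atomic_number(x$composition),
              mean_excitation_energy(x), mean_z_over_a(x)))
  comp <- data.frame(element = names(x$composition),
                     atomic_fraction = round(unname(x$composition), 5),
                     mass_fraction = round(unname(w[names(x$composition)]), 5))
  print(comp, row.names = FALSE)
  invisible(x)
}

#' Convert atomic fractions to mass fractions
#'
#' `w_i = f_i A_i / sum_j f_j A_j` with standard atomic weights.
#'
#' @param composition named numeric vector of atomic fractions.
#' @return named numeric vector of mass fractions (sums to 1).
#' @export
atomic_to_mass_fractions <- function(composition) {
  comp <- normalize_composition(composition)
  info <- element_info(names(comp))
  w <- comp * info$A
  w / sum(w)
}

electron_fractions <- function(composition) {
  comp <- normalize_composition(composition)
  info <- element_info(names(comp))
  a <- comp * info$Z
  a / sum(a)
}

#' Power-law effective atomic number
#'
#' Mayneord power-law effective atomic number with electron-fraction
#' weighting, `Z_eff = (sum_i alpha_i Z_i^m)^(1/m)` with
#' `alpha_i = f_i Z_i / sum_j f_j Z_j`.  The default exponent `m = 2.94` is
#' the conventional photoelectric-regime choice.
#'
#' @param composition named atomic-fraction vector or a `material`.
#' @param exponent power-law exponent m.
#' @return dimensionless Z_eff, bounded by the constituent Z range.
#' @export
effective_atomic_number <- function(composition, exponent = 2.94) {
  if (inherits(composition, "material")) composition <- composition$composition
  comp <- normalize_composition(composition)
  info <- element_info(names(comp))
  alpha <- comp * info$Z / sum(comp * info$Z)
  sum(alpha * info$Z^exponent)^(1 / exponent)
}

#' Mean excitation energy by Bragg additivity
#'
#' `ln I = sum_i w_i (Z_i/A_i) ln I_i / sum_i w_i (Z_i/A_i)`.  Elements that
#' are gaseous in their pure state receive the conventional 1.13x
#' condensed-phase adjustment of their I value when `condensed = TRUE`
#' (the material is assumed to be a solid or liquid compound).  An
#' `I_override` on the material short-circuits the computation.
#'
#' @param mat a `material`.
#' @param condensed apply the condensed-phase adjustment to gaseous elements.
#' @return I in eV.
#' @export
mean_excitation_energy <- function(mat, condensed = TRUE) {
  stopifnot(inherits(mat, "material"))
  if (!is.na(mat$I_override)) return(mat$I_override)
  w <- atomic_to_mass_fractions(mat$composition)
  info <- element_info(names(w))
  I_i <- info$I_eV
  if (condensed) I_i <- ifelse(info$gas == 1, 1.13 * I_i, I_i)
  zw <- w * info$Z / info$A
  exp(sum(zw * log(I_i)) / sum(zw))
}

mean_z_over_a <- function(mat) {
  w <- atomic_to_mass_fractions(mat$composition)
  info <- element_info(names(w))
  sum(w * info$Z / info$A)
}

#' Electron density of a material
#'
#' @param mat a `material`.
#' @return electrons per gram.
#' @export
electron_density <- function(mat) {
  .n_avogadro * mean_z_over_a(mat)
}

material_registry <- function() {
  if (is.null(.letfilm_cache$materials)) {
    .letfilm_cache$materials <- utils::read.delim(
      extdata_path("materials.tsv"), comment.char = "#",
      stringsAsFactors = FALSE)
  }
  .letfilm_cache$materials
}

#' List bundled materials
#' @return character vector of registry names.
#' @export
list_materials <- function() material_registry()$name

#' Load a bundled material
#'
#' The registry carries the manufacturer atomic compositions of the EBT3 and
#' MD-V3 active layers and whole films, plus water, aluminium and PMMA.
#'
#' @param name registry name (see [list_materials()]).
#' @param density optional density override in g/cm^3.
#' @return a `material`.
#' @export
load_material <- function(name, density = NULL) {
  reg <- material_registry()
  row <- reg[reg$name == name, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown material '", name, "'; available: ",
         paste(reg$name, collapse = ", "))
  }
  pairs <- strsplit(row$composition, ";", fixed = TRUE)[[1]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  comp <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(comp) <- vapply(kv, `[[`, character(1), 1)
  material(name, comp,
           density = if (is.null(density)) row$density_g_cm3 else density,
           I_override = row$I_eV)
}
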