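#' @title Track- and dose-average LET
#' @description Fluence- and dose-weighted averages of the restricted LET over
#'   a binned electron spectrum, with the track-end term `S(delta) phi(delta)
#'   delta` accounting for electrons slowing below the cut, bootstrap
#'   uncertainties, and the derived ratio statistics used to summarise a
#'   beams-by-spectra grid.
#' @name let_average
NULL

#' LET computation configuration
#'
#' @param delta restriction/track-end cut in keV (default 1).
#' @param density density in g/cm^3 for the keV/um conversion; `NULL` takes
#'   the stopping table's density.
#' @return object of class `let_config`.
#' @export
let_config <- function(delta = 1.0, density = NULL) {
  if (delta <= 0) stop("delta must be > 0")
  structure(list(delta = delta, density = density), class = "let_config")
}

let_sums <- function(spectrum, table, config) {
  delta <- config$delta
  if (delta > spectrum$bin_edges[1] + 1e-9) {
    stop("configuration error: delta lies above the first bin edge")
  }
  if (sum(spectrum$phi) == 0) {
    stop("undefined result: spectrum is entirely empty")
  }
  mids <- spectrum_mids(spectrum)
  w <- spectrum_widths(spectrum)
  L <- lookup_stopping(table, mids, "L")
  S_d <- lookup_stopping(table, delta, "S")
  phi_d <- spectrum$phi[1]  # fluence density at the cut: lowest bin
  dens <- if (!is.null(config$density)) config$density else table$density
  if (is.null(dens) || is.na(dens)) stop("no density available for conversion")
  list(mids = mids, w = w, L = L, S_d = S_d, phi_d = phi_d, dens = dens,
       delta = delta)
}

#' Track-average LET of a fluence spectrum
#'
#' Fluence-weighted mean of the restricted LET:
#' numerator `sum_i L(E_i) phi_i dE_i + S(delta) phi(delta) delta`,
#' denominator `sum_i phi_i dE_i + phi(delta) delta`, with `phi(delta)` read
#' from the lowest bin, converted to keV/um with the material density.
#'
#' @param spectrum a `fluence_spectrum` covering `[delta, E_max]`.
#' @param table a `stopping_table` for the spectrum's medium.
#' @param config a [let_config()].
#' @return track-average LET in keV/um.
#' @export
track_average_let <- function(spectrum, table, config = let_config()) {
  p <- let_sums(spectrum, table, config)
  num <- sum(p$L * spectrum$phi * p$w) + p$S_d * p$phi_d * p$delta
  den <- sum(spectrum$phi * p$w) + p$phi_d * p$delta
  linear_let(num / den, p$dens)
}

#' Dose-average LET of a fluence spectrum
#'
#' LET weighted by each spectral component's contribution to absorbed dose:
#' numerator uses `L^2` (and `S(delta)^2` in the track-end term); the
#' denominator is exactly the track-average numerator.  Always `>=` the
#' track average (Cauchy-Schwarz).
#'
#' @inheritParams track_average_let
#' @return dose-average LET in keV/um.
#' @export
dose_average_let <- function(spectrum, table, config = let_config()) {
  p <- let_sums(spectrum, table, config)
  num <- sum(p$L^2 * spectrum$phi * p$w) + p$S_d^2 * p$phi_d * p$delta
  den <- sum(p$L * spectrum$phi * p$w) + p$S_d * p$phi_d * p$delta
  linear_let(num / den, p$dens)
}

#' Both LET averages with bootstrap uncertainties
#'
#' @inheritParams track_average_let
#' @param n_boot bootstrap resamples (0 skips the uncertainty estimate).
#' @param seed RNG seed for the bootstrap (required when `n_boot > 0`).
#' @return object of class `let_result` with fields `L_track`, `L_dose`,
#'   `u_track`, `u_dose`, `delta`, `kind`, `medium`, `beam`.
#' @export
let_averages <- function(spectrum, table, config = let_config(),
                         n_boot = 0, seed = NULL) {
  lt <- track_average_let(spectrum, table, config)
  ld <- dose_average_let(spectrum, table, config)
  u <- c(u_track = 0, u_dose = 0)
  if (n_boot > 0) {
    u <- let_uncertainties(spectrum, table, config, n_boot = n_boot,
                           seed = seed)
  }
  structure(
    list(L_track = lt, L_dose = ld,
         u_track = unname(u["u_track"]), u_dose = unname(u["u_dose"]),
         delta = config$delta, kind = spectrum$kind,
         medium = spectrum$medium, beam = spectrum$beam),
    class = "let_result")
}

#' @export
print.let_result <- function(x, ...) {
  cat(sprintf(
    "<let_result> %s / %s / %s (delta = %g keV)\n  L_track = %.4g +/- %.2g keV/um\n  L_dose  = %.4g +/- %.2g keV/um  (ratio %.3g)\n",
    x$medium, x$beam, x$kind, x$delta, x$L_track, x$u_track,
    x$L_dose, x$u_dose, x$L_dose / x$L_track))
  invisible(x)
}

#' Bootstrap uncertainties of the LET averages
#'
#' Resamples each bin `phi_i ~ Normal(phi_i, sigma_phi_i)` truncated at zero,
#' recomputes both averages, and reports the sample standard deviations.
#' Deterministic under a fixed seed.
#'
#' @inheritParams track_average_let
#' @param n_boot number of resamples (>= 100).
#' @param seed RNG seed (mandatory).
#' @return named numeric `c(u_track =, u_dose =)` in keV/um.
#' @export
let_uncertainties <- function(spectrum, table, config = let_config(),
                              n_boot = 1000, seed) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (all(spectrum$sigma_phi == 0)) return(c(u_track = 0, u_dose = 0))
  p <- let_sums(spectrum, table, config)
  n <- length(spectrum$phi)
  phi_b <- with_seed(seed, {
    matrix(pmax(0, rep(spectrum$phi, each = n_boot) +
                   stats::rnorm(n_boot * n) *
                   rep(spectrum$sigma_phi, each = n_boot)),
           nrow = n_boot)
  })
  a1 <- as.vector(phi_b %*% (p$L * p$w)) + phi_b[, 1] * p$S_d * p$delta
  a0 <- as.vector(phi_b %*% p$w) + phi_b[, 1] * p$delta
  a2 <- as.vector(phi_b %*% (p$L^2 * p$w)) + phi_b[, 1] * p$S_d^2 * p$delta
  lt <- a1 / a0 * p$dens * 0.1
  ld <- a2 / a1 * p$dens * 0.1
  c(u_track = stats::sd(lt), u_dose = stats::sd(ld))
}

#' Dose-to-track LET ratio
#'
#' @param result a `let_result` (or any list with `L_dose`, `L_track`).
#' @return `L_dose / L_track` (>= 1).
#' @export
let_ratio <- function(result) result$L_dose / result$L_track

#' Published LET grid
#'
#' Loads the bundled grid of published track- and dose-average LET values
#' (both films, TEF and SE, six beams) for ratio statistics.
#'
#' @return data.frame with columns `film`, `kind`, `beam`,
#'   `equiv_energy_keV`, `L_track`, `L_dose`.
#' @export
load_printed_let_grid <- function() {
  utils::read.delim(extdata_path("let_grid_printed.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Derived ratio statistics over a beams-by-spectra LET grid
#'
#' Computes, per film: the SE/TEF ratio of the track-average LET per beam;
#' each beam's track-average LET relative to the Co-60 reference per spectrum
#' kind; the percent excess of the dose average over the track average; and
#' the dose/track ratio -- with min/max summaries using the conventional
#' roundings (ratios to the nearest integer, percent excess to the nearest
#' integer percent, low-energy dose/track ratios to one decimal).
#'
#' @param grid data.frame as from [load_printed_let_grid()]; any subset of the
#'   films-by-kinds-by-beams grid.  Missing cells are skipped with a warning.
#' @param reference_beam beam used as denominator for the relative ratios
#'   (default `"Co60"`; falls back to the highest-equivalent-energy beam with
#'   a warning).  The reference beam is excluded from the relative min/max.
#' @param low_e_cut equivalent energy (keV) below which the "low energy"
#'   summaries are taken (default 100).
#' @return list with `per_spectrum`, `se_tef_track`, `rel_track`, `summary`
#'   data.frames.
#' @export
cross_statistics <- function(grid, reference_beam = "Co60", low_e_cut = 100) {
  need <- c("film", "kind", "beam", "equiv_energy_keV", "L_track", "L_dose")
  if (!all(need %in% names(grid))) {
    stop("grid must have columns: ", paste(need, collapse = ", "))
  }
  per <- grid
  per$ld_lt <- per$L_dose / per$L_track
  per$pct_excess <- 100 * (per$ld_lt - 1)

  se_tef <- NULL
  rel <- NULL
  summary_rows <- list()
  add <- function(film, kind, statistic, value) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(film = film, kind = kind, statistic = statistic,
                 value = value, stringsAsFactors = FALSE)
  }

  for (f in unique(per$film)) {
    g <- per[per$film == f, , drop = FALSE]
    # SE/TEF track-average ratio per beam
    tef <- g[g$kind == "TEF", ]; se <- g[g$kind == "SE", ]
    common <- intersect(tef$beam, se$beam)
    skipped <- setdiff(union(tef$beam, se$beam), common)
    if (length(skipped)) {
      warning(sprintf("film %s: beams without both kinds skipped: %s",
                      f, paste(skipped, collapse = ", ")))
    }
    if (length(common)) {
      r <- se$L_track[match(common, se$beam)] /
           tef$L_track[match(common, tef$beam)]
      se_tef <- rbind(se_tef, data.frame(
        film = f, beam = common,
        equiv_energy_keV = tef$equiv_energy_keV[match(common, tef$beam)],
        ratio = r, stringsAsFactors = FALSE))
      add(f, NA_character_, "se_tef_track_min", round(min(r)))
      add(f, NA_character_, "se_tef_track_max", round(max(r)))
    }
    for (k in unique(g$kind)) {
      gk <- g[g$kind == k, , drop = FALSE]
      ref <- reference_beam
      if (!ref %in% gk$beam) {
        ref <- gk$beam[which.max(gk$equiv_energy_keV)]
        warning(sprintf(
          "film %s kind %s: reference beam '%s' missing, using '%s'",
          f, k, reference_beam, ref))
      }
      r <- gk$L_track / gk$L_track[gk$beam == ref]
      rel <- rbind(rel, data.frame(film = f, kind = k, beam = gk$beam,
                                   ratio = r, stringsAsFactors = FALSE))
      others <- r[gk$beam != ref]
      if (length(others)) {
        add(f, k, "rel_track_min", round(min(others)))
        add(f, k, "rel_track_max", round(max(others)))
      } else {
        add(f, k, "rel_track_min", 1.0)
        add(f, k, "rel_track_max", 1.0)
      }
      low <- gk$equiv_energy_keV < low_e_cut
      if (any(low)) {
        pe <- 100 * (gk$L_dose[low] / gk$L_track[low] - 1)
        add(f, k, "pct_excess_low_e_min", round(min(pe)))
        add(f, k, "pct_excess_low_e_max", round(max(pe)))
        rr <- gk$L_dose[low] / gk$L_track[low]
        add(f, k, "ld_lt_low_e_min", round(min(rr), 1))
        add(f, k, "ld_lt_low_e_max", round(max(rr), 1))
      }
      if (ref %in% gk$beam) {
        add(f, k, "ld_lt_reference",
            round(gk$L_dose[gk$beam == ref] / gk$L_track[gk$beam == ref]))
      }
    }
  }
  list(per_spectrum = per, se_tef_track = se_tef, rel_track = rel,
       summary = do.call(rbind, summary_rows))
}
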