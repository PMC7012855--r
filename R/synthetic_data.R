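#' @title Synthetic fluence spectra and dose-response curves
#' @description Seeded generators that emulate the statistical structure of
#'   Monte Carlo electron-fluence tallies (photopeaks with slowing-down
#'   shelves, Compton continuum with a low-energy slowing-down tail, a
#'   power-law secondary-electron tail, K-shell lines of Na/Al/S/Cl) and of
#'   film netOD-dose calibration curves (saturating exponential with a
#'   per-beam sensitivity scale whose ratio to the Co-60 scale is the
#'   ground-truth relative efficiency).  Shape-level realism only: this is
#'   not a transport code.
#' @name synthetic_data
NULL

.kshell_keV <- c(Na = 1.07, Al = 1.56, S = 2.47, Cl = 2.82)

#' Spectrum generator configuration
#'
#' Explicit component parameterisation of one beam/medium spectrum pair.
#' Amplitudes are relative (the pair is renormalised so the TEF CEMA equals
#' 1 Gy per Gy); K-shell line energies default to the Na/Al/S/Cl values with
#' amplitudes tied to the medium's atomic fractions.
#'
#' @param beam beam-quality name.
#' @param medium material registry name the fluence is scored in.
#' @param e_max spectrum upper edge in keV.
#' @param n_bins number of logarithmic bins on `[1, e_max]` keV.
#' @param photopeaks list of `c(center, width, amp)` Gaussian photopeaks
#'   (keV, keV, relative area); each carries a flat slowing-down shelf below
#'   the peak with area `shelf_frac * amp`.
#' @param shelf_frac slowing-down shelf fraction per photopeak.
#' @param compton `c(edge, shape, amp, tail_frac)`: smoothed flat-topped
#'   continuum ending at the Compton edge (keV) plus a low-energy
#'   slowing-down tail `~ T^-shape` with relative amplitude `tail_frac`.
#' @param se_tail `c(amp, index)`: power-law secondary-electron tail
#'   `amp * T^-index` on `[1, e_max/2]`.
#' @param kshell named numeric of K-line areas keyed by element symbol
#'   (NULL derives them from the medium's composition).
#' @param noise_rel relative Monte-Carlo-like noise per bin (truncated
#'   normal).
#' @param seed RNG seed.
#' @return object of class `spectrum_gen_config`.
#' @export
spectrum_gen_config <- function(beam, medium, e_max, n_bins = 140,
                                photopeaks = list(),
                                shelf_frac = 0.35,
                                compton = c(edge = 0, shape = 1.2, amp = 0,
                                            tail_frac = 0.15),
                                se_tail = c(amp = 1, index = 2),
                                kshell = NULL, noise_rel = 0.02, seed = 1) {
  if (e_max <= .kev_floor * 2) stop("e_max too small")
  amps <- c(vapply(photopeaks, function(p) p[["amp"]], numeric(1)),
            compton[["amp"]], se_tail[["amp"]])
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  if (all(amps == 0)) stop("all-zero components: normalization unsatisfiable")
  if (is.null(kshell)) {
    comp <- load_material(medium)$composition
    present <- intersect(names(.kshell_keV), names(comp))
    kshell <- 2 * comp[present]
  }
  structure(list(beam = beam, medium = medium, e_max = e_max, n_bins = n_bins,
                 photopeaks = photopeaks, shelf_frac = shelf_frac,
                 compton = compton, se_tail = se_tail, kshell = kshell,
                 noise_rel = noise_rel, seed = seed),
            class = "spectrum_gen_config")
}

compton_edge_keV <- function(e_photon_keV) {
  2 * e_photon_keV^2 / (.mec2 + 2 * e_photon_keV)
}

#' Default per-beam spectrum generator configuration
#'
#' Presets emulating the published spectra: a photoelectric peak at the
#' beam's effective energy for the x-ray qualities (two main structures at
#' 80 kV and above, where the Compton continuum is also populated), a
#' Compton-dominated Co-60 spectrum, and a secondary-electron tail whose
#' low-energy contribution grows with photon energy.
#'
#' @param beam one of the bundled beam names (see [load_beams()]).
#' @param medium material registry name.
#' @param seed RNG seed.
#' @param noise_rel relative per-bin noise.
#' @return a `spectrum_gen_config`.
#' @export
default_spectrum_config <- function(beam, medium = "EBT3_active", seed = 1,
                                    noise_rel = 0.02) {
  beams <- load_beams()
  row <- beams[beams$name == beam, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown beam '", beam, "'; available: ",
         paste(beams$name, collapse = ", "))
  }
  eeff <- row$effective_energy_keV
  is_co <- beam == "Co60"
  e_max <- if (is_co) 1250 else as.numeric(row$tube_potential_kV)
  edge <- compton_edge_keV(eeff)
  # relative SE amplitude grows with photon energy (more cascades per primary)
  se_amp <- c(`20kV` = 0.007, `50kV` = 0.012, `80kV` = 0.02,
              `120kV` = 0.03, `160kV` = 0.04, Co60 = 1)[[beam]]
  compton_amp <- c(`20kV` = 0, `50kV` = 0, `80kV` = 0.6,
                   `120kV` = 0.4, `160kV` = 0.4, Co60 = 1)[[beam]]
  peaks <- if (is_co) list() else {
    list(c(center = eeff, width = max(0.08 * eeff, 1.0), amp = 1))
  }
  spectrum_gen_config(
    beam = beam, medium = medium, e_max = e_max,
    photopeaks = peaks, shelf_frac = 0.35,
    compton = c(edge = edge, shape = 1.2, amp = compton_amp,
                tail_frac = 0.15),
    se_tail = c(amp = se_amp, index = 2),
    noise_rel = noise_rel, seed = seed)
}

# Component densities (arbitrary units, per keV) evaluated at energies T.
spectrum_components <- function(config, T) {
  se <- config$se_tail[["amp"]] * T^(-config$se_tail[["index"]]) *
    (T >= .kev_floor & T <= config$e_max / 2)
  pe <- rep(0, length(T))
  for (p in config$photopeaks) {
    pe <- pe + p[["amp"]] * stats::dnorm(T, p[["center"]], p[["width"]])
    if (p[["center"]] > .kev_floor) {
      pe <- pe + p[["amp"]] * config$shelf_frac /
        (p[["center"]] - .kev_floor) * (T < p[["center"]])
    }
  }
  cm <- rep(0, length(T))
  edge <- config$compton[["edge"]]
  if (config$compton[["amp"]] > 0 && edge > .kev_floor) {
    plateau <- stats::plogis((T - edge / 3) / (0.03 * edge)) *
      stats::plogis((edge - T) / (0.04 * edge))
    tail <- config$compton[["tail_frac"]] *
      T^(-config$compton[["shape"]]) * (T < edge)
    cm <- config$compton[["amp"]] * (plateau + tail)
  }
  kl <- rep(0, length(T))
  for (el in names(config$kshell)) {
    ek <- .kshell_keV[[el]]
    if (ek > .kev_floor && ek < config$e_max) {
      kl <- kl + config$kshell[[el]] * stats::dnorm(T, ek, 0.06)
    }
  }
  list(se = se, tef = se + pe + cm + kl)
}

#' Simulate a TEF/SE fluence-spectrum pair
#'
#' Builds both spectra on a logarithmic grid with bin-averaged component
#' densities (7-point sub-sampling), renormalises the pair so the TEF CEMA
#' in the configured medium equals 1 Gy per Gy, then applies independent
#' truncated-normal noise with `sd = noise_rel * phi` and per-bin
#' `sigma_phi = noise_rel * phi`.  Pure function of (config, seed).
#'
#' @param config a `spectrum_gen_config`.
#' @return list with elements `tef` and `se` (`fluence_spectrum`s).
#' @export
simulate_fluence_spectrum <- function(config) {
  stopifnot(inherits(config, "spectrum_gen_config"))
  edges <- exp(seq(log(.kev_floor), log(config$e_max),
                   length.out = config$n_bins + 1L))
  nb <- config$n_bins
  # bin-averaged densities on a geometric sub-grid
  nsub <- 7L
  fr <- (seq_len(nsub) - 0.5) / nsub
  lo <- edges[-(nb + 1)]; hi <- edges[-1]
  Tsub <- exp(outer(log(lo), rep(1, nsub)) +
              outer(log(hi / lo), fr))
  comp <- spectrum_components(config, as.vector(Tsub))
  se_d <- rowMeans(matrix(comp$se, nrow = nb))
  tef_d <- rowMeans(matrix(comp$tef, nrow = nb))

  mat <- load_material(config$medium)
  tab <- build_stopping_table(
    mat, exp(seq(log(.kev_floor), log(config$e_max), length.out = 240)))
  tef0 <- fluence_spectrum(edges, tef_d, 0, kind = "TEF",
                           medium = config$medium, beam = config$beam)
  norm <- cema(tef0, tab)
  if (norm <= 0) stop("unsatisfiable normalization (all-zero components)")
  tef_d <- tef_d / norm
  se_d <- se_d / norm

  noisy <- with_seed(config$seed, {
    list(tef = pmax(0, tef_d * (1 + config$noise_rel * stats::rnorm(nb))),
         se = pmax(0, se_d * (1 + config$noise_rel * stats::rnorm(nb))))
  })
  list(
    tef = fluence_spectrum(edges, noisy$tef, config$noise_rel * tef_d,
                           kind = "TEF", medium = config$medium,
                           beam = config$beam),
    se = fluence_spectrum(edges, noisy$se, config$noise_rel * se_d,
                          kind = "SE", medium = config$medium,
                          beam = config$beam))
}

#' Dose-response generator configuration
#'
#' Saturating response `netOD(D) = a (1 - exp(-b s_Q D))`: the per-beam
#' sensitivity scale `s_Q` acts as a pure dose scaling, so the ground-truth
#' relative efficiency of beam Q equals `s_Q / s_Co60` at every netOD level
#' (RE independent of the dose imparted, by construction).
#'
#' @param film film name (sets defaults for `a`, `b`).
#' @param a saturation netOD.
#' @param b dose constant in 1/Gy.
#' @param scales named per-beam sensitivity scales; must include the
#'   reference beam `Co60` (conventionally 1).
#' @param dose_grid measurement doses in Gy.
#' @param noise_rel relative netOD noise per point.
#' @param seed RNG seed.
#' @return object of class `response_gen_config`.
#' @export
response_gen_config <- function(film = "EBT3",
                                a = if (grepl("^EBT3", film)) 0.7 else 0.3,
                                b = if (grepl("^EBT3", film)) 0.10 else 0.02,
                                scales = c(Co60 = 1),
                                dose_grid = exp(seq(log(0.05), log(25),
                                                    length.out = 24)),
                                noise_rel = 0.005, seed = 1) {
  if (a <= 0 || b <= 0) stop("a and b must be > 0")
  if (is.null(names(scales)) || any(scales < 0)) {
    stop("scales must be a named non-negative vector")
  }
  structure(list(film = film, a = a, b = b, scales = scales,
                 dose_grid = sort(dose_grid), noise_rel = noise_rel,
                 seed = seed),
            class = "response_gen_config")
}

#' Simulate per-beam dose-response curves
#'
#' @param config a `response_gen_config`.
#' @param beams beams to generate (default all named in `config$scales`).
#' @return named list of `dose_response_curve`s.
#' @export
simulate_dose_response <- function(config, beams = names(config$scales)) {
  stopifnot(inherits(config, "response_gen_config"))
  missing_beams <- setdiff(beams, names(config$scales))
  if (length(missing_beams)) {
    stop("no sensitivity scale for beam(s): ",
         paste(missing_beams, collapse = ", "))
  }
  d <- config$dose_grid
  out <- vector("list", length(beams)); names(out) <- beams
  for (i in seq_along(beams)) {
    q <- beams[i]
    clean <- config$a * (1 - exp(-config$b * config$scales[[q]] * d))
    noisy <- with_seed(child_seed(config$seed, i), {
      pmax(0, clean * (1 + config$noise_rel * stats::rnorm(length(d))))
    })
    out[[q]] <- dose_response_curve(config$film, q, "red", dose = d,
                                    netod = noisy,
                                    sigma_netod = config$noise_rel * clean)
  }
  out
}

#' Ground-truth RE as a monotone function of dose-average LET
#'
#' The sensitivity map used by [make_study_fixture()]: almost constant at low
#' LET, a rapid logistic rise around `l50`, then a slow continued rise --
#' the qualitative shape of the film relative-efficiency curve.
#'
#' @param let_keV_um dose-average LET in keV/um.
#' @param base low-LET plateau value.
#' @param rise logistic rise amplitude.
#' @param l50 LET of the half-rise, keV/um.
#' @param width logistic width, keV/um.
#' @param slope slow terminal slope per keV/um.
#' @return sensitivity values (monotone non-decreasing in LET).
#' @export
re_level_curve <- function(let_keV_um, base = 1, rise = 2.6, l50 = 5,
                           width = 0.8, slope = 0.03) {
  base + rise * stats::plogis((let_keV_um - l50) / width) +
    slope * let_keV_um
}

#' Generate a full synthetic study fixture
#'
#' Writes, for each film and each of the six beams, a TEF/SE spectrum pair
#' and a netOD-dose calibration curve in the package text dialects, plus a
#' `manifest.tsv` with the ground-truth sensitivity scales.  The per-beam
#' scale is a monotone function ([re_level_curve()]) of the dose-average LET
#' computed from the generated TEF spectrum, normalised to the Co-60 beam,
#' so the recovered RE-vs-LET curve is monotone with the expected shape.
#' Byte-identical under a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param seed root RNG seed; per-stage seeds derive from it.
#' @param films films to generate.
#' @param noise_rel_spectrum per-bin spectrum noise.
#' @param noise_rel_response per-point netOD noise.
#' @return (invisibly) the manifest data.frame.
#' @export
make_study_fixture <- function(dir, seed = 1, films = c("EBT3", "MDV3"),
                               noise_rel_spectrum = 0.02,
                               noise_rel_response = 0.005) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("unwritable target directory: ", dir)
  }
  beams <- load_beams()$name
  manifest <- NULL
  idx <- 0L
  for (film in films) {
    medium <- paste0(film, "_active")
    mat <- load_material(medium)
    ld <- numeric(length(beams)); names(ld) <- beams
    for (bm in beams) {
      idx <- idx + 1L
      cfg <- default_spectrum_config(bm, medium,
                                     seed = child_seed(seed, idx),
                                     noise_rel = noise_rel_spectrum)
      pair <- simulate_fluence_spectrum(cfg)
      tab <- build_stopping_table(
        mat, exp(seq(log(1), log(cfg$e_max), length.out = 240)))
      ld[bm] <- dose_average_let(pair$tef, tab)
      write_spectrum(pair$tef,
                     file.path(dir, sprintf("spectrum_%s_%s_TEF.txt", film, bm)))
      write_spectrum(pair$se,
                     file.path(dir, sprintf("spectrum_%s_%s_SE.txt", film, bm)))
    }
    s_raw <- re_level_curve(ld)
    s_q <- s_raw / s_raw[["Co60"]]
    rcfg <- response_gen_config(film = film, scales = s_q,
                                noise_rel = noise_rel_response,
                                seed = child_seed(seed, 1000L + idx))
    curves <- simulate_dose_response(rcfg)
    for (bm in beams) {
      write_dose_response(curves[[bm]],
                          file.path(dir, sprintf("curve_%s_%s.txt", film, bm)))
    }
    manifest <- rbind(manifest, data.frame(
      film = film, beam = beams,
      s_true = as.numeric(s_q[beams]),
      L_dose_tef = as.numeric(ld[beams]),
      stringsAsFactors = FALSE))
  }
  man_lines <- c(
    "# Synthetic study manifest: ground-truth sensitivity scales (s_true is",
    "# the generated relative efficiency vs Co60) and the dose-average LET of",
    "# the generated TEF spectrum used to set them.",
    sprintf("# seed: %d", as.integer(seed)),
    "film\tbeam\ts_true\tL_dose_tef",
    sprintf("%s\t%s\t%.10g\t%.10g", manifest$film, manifest$beam,
            manifest$s_true, manifest$L_dose_tef))
  writeLines(man_lines, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read a study-fixture manifest
#'
#' @param dir study directory written by [make_study_fixture()].
#' @return data.frame with the ground-truth scales.
#' @export
read_study_manifest <- function(dir) {
  utils::read.delim(file.path(dir, "manifest.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
}
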