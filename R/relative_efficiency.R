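#' @title Film relative efficiency
#' @description Relative efficiency of a radiochromic film under beam quality
#'   Q is the ratio of the Co-60 dose to the test-beam dose producing the same
#'   net optical density: `RE = D_Co60(netOD) / D_Q(netOD)`.  Dose-response
#'   curves are modelled as monotone shape-preserving cubics and inverted by
#'   root finding; per-beam weight-averaged RE uses inverse-variance weights
#'   across the netOD evaluation levels.
#' @name relative_efficiency
NULL

#' Construct a dose-response curve
#'
#' @param film film name.
#' @param beam beam-quality name.
#' @param channel colour channel label (default `"red"`).
#' @param dose strictly increasing doses in Gy.
#' @param netod net optical densities (>= 0), non-decreasing with dose beyond
#'   noise tolerance (3 sigma of the neighbouring points).
#' @param sigma_netod per-point standard uncertainty (>= 0).
#' @return object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(film, beam, channel = "red",
                                dose, netod, sigma_netod = 0) {
  if (any(diff(dose) <= 0)) stop("doses must be strictly increasing")
  if (length(netod) != length(dose)) stop("dose/netod length mismatch")
  if (length(sigma_netod) == 1L) sigma_netod <- rep(sigma_netod, length(dose))
  if (any(netod < 0) || any(sigma_netod < 0)) {
    stop("netod and sigma_netod must be non-negative")
  }
  drops <- -diff(netod)
  tol <- 3 * sqrt(sigma_netod[-1]^2 + sigma_netod[-length(netod)]^2) + 1e-12
  if (any(drops > tol)) {
    stop(sprintf(
      "validation error: netOD decreases beyond noise tolerance at point %d",
      which(drops > tol)[1] + 1L))
  }
  structure(list(film = film, beam = beam, channel = channel,
                 dose = as.numeric(dose), netod = as.numeric(netod),
                 sigma_netod = as.numeric(sigma_netod)),
            class = "dose_response_curve")
}

# Monotone forward interpolant netOD(D).  Small noise-induced dips are
# flattened by isotonic regression before fitting the monoH.FC spline.
curve_forward <- function(curve) {
  y <- curve$netod
  if (any(diff(y) <= 0)) y <- stats::isoreg(curve$dose, y)$yf
  keep <- c(TRUE, diff(y) > 0)
  stats::splinefun(curve$dose[keep], y[keep], method = "monoH.FC")
}

#' Evaluate a dose-response curve
#'
#' @param curve a `dose_response_curve`.
#' @param dose doses in Gy within the measured range.
#' @return interpolated netOD.
#' @export
curve_netod <- function(curve, dose) {
  rng <- range(curve$dose)
  if (any(dose < rng[1]) || any(dose > rng[2])) {
    stop("dose outside the measured range (no extrapolation)")
  }
  curve_forward(curve)(dose)
}

#' Invert a dose-response curve
#'
#' Dose required to produce a given netOD, by root finding on the monotone
#' forward interpolant (round-trip exact to the root tolerance).  Never
#' extrapolates.
#'
#' @param curve a `dose_response_curve`.
#' @param netod target netOD values within the measured netOD range.
#' @param with_sigma also propagate the local netOD uncertainty through the
#'   slope, returning a data.frame.
#' @return doses in Gy, or a data.frame `dose`, `sigma_dose`.
#' @export
dose_for_netod <- function(curve, netod, with_sigma = FALSE) {
  f <- curve_forward(curve)
  ylo <- min(curve$netod); yhi <- max(curve$netod)
  if (any(netod < ylo - 1e-12) || any(netod > yhi + 1e-12)) {
    stop(sprintf(
      "range error: netOD %.4g outside the measured range [%.4g, %.4g]",
      netod[netod < ylo - 1e-12 | netod > yhi + 1e-12][1], ylo, yhi))
  }
  d1 <- min(curve$dose); d2 <- max(curve$dose)
  dose <- vapply(netod, function(y) {
    i <- match(TRUE, abs(curve$netod - y) < 1e-15)
    if (!is.na(i)) return(curve$dose[i])  # tabulated point: exact
    if (y <= f(d1)) return(d1)
    if (y >= f(d2)) return(d2)
    stats::uniroot(function(d) f(d) - y, lower = d1, upper = d2,
                   tol = 1e-10, extendInt = "no")$root
  }, numeric(1))
  if (!with_sigma) return(dose)
  slope <- pmax(f(dose, deriv = 1), 1e-300)
  sig_local <- stats::approx(curve$dose, curve$sigma_netod, xout = dose,
                             rule = 2)$y
  data.frame(dose = dose, sigma_dose = sig_local / slope)
}

#' Relative efficiency at given netOD levels
#'
#' `RE = D_Co60(netOD) / D_Q(netOD)`: the Co-60 (reference) dose over the
#' test-beam dose producing the same netOD.  Uncertainties from the two
#' inversions combine in quadrature on the log scale.
#'
#' @param curve_co60 reference-beam curve.
#' @param curve_q test-beam curve (same film and channel).
#' @param netod netOD evaluation levels covered by both curves.
#' @return data.frame `netod`, `re`, `sigma_re`.
#' @export
relative_efficiency <- function(curve_co60, curve_q, netod) {
  if (!identical(curve_co60$film, curve_q$film) ||
      !identical(curve_co60$channel, curve_q$channel)) {
    stop("film/channel mismatch between the two curves")
  }
  a <- dose_for_netod(curve_co60, netod, with_sigma = TRUE)
  b <- dose_for_netod(curve_q, netod, with_sigma = TRUE)
  re <- a$dose / b$dose
  sigma <- re * sqrt((a$sigma_dose / a$dose)^2 + (b$sigma_dose / b$dose)^2)
  data.frame(netod = netod, re = re, sigma_re = sigma)
}

#' Inverse-variance weighted mean RE
#'
#' Falls back to equal weights when uncertainties are absent or all zero.
#'
#' @param re_values RE values across netOD levels (>= 1 value).
#' @param re_sigmas matching standard uncertainties, or `NULL`.
#' @return named numeric `c(re_weighted =, sigma =)`.
#' @export
weighted_average_re <- function(re_values, re_sigmas = NULL) {
  if (length(re_values) == 0L) stop("empty input")
  if (is.null(re_sigmas) || all(re_sigmas <= 0)) {
    n <- length(re_values)
    s <- if (n > 1) stats::sd(re_values) / sqrt(n) else 0
    return(c(re_weighted = mean(re_values), sigma = s))
  }
  if (any(re_sigmas <= 0)) stop("sigmas must all be positive (or all absent)")
  w <- 1 / re_sigmas^2
  c(re_weighted = sum(w * re_values) / sum(w), sigma = sqrt(1 / sum(w)))
}

#' Default netOD evaluation levels per film
#'
#' The red-channel levels used in the film study: 0.053, 0.176, 0.510 for
#' EBT3 and 0.009, 0.023, 0.095 for MD-V3.
#'
#' @param film `"EBT3"` or `"MDV3"` (prefix-matched).
#' @return numeric vector of netOD levels.
#' @export
default_netod_levels <- function(film) {
  if (grepl("^EBT3", film)) return(c(0.053, 0.176, 0.510))
  if (grepl("^MD-?V3", film)) return(c(0.009, 0.023, 0.095))
  stop("no default netOD levels for film '", film, "'")
}

#' Per-beam RE with weight-averaging across levels
#'
#' @inheritParams relative_efficiency
#' @param levels netOD levels (default per film via
#'   [default_netod_levels()]).
#' @return object of class `re_result`: per-level values plus the weighted
#'   average.
#' @export
relative_efficiency_levels <- function(curve_co60, curve_q,
                                       levels = default_netod_levels(curve_q$film)) {
  per <- relative_efficiency(curve_co60, curve_q, levels)
  wa <- weighted_average_re(per$re, if (all(per$sigma_re > 0)) per$sigma_re)
  structure(list(film = curve_q$film, beam = curve_q$beam,
                 netod_levels = per$netod, re_values = per$re,
                 re_sigmas = per$sigma_re,
                 re_weighted = unname(wa["re_weighted"]),
                 re_weighted_sigma = unname(wa["sigma"])),
            class = "re_result")
}

#' Join per-beam values against LET to form a response-vs-LET table
#'
#' Joins per-beam RE (or dose) values with the LET results of the chosen
#' spectrum kind on the chosen axis and sorts by LET ascending.  Switching
#' the axis only re-labels the abscissa; the response values are untouched.
#'
#' @param values data.frame with columns `beam`, `value` and optionally
#'   `sigma` (e.g. weighted RE per beam, or `D(netOD)` per beam).
#' @param let_results data.frame with columns `beam`, `kind`, `L_track`,
#'   `L_dose` (keV/um).
#' @param axis `"track"` or `"dose"`.
#' @param kind spectrum kind to take the LET from (`"TEF"` or `"SE"`).
#' @return data.frame `beam`, `let_keV_um`, `value`, `sigma`, sorted by LET.
#' @export
assemble_re_vs_let <- function(values, let_results, axis = c("track", "dose"),
                               kind = c("TEF", "SE")) {
  axis <- match.arg(axis); kind <- match.arg(kind)
  lk <- let_results[let_results$kind == kind, , drop = FALSE]
  missing_beams <- setdiff(values$beam, lk$beam)
  if (length(missing_beams)) {
    stop("join error: beams missing from LET results: ",
         paste(missing_beams, collapse = ", "))
  }
  idx <- match(values$beam, lk$beam)
  let <- if (axis == "track") lk$L_track[idx] else lk$L_dose[idx]
  out <- data.frame(beam = values$beam, let_keV_um = let,
                    value = values$value,
                    sigma = if ("sigma" %in% names(values)) values$sigma else NA_real_,
                    stringsAsFactors = FALSE)
  out[order(out$let_keV_um), , drop = FALSE]
}

#' Write a dose-response curve to the text dialect
#'
#' `#` header keys `film`, `beam`, `channel`; rows `dose_Gy netOD sigma_netOD`.
#'
#' @param curve a `dose_response_curve`.
#' @param path output file.
#' @export
write_dose_response <- function(curve, path) {
  rows <- sprintf("%.15g %.15g %.15g", curve$dose, curve$netod,
                  curve$sigma_netod)
  writeLines(c(paste0("# film: ", curve$film),
               paste0("# beam: ", curve$beam),
               paste0("# channel: ", curve$channel),
               "# columns: dose_Gy netOD sigma_netOD",
               rows), path)
  invisible(path)
}

#' Read a dose-response curve from the text dialect
#'
#' @param path input file (dialect of [write_dose_response()]).
#' @return a validated `dose_response_curve`.
#' @export
read_dose_response <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^\\s*#", lines)]
  get_key <- function(key) {
    m <- grep(paste0("^\\s*#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(m) == 0L) {
      stop(sprintf("format error in '%s': missing header key '%s'", path, key))
    }
    trimws(sub(paste0("^\\s*#\\s*", key, "\\s*:"), "", m[1]))
  }
  dat <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(dat), "\\s+")
  if (any(lengths(fields) != 3L)) {
    stop("format error in '", path, "': rows must have 3 columns")
  }
  num <- matrix(as.numeric(unlist(fields)), ncol = 3, byrow = TRUE)
  if (anyNA(num)) stop("format error in '", path, "': non-numeric entry")
  dose_response_curve(get_key("film"), get_key("beam"), get_key("channel"),
                      dose = num[, 1], netod = num[, 2],
                      sigma_netod = num[, 3])
}
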