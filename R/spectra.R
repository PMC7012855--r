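#' @title Binned electron-fluence spectra
#' @description Electron fluence differential in energy, normalised per unit
#'   absorbed dose (cm^-2 keV^-1 Gy^-1), on half-open bins `[lo, hi)` with a
#'   1 keV energy floor.  Covers reading/writing the text dialect, the SE/TEF
#'   ratio, the CEMA self-consistency integral and conservative rebinning.
#' @name spectra
NULL

#' Construct a fluence spectrum
#'
#' @param bin_edges strictly increasing bin edges in keV; first edge >= 1 keV.
#' @param phi fluence density per bin, cm^-2 keV^-1 Gy^-1 (>= 0).
#' @param sigma_phi per-bin standard uncertainty, same units (>= 0).
#' @param kind one of `"TEF"`, `"PE"`, `"SE"`.
#' @param medium material name the fluence was scored in.
#' @param beam beam-quality name.
#' @return object of class `fluence_spectrum`.
#' @export
fluence_spectrum <- function(bin_edges, phi, sigma_phi = 0,
                             kind = c("TEF", "PE", "SE"),
                             medium = "unknown", beam = "unknown") {
  kind <- match.arg(kind)
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (bin_edges[1] < .kev_floor - 1e-9) {
    stop(sprintf("first bin edge must be >= %g keV (energy floor)", .kev_floor))
  }
  n <- length(bin_edges) - 1L
  if (length(phi) != n) stop("length(phi) must equal length(bin_edges) - 1")
  if (length(sigma_phi) == 1L) sigma_phi <- rep(sigma_phi, n)
  if (length(sigma_phi) != n) stop("sigma_phi has wrong length")
  if (any(phi < 0) || any(sigma_phi < 0)) {
    stop("phi and sigma_phi must be non-negative")
  }
  structure(
    list(bin_edges = as.numeric(bin_edges), phi = as.numeric(phi),
         sigma_phi = as.numeric(sigma_phi), kind = kind,
         medium = medium, beam = beam),
    class = "fluence_spectrum")
}

spectrum_mids <- function(s) {
  (s$bin_edges[-1] + s$bin_edges[-length(s$bin_edges)]) / 2
}
spectrum_widths <- function(s) diff(s$bin_edges)
spectrum_emax <- function(s) s$bin_edges[length(s$bin_edges)]

#' @export
print.fluence_spectrum <- function(x, ...) {
  cat(sprintf(
    "<fluence_spectrum> %s in %s, beam %s: %d bins, %.3g-%.4g keV, total %.4g cm^-2/Gy\n",
    x$kind, x$medium, x$beam, length(x$phi), x$bin_edges[1],
    spectrum_emax(x), sum(x$phi * spectrum_widths(x))))
  invisible(x)
}

.spec_units <- "per_cm2_per_keV_per_Gy"

#' Write a fluence spectrum to the text dialect
#'
#' UTF-8 text with `#`-prefixed header keys `kind`, `medium`, `beam`, `units`,
#' then rows `e_lo_keV  e_hi_keV  phi  sigma_phi`.  Round-trips bit-identically
#' through [read_spectrum()].
#'
#' @param spectrum a `fluence_spectrum`.
#' @param path output file.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "fluence_spectrum"))
  n <- length(spectrum$phi)
  rows <- sprintf("%.15g %.15g %.15g %.15g",
                  spectrum$bin_edges[-(n + 1)], spectrum$bin_edges[-1],
                  spectrum$phi, spectrum$sigma_phi)
  writeLines(c(
    paste0("# kind: ", spectrum$kind),
    paste0("# medium: ", spectrum$medium),
    paste0("# beam: ", spectrum$beam),
    paste0("# units: ", .spec_units),
    "# columns: e_lo_keV e_hi_keV phi sigma_phi",
    rows), path)
  invisible(path)
}

#' Read a fluence spectrum from the text dialect
#'
#' @param path input file (dialect of [write_spectrum()]).
#' @return a validated `fluence_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grepl("^\\s*#", lines)
  get_key <- function(key) {
    m <- grep(paste0("^\\s*#\\s*", key, "\\s*:"), lines[hdr_idx], value = TRUE)
    if (length(m) == 0L) {
      stop(sprintf("format error in '%s': missing mandatory header key '%s'",
                   path, key))
    }
    trimws(sub(paste0("^\\s*#\\s*", key, "\\s*:"), "", m[1]))
  }
  kind <- get_key("kind"); medium <- get_key("medium")
  beam <- get_key("beam"); units <- get_key("units")
  if (units != .spec_units) {
    stop(sprintf("format error in '%s': units must be '%s'", path, .spec_units))
  }
  data_idx <- which(!hdr_idx & nzchar(trimws(lines)))
  if (length(data_idx) == 0L) stop("format error: no data rows in ", path)
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    stop(sprintf("format error in '%s': line %d does not have 4 columns",
                 path, data_idx[bad[1]]))
  }
  num <- matrix(as.numeric(unlist(fields)), ncol = 4, byrow = TRUE)
  if (anyNA(num)) {
    bad <- data_idx[which(rowSums(is.na(num)) > 0)[1]]
    stop(sprintf("format error in '%s': non-numeric entry on line %d",
                 path, bad))
  }
  lo <- num[, 1]; hi <- num[, 2]
  if (any(hi <= lo)) {
    stop(sprintf("format error in '%s': line %d has e_hi <= e_lo",
                 path, data_idx[which(hi <= lo)[1]]))
  }
  n <- nrow(num)
  if (n > 1 && any(abs(lo[-1] - hi[-n]) > 1e-9 * pmax(1, hi[-n]))) {
    bad <- which(abs(lo[-1] - hi[-n]) > 1e-9 * pmax(1, hi[-n]))[1]
    stop(sprintf("format error in '%s': bins not contiguous at line %d",
                 path, data_idx[bad + 1]))
  }
  if (any(num[, 3] < 0)) {
    stop(sprintf("format error in '%s': negative fluence on line %d",
                 path, data_idx[which(num[, 3] < 0)[1]]))
  }
  fluence_spectrum(c(lo, hi[n]), num[, 3], num[, 4],
                   kind = kind, medium = medium, beam = beam)
}

#' Bin-wise SE/TEF fluence ratio
#'
#' @param se,tef `fluence_spectrum`s on identical bins, same medium and beam.
#' @return object of class `ratio_spectrum` (fields `bin_edges`, `ratio`,
#'   `sigma`); 0/0 bins give 0; values clipped to `[0, 1]` (tolerance 1e-9).
#' @export
se_fraction <- function(se, tef) {
  stopifnot(inherits(se, "fluence_spectrum"), inherits(tef, "fluence_spectrum"))
  if (length(se$phi) != length(tef$phi) ||
      any(abs(se$bin_edges - tef$bin_edges) >
          1e-9 * pmax(1, tef$bin_edges))) {
    stop("alignment error: spectra are not on identical bins")
  }
  if (!identical(se$medium, tef$medium) || !identical(se$beam, tef$beam)) {
    stop("alignment error: spectra have different medium or beam")
  }
  ratio <- ifelse(tef$phi > 0, se$phi / tef$phi, 0)
  sigma <- ifelse(tef$phi > 0 & se$phi > 0,
                  ratio * sqrt((se$sigma_phi / pmax(se$phi, 1e-300))^2 +
                               (tef$sigma_phi / tef$phi)^2),
                  0)
  ratio <- pmin(pmax(ratio, 0), 1 + 1e-9)
  ratio <- pmin(ratio, 1)
  structure(list(bin_edges = tef$bin_edges, ratio = ratio, sigma = sigma,
                 medium = tef$medium, beam = tef$beam),
            class = "ratio_spectrum")
}

#' CEMA of a fluence spectrum
#'
#' Converted energy per unit mass: `sum_i S(E_i) phi_i dE_i` converted to Gy.
#' For a spectrum normalised per unit absorbed dose this self-consistency
#' integral is ~1 Gy per Gy when the spectrum and stopping powers are
#' consistent.
#'
#' @param spectrum a `fluence_spectrum`.
#' @param table a `stopping_table` for the spectrum's medium covering its
#'   energy range.
#' @return CEMA in Gy (per Gy of the normalising dose).
#' @export
cema <- function(spectrum, table) {
  stopifnot(inherits(spectrum, "fluence_spectrum"),
            inherits(table, "stopping_table"))
  if (!is.na(table$material) && table$material != spectrum$medium) {
    stop(sprintf("table material '%s' does not match spectrum medium '%s'",
                 table$material, spectrum$medium))
  }
  rng <- range(table$energies)
  mids <- spectrum_mids(spectrum)
  if (min(mids) < rng[1] * (1 - 1e-9) || max(mids) > rng[2] * (1 + 1e-9)) {
    stop("range mismatch: stopping table does not cover the spectrum")
  }
  S <- lookup_stopping(table, mids, "S")
  sum(S * spectrum$phi * spectrum_widths(spectrum)) * .mev_g_to_gy
}

#' Rebin a fluence spectrum conservatively
#'
#' Total fluence `sum phi dE` is conserved exactly (piecewise-constant
#' density model); per-bin uncertainties propagate as uncorrelated
#' overlap-weighted sums.
#'
#' @param spectrum a `fluence_spectrum`.
#' @param new_edges strictly increasing edges within the old range.
#' @return a `fluence_spectrum` on the new bins.
#' @export
rebin <- function(spectrum, new_edges) {
  stopifnot(inherits(spectrum, "fluence_spectrum"))
  old <- spectrum$bin_edges
  if (any(diff(new_edges) <= 0)) stop("new_edges must be strictly increasing")
  if (new_edges[1] < old[1] - 1e-9 ||
      new_edges[length(new_edges)] > old[length(old)] + 1e-9) {
    stop("new_edges outside the spectrum's energy range")
  }
  cum <- c(0, cumsum(spectrum$phi * diff(old)))
  cnew <- stats::approx(old, cum, xout = new_edges, rule = 2)$y
  wnew <- diff(new_edges)
  phi_new <- pmax(diff(cnew), 0) / wnew
  # uncorrelated propagation via bin overlaps
  nn <- length(wnew); no <- length(old) - 1L
  var_new <- numeric(nn)
  for (i in seq_len(nn)) {
    ov <- pmin(new_edges[i + 1], old[-1]) - pmax(new_edges[i], old[-(no + 1)])
    ov <- pmax(ov, 0)
    var_new[i] <- sum((ov * spectrum$sigma_phi)^2) / wnew[i]^2
  }
  fluence_spectrum(new_edges, phi_new, sqrt(var_new),
                   kind = spectrum$kind, medium = spectrum$medium,
                   beam = spectrum$beam)
}
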