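test_that("spectrum construction validates its invariants", {
  expect_s3_class(fluence_spectrum(c(1, 2, 4), c(1, 2), kind = "TEF"),
                  "fluence_spectrum")
  expect_error(fluence_spectrum(c(1, 2, 2), c(1, 2)), "increasing")
  expect_error(fluence_spectrum(c(0.5, 1, 2), c(1, 2)), "floor")
  expect_error(fluence_spectrum(c(1, 2, 4), c(1, -1)), "non-negative")
  expect_error(fluence_spectrum(c(1, 2, 4), c(1, 2, 3)), "length")
})

test_that("spectrum files round-trip bit-identically", {
  s <- fluence_spectrum(c(1, 2, 4, 8), c(0.5, 1.25e-3, 2),
                        sigma_phi = c(0.01, 1e-5, 0.2),
                        kind = "SE", medium = "water", beam = "50kV")
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, p1)
  s2 <- read_spectrum(p1)
  expect_equal(s2$phi, s$phi, tolerance = 1e-12)
  expect_equal(s2$bin_edges, s$bin_edges, tolerance = 1e-12)
  expect_identical(s2$kind, "SE")
  expect_identical(s2$beam, "50kV")
  write_spectrum(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("malformed spectrum files fail with located format errors", {
  p <- withr::local_tempfile(fileext = ".txt")
  hdr <- c("# kind: TEF", "# medium: water", "# beam: b",
           "# units: per_cm2_per_keV_per_Gy")
  writeLines(c(hdr, "2 1 0.5 0"), p)   # descending edges
  expect_error(read_spectrum(p), "e_hi <= e_lo")
  writeLines(c(hdr, "1 2 -0.5 0"), p)  # negative fluence
  expect_error(read_spectrum(p), "negative fluence")
  writeLines(c(hdr[-1], "1 2 0.5 0"), p)  # missing mandatory key
  expect_error(read_spectrum(p), "missing mandatory header key 'kind'")
  writeLines(c(hdr, "1 2 0.5 0", "3 4 0.5 0"), p)  # gap between bins
  expect_error(read_spectrum(p), "not contiguous")
})

test_that("se_fraction handles degenerate bins and mismatches", {
  edges <- c(1, 2, 4, 8)
  tef <- fluence_spectrum(edges, c(2, 0, 4), kind = "TEF",
                          medium = "w", beam = "b")
  se_eq <- fluence_spectrum(edges, c(2, 0, 4), kind = "SE",
                            medium = "w", beam = "b")
  r <- se_fraction(se_eq, tef)
  expect_equal(r$ratio, c(1, 0, 1))  # 0/0 -> 0
  se0 <- fluence_spectrum(edges, c(0, 0, 0), kind = "SE",
                          medium = "w", beam = "b")
  expect_equal(se_fraction(se0, tef)$ratio, c(0, 0, 0))
  other <- fluence_spectrum(c(1, 2, 4, 9), c(1, 1, 1), kind = "SE",
                            medium = "w", beam = "b")
  expect_error(se_fraction(other, tef), "alignment error")
  wrong_beam <- fluence_spectrum(edges, c(1, 1, 1), kind = "SE",
                                 medium = "w", beam = "c")
  expect_error(se_fraction(wrong_beam, tef), "alignment error")
})

test_that("cema is linear and ~1 Gy/Gy for generator output", {
  edges <- exp(seq(log(1), log(100), length.out = 21))
  zero <- fluence_spectrum(edges, rep(0, 20), kind = "TEF",
                           medium = "water", beam = "b")
  expect_equal(cema(zero, water_table), 0)
  s1 <- random_spectrum(11, n_bins = 20, e_max = 100)
  s2 <- fluence_spectrum(s1$bin_edges, 2 * s1$phi, kind = "TEF",
                         medium = "water", beam = "test")
  expect_equal(cema(s2, water_table), 2 * cema(s1, water_table),
               tolerance = 1e-12)
  # generated spectra are normalised to unit CEMA; check against an
  # independent fine-grid oracle (direct analytic stopping powers on a
  # 10x refined grid)
  pair <- simulate_fluence_spectrum(
    default_spectrum_config("50kV", "EBT3_active", seed = 1, noise_rel = 0))
  tef <- pair$tef
  fine_edges <- exp(seq(log(tef$bin_edges[1]), log(spectrum_emax(tef)),
                        length.out = 10 * length(tef$phi) + 1))
  fine <- rebin(tef, fine_edges)
  mids <- letfilm:::spectrum_mids(fine)
  S <- collision_stopping_power(load_material("EBT3_active"), mids)
  oracle <- sum(S * fine$phi * diff(fine_edges)) * 1.602176634e-10
  expect_equal(oracle, 1.0, tolerance = 0.02)
})

test_that("rebin conserves total fluence", {
  s <- random_spectrum(3, n_bins = 25, e_max = 200)
  total <- sum(s$phi * diff(s$bin_edges))
  expect_equal(rebin(s, s$bin_edges)$phi, s$phi, tolerance = 1e-12)
  # merge two bins: width-weighted average
  e <- c(1, 2, 4, 8)
  sp <- fluence_spectrum(e, c(3, 6, 1), kind = "TEF", medium = "w", beam = "b")
  m <- rebin(sp, c(1, 4, 8))
  expect_equal(m$phi[1], (3 * 1 + 6 * 2) / 3, tolerance = 1e-12)
  # random refine/coarsen round trip conserves fluence to 1e-9
  for (seed in 1:20) {
    new_edges <- letfilm:::with_seed(seed, {
      sort(c(range(s$bin_edges),
             runif(17, min(s$bin_edges), max(s$bin_edges))))
    })
    r <- rebin(s, new_edges)
    expect_equal(sum(r$phi * diff(new_edges)), total, tolerance = 1e-9)
    back <- rebin(r, range(s$bin_edges))
    expect_equal(sum(back$phi * diff(range(s$bin_edges))), total,
                 tolerance = 1e-9)
  }
  expect_error(rebin(s, c(0.5, 10)), "outside")
})
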