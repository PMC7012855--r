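test_that("monoenergetic spectra collapse both averages to L(E0)", {
  # single populated bin far above delta; empty lowest bin kills the
  # track-end term
  edges <- c(1, 2, 99, 101, 120)
  phi <- c(0, 0, 5, 0)
  s <- fluence_spectrum(edges, phi, kind = "TEF", medium = "water",
                        beam = "b")
  L0 <- linear_let(lookup_stopping(water_table, 100, "L"), 1.0)
  lt <- track_average_let(s, water_table)
  ld <- dose_average_let(s, water_table)
  expect_equal(lt, L0, tolerance = 1e-12)
  expect_equal(ld, L0, tolerance = 1e-12)
  expect_equal(let_ratio(list(L_dose = ld, L_track = lt)), 1.0,
               tolerance = 1e-12)
})

test_that("two equal-fluence bins give the closed-form averages", {
  # mocked table: linear LET exactly 2 and 4 keV/um at the two bin
  # midpoints; equal fluence content; empty lowest bin
  edges <- c(1, 3, 5, 7)
  tab <- mock_table(energies = c(1, 4, 6), let_keV_um = c(1, 2, 4))
  phi <- c(0, 1, 1)
  s <- fluence_spectrum(edges, phi, kind = "TEF", medium = "w", beam = "b")
  expect_equal(track_average_let(s, tab), 3.0, tolerance = 1e-9)
  expect_equal(dose_average_let(s, tab), (4 + 16) / (2 + 4),
               tolerance = 1e-9)
})

test_that("track-end term contributes the analytically predicted sums", {
  s <- random_spectrum(5, n_bins = 12, e_max = 50)
  cfg <- let_config(delta = 1)
  mids <- letfilm:::spectrum_mids(s)
  w <- diff(s$bin_edges)
  L <- lookup_stopping(water_table, mids, "L")
  Sd <- lookup_stopping(water_table, 1, "S")
  # independent brute-force evaluation of both averages
  num1 <- sum(L * s$phi * w) + Sd * s$phi[1] * 1
  den0 <- sum(s$phi * w) + s$phi[1] * 1
  num2 <- sum(L^2 * s$phi * w) + Sd^2 * s$phi[1] * 1
  expect_equal(track_average_let(s, water_table, cfg), 0.1 * num1 / den0,
               tolerance = 1e-12)
  expect_equal(dose_average_let(s, water_table, cfg), 0.1 * num2 / num1,
               tolerance = 1e-12)
})

test_that("dose average dominates track average on random spectra", {
  for (seed in 1:1000) {
    edges <- exp(seq(log(1), log(300), length.out = 13))
    phi <- letfilm:::with_seed(seed, stats::rgamma(12, shape = 0.6))
    if (sum(phi) == 0) next
    s <- fluence_spectrum(edges, phi, kind = "TEF", medium = "water",
                          beam = "b")
    lt <- track_average_let(s, water_table)
    ld <- dose_average_let(s, water_table)
    expect_true(ld >= lt * (1 - 1e-12), label = paste("seed", seed))
  }
})

test_that("averages are invariant under fluence rescaling", {
  s <- random_spectrum(9, n_bins = 20, e_max = 400)
  s3 <- fluence_spectrum(s$bin_edges, 137 * s$phi, kind = "TEF",
                         medium = "water", beam = "b")
  expect_equal(track_average_let(s3, water_table),
               track_average_let(s, water_table), tolerance = 1e-12)
  expect_equal(dose_average_let(s3, water_table),
               dose_average_let(s, water_table), tolerance = 1e-12)
})

test_that("averages are stable under 10x bin refinement", {
  s <- random_spectrum(17, n_bins = 50, e_max = 500)
  fine_edges <- exp(seq(log(1), log(500), length.out = 501))
  fine <- rebin(s, fine_edges)
  for (f in list(track_average_let, dose_average_let)) {
    expect_equal(f(fine, water_table), f(s, water_table), tolerance = 2e-3)
  }
})

test_that("degenerate inputs raise the contracted errors", {
  edges <- c(1, 2, 4)
  empty <- fluence_spectrum(edges, c(0, 0), kind = "TEF", medium = "w",
                            beam = "b")
  expect_error(track_average_let(empty, water_table), "entirely empty")
  s <- fluence_spectrum(c(2, 4, 8), c(1, 1), kind = "TEF", medium = "w",
                        beam = "b")
  expect_error(track_average_let(s, water_table, let_config(delta = 3)),
               "configuration error")
})

test_that("bootstrap uncertainties are seeded, zero-safe and averaging", {
  s <- random_spectrum(21, n_bins = 25, e_max = 200)
  expect_equal(let_uncertainties(s, water_table, seed = 1),
               c(u_track = 0, u_dose = 0))
  # flat spectrum with 1% relative noise: averaging suppresses the
  # uncertainty well below 1%
  edges <- exp(seq(log(1), log(200), length.out = 31))
  flat <- fluence_spectrum(edges, rep(1, 30), sigma_phi = rep(0.01, 30),
                           kind = "TEF", medium = "water", beam = "b")
  u <- let_uncertainties(flat, water_table, n_boot = 400, seed = 2)
  lt <- track_average_let(flat, water_table)
  expect_lt(u[["u_track"]] / lt, 0.01)
  u2 <- let_uncertainties(flat, water_table, n_boot = 400, seed = 2)
  expect_identical(u, u2)
  u3 <- let_uncertainties(flat, water_table, n_boot = 400, seed = 3)
  expect_false(identical(u, u3))
  expect_error(let_uncertainties(flat, water_table, n_boot = 50, seed = 1),
               "n_boot")
})

test_that("cross statistics handle subsets gracefully", {
  grid <- load_printed_let_grid()
  one <- grid[grid$beam == "20kV" & grid$film == "EBT3" &
                grid$kind == "TEF", ]
  w <- capture_warnings(cs <- cross_statistics(one))
  expect_match(w, "reference beam", all = FALSE)
  expect_equal(cs$rel_track$ratio, 1)
  s <- cs$summary
  expect_equal(s$value[s$statistic == "rel_track_min" & s$kind == "TEF"], 1.0)
  # missing SE cells are skipped with a warning
  holes <- grid[grid$film == "EBT3" &
                  !(grid$kind == "SE" & grid$beam == "80kV"), ]
  expect_warning(cross_statistics(holes), "skipped")
  expect_error(cross_statistics(grid[, 1:3]), "columns")
})
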