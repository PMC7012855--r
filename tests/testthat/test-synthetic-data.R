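test_that("spectrum generation is a pure function of (config, seed)", {
  cfg <- default_spectrum_config("80kV", "EBT3_active", seed = 5)
  before <- letfilm:::with_seed(99, runif(3))
  a <- simulate_fluence_spectrum(cfg)
  b <- simulate_fluence_spectrum(cfg)
  expect_identical(a$tef$phi, b$tef$phi)
  expect_identical(a$se$phi, b$se$phi)
  # the caller's RNG stream is untouched
  expect_identical(letfilm:::with_seed(99, runif(3)), before)
  c2 <- simulate_fluence_spectrum(
    default_spectrum_config("80kV", "EBT3_active", seed = 6))
  expect_false(identical(a$tef$phi, c2$tef$phi))
})

test_that("zero SE amplitude yields an identically zero SE spectrum", {
  cfg <- default_spectrum_config("50kV", "EBT3_active", seed = 3)
  cfg$se_tail[["amp"]] <- 0
  pair <- simulate_fluence_spectrum(cfg)
  expect_true(all(pair$se$phi == 0))
  expect_equal(sum(se_fraction(pair$se, pair$tef)$ratio), 0)
})

test_that("noiseless TEF dominates SE bin-wise and CEMA normalises to 1", {
  for (bm in c("20kV", "Co60")) {
    cfg <- default_spectrum_config(bm, "MDV3_active", seed = 2,
                                   noise_rel = 0)
    pair <- simulate_fluence_spectrum(cfg)
    expect_true(all(pair$tef$phi >= pair$se$phi - 1e-12), label = bm)
    tab <- build_stopping_table(
      load_material("MDV3_active"),
      exp(seq(log(1), log(cfg$e_max), length.out = 300)))
    expect_equal(cema(pair$tef, tab), 1.0, tolerance = 0.02, label = bm)
  }
})

test_that("SE contribution matches the physics-motivated calibration", {
  # Co-60: secondary electrons carry 40-90% of the total fluence in every
  # 1-10 keV bin; soft x rays: below 30% at 1 keV, falling with energy
  for (med in c("EBT3_active", "MDV3_active")) {
    pair <- simulate_fluence_spectrum(
      default_spectrum_config("Co60", med, seed = 42))
    r <- se_fraction(pair$se, pair$tef)
    mids <- letfilm:::spectrum_mids(pair$tef)
    band <- r$ratio[mids >= 1 & mids <= 10]
    expect_true(all(band >= 0.40 & band <= 0.90), label = med)
  }
  p20 <- simulate_fluence_spectrum(
    default_spectrum_config("20kV", "EBT3_active", seed = 42))
  r20 <- se_fraction(p20$se, p20$tef)
  expect_lt(r20$ratio[1], 0.30)
  expect_true(all(r20$ratio <= 1))
  # noiseless x-ray ratio decreases with energy over the SE range
  # (K-shell lines off: they punch local dips into the TEF denominator)
  cfg0 <- default_spectrum_config("20kV", "EBT3_active", seed = 1,
                                  noise_rel = 0)
  cfg0$kshell <- numeric(0)
  p0 <- simulate_fluence_spectrum(cfg0)
  r0 <- se_fraction(p0$se, p0$tef)
  mids <- letfilm:::spectrum_mids(p0$tef)
  sel <- which(mids >= 1 & mids <= 8 & r0$ratio > 0)
  expect_true(all(diff(r0$ratio[sel]) <= 1e-9))
})

test_that("dose-response generator encodes the scale as ground-truth RE", {
  cfg <- response_gen_config("EBT3", scales = c(Co60 = 1, `20kV` = 4),
                             noise_rel = 0, seed = 1)
  cur <- simulate_dose_response(cfg)
  re <- relative_efficiency(cur$Co60, cur$`20kV`, c(0.053, 0.176, 0.510))
  expect_equal(re$re, rep(4, 3), tolerance = 1e-3)
  # all-equal scales: curves identical up to noise, RE ~ 1
  cfg1 <- response_gen_config("EBT3",
                              scales = c(Co60 = 1, A = 1, B = 1),
                              noise_rel = 0.005, seed = 9)
  cur1 <- simulate_dose_response(cfg1)
  r1 <- relative_efficiency_levels(cur1$Co60, cur1$A)
  expect_equal(r1$re_weighted, 1, tolerance = 0.03)
  expect_error(simulate_dose_response(cfg, beams = c("Co60", "nope")),
               "no sensitivity scale")
})

test_that("study fixture is reproducible and carries a recoverable truth", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man1 <- make_study_fixture(d1, seed = 4, films = "EBT3")
  man2 <- make_study_fixture(d2, seed = 4, films = "EBT3")
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(all(man1$s_true[man1$beam == "Co60"] == 1))
  # ground truth is monotone in the generated dose-average LET
  o <- order(man1$L_dose_tef)
  expect_true(all(diff(man1$s_true[o]) >= 0))
  # the sensitivity map itself has the flat / rapid-rise / slow-rise shape
  l <- seq(0.2, 12, by = 0.1)
  s <- re_level_curve(l)
  expect_true(all(diff(s) > 0))
  d <- diff(s)
  expect_gt(which.max(d), 10)              # steepest rise is interior...
  expect_lt(which.max(d), length(d) - 10)  # ...not at either end
  expect_lt(max(abs(s[l <= 2] / s[1] - 1)), 0.12)  # flat low-LET plateau
  expect_lt(max(d[l[-1] > 9]) / max(d), 0.15)      # slow terminal rise
})
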