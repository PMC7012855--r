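test_that("curve construction validates monotonicity within noise", {
  expect_error(dose_response_curve("F", "B", dose = c(1, 1, 2),
                                   netod = c(0.1, 0.2, 0.3)),
               "strictly increasing")
  expect_error(dose_response_curve("F", "B", dose = 1:3,
                                   netod = c(0.1, 0.3, 0.2)),
               "validation error")
  # a dip inside 3 sigma is tolerated
  expect_s3_class(
    dose_response_curve("F", "B", dose = 1:3, netod = c(0.1, 0.3, 0.295),
                        sigma_netod = rep(0.01, 3)),
    "dose_response_curve")
})

test_that("curve files round-trip", {
  cv <- make_curve(s = 2, sigma_rel = 0.01)
  p <- withr::local_tempfile(fileext = ".txt")
  write_dose_response(cv, p)
  cv2 <- read_dose_response(p)
  expect_equal(cv2$dose, cv$dose, tolerance = 1e-12)
  expect_equal(cv2$netod, cv$netod, tolerance = 1e-12)
  expect_identical(cv2$film, "EBT3")
})

test_that("dose inversion is exact at points, closed-form on linear curves", {
  lin <- dose_response_curve("F", "B", dose = seq(1, 10),
                             netod = 0.1 * seq(1, 10))
  expect_equal(dose_for_netod(lin, 0.5), 5, tolerance = 1e-8)
  expect_equal(dose_for_netod(lin, 0.3), 3, tolerance = 1e-12)  # tabulated
  expect_error(dose_for_netod(lin, 1.5), "range error")
  expect_error(dose_for_netod(lin, 0.05), "range error")
})

test_that("inversion round-trips through the forward curve", {
  cv <- make_curve(s = 1.7)
  y <- seq(min(cv$netod) + 1e-6, max(cv$netod) - 1e-6, length.out = 40)
  d <- dose_for_netod(cv, y)
  expect_equal(curve_netod(cv, d), y, tolerance = 1e-6)
})

test_that("RE is the dose-scaling factor, independent of level and channel scale", {
  co <- make_curve(beam = "Co60", s = 1)
  q4 <- make_curve(beam = "20kV", s = 4)
  lv <- c(0.053, 0.176, 0.510)
  re <- relative_efficiency(co, q4, lv)
  expect_equal(re$re, rep(4, 3), tolerance = 1e-3)
  expect_equal(relative_efficiency(co, co, lv)$re, rep(1, 3),
               tolerance = 1e-12)
  # common rescaling of both netOD axes cancels
  scale_curve <- function(cv, k) dose_response_curve(
    cv$film, cv$beam, cv$channel, cv$dose, k * cv$netod, k * cv$sigma_netod)
  re2 <- relative_efficiency(scale_curve(co, 0.37), scale_curve(q4, 0.37),
                             0.37 * lv)
  expect_equal(re2$re, re$re, tolerance = 1e-9)
  other <- make_curve(film = "MDV3", s = 4)
  expect_error(relative_efficiency(co, other, 0.05), "mismatch")
})

test_that("weighted average RE has the closed forms", {
  expect_equal(weighted_average_re(3)[["re_weighted"]], 3)
  expect_equal(weighted_average_re(c(2, 2, 2),
                                   c(0.1, 0.5, 2))[["re_weighted"]], 2)
  wa <- weighted_average_re(c(1, 3), c(1, 1))
  expect_equal(wa[["re_weighted"]], 2.0)
  expect_equal(wa[["sigma"]], sqrt(0.5), tolerance = 1e-12)
  expect_error(weighted_average_re(numeric(0)), "empty")
})

test_that("weighted RE recovers the generator scale under noise", {
  err <- vapply(1:20, function(i) {
    co <- make_curve(beam = "Co60", s = 1, noise_rel = 0.01,
                     sigma_rel = 0.01, seed = 2 * i)
    q <- make_curve(beam = "50kV", s = 3, noise_rel = 0.01,
                    sigma_rel = 0.01, seed = 2 * i + 1)
    rr <- relative_efficiency_levels(co, q, levels = c(0.053, 0.176, 0.510))
    abs(rr$re_weighted / 3 - 1)
  }, numeric(1))
  expect_lt(mean(err), 0.02)
})

test_that("response-vs-LET assembly joins, sorts, and is axis-invariant", {
  lets <- data.frame(beam = c("A", "B", "C"), kind = "TEF",
                     L_track = c(5, 1, 3), L_dose = c(9, 2, 30))
  vals <- data.frame(beam = c("A", "B", "C"), value = c(3, 1, 2))
  t1 <- assemble_re_vs_let(vals, lets, axis = "track", kind = "TEF")
  expect_equal(t1$beam, c("B", "C", "A"))
  expect_true(all(diff(t1$value) > 0))  # monotone by construction here
  t2 <- assemble_re_vs_let(vals, lets, axis = "dose", kind = "TEF")
  expect_equal(sort(t2$value), sort(t1$value))  # axis switch: same values
  expect_equal(t2$beam, c("B", "A", "C"))       # only the order can change
  one <- assemble_re_vs_let(vals[1, ], lets, axis = "track", kind = "TEF")
  expect_equal(nrow(one), 1)
  bad <- data.frame(beam = c("A", "Z"), value = c(1, 2))
  expect_error(assemble_re_vs_let(bad, lets), "join error.*Z")
})
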