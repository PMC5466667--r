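test_that("exponential fit recovers a noiseless release rate exactly", {
  t <- seq(0, 60, by = 2)
  tr <- release_trace(t, 1 - exp(-0.05 * t))
  fit <- fit_release_rate(tr)
  expect_equal(fit$k, 0.05, tolerance = 1e-6)
  expect_gt(fit$R2, 1 - 1e-10)
  expect_equal(fit$F_inf, 1)
})

test_that("degenerate and underdetermined traces are rejected", {
  expect_error(fit_release_rate(release_trace(1:10, rep(0.4, 10))),
               "degenerate")
  expect_error(fit_release_rate(release_trace(1:3, c(0.1, 0.2, 0.3))),
               "4 points")
  expect_error(release_trace(c(1, 1, 2), c(0, 0.1, 0.2)),
               "strictly increasing")
  expect_error(release_trace(1:3, c(0, 0.5, 1.2)), "\\[0, 1\\]")
})

test_that("noisy recovery stays within 5% with R2 at the assay floor", {
  tr <- gen_release_trace(k_true = 0.02, times = seq(0, 120, by = 4),
                          noise_sd = 0.01, seed = 31)
  fit <- fit_release_rate(tr)
  expect_lt(abs(fit$k - 0.02) / 0.02, 0.05)
  expect_gte(fit$R2, 0.96)
})

test_that("early-linear fitting uses the F < 0.3 window", {
  t <- seq(0, 100, by = 5)
  k <- 0.01
  tr <- release_trace(t, 1 - exp(-k * t))
  fit <- fit_release_rate(tr, method = "early_linear")
  # the early-time slope of 1 - exp(-kt) approaches k from below
  expect_lt(abs(fit$k - k) / k, 0.2)
  expect_gt(fit$k, 0)
})

test_that("permeability and diffusion derive from rate and geometry", {
  geom <- assay_geometry()
  pd <- permeability_from_rate(0.03, geom, k_unit = "per_h")
  expect_equal(pd$P, 5.56e-13, tolerance = 1e-3)
  expect_equal(pd$D, 1.67e-21, tolerance = 1e-3)
  pd2 <- permeability_from_rate(0.03, assay_geometry(radius = 400),
                                k_unit = "per_h")
  expect_equal(pd2$P, 2 * pd$P)
  # rate_from_permeability inverts the map
  expect_equal(rate_from_permeability(pd$P, geom, "per_h"), 0.03,
               tolerance = 1e-12)
})

test_that("molar fractions convert to surface fractions by head area", {
  expect_equal(molar_to_surface_fraction(0.5, 0.2, 0.6), 0.75)
  expect_equal(molar_to_surface_fraction(0.25, 0.2, 0.4), 0.4)
  expect_equal(molar_to_surface_fraction(c(0, 1)), c(0, 1))
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(molar_to_surface_fraction(x)) > 0))
})

test_that("fit_permeability_curve reproduces its inputs exactly", {
  chi <- c(0, 0.25, 0.6, 1)
  val <- c(2, 9, 14, 5)
  cv <- fit_permeability_curve(chi, val)
  expect_equal(eval_curve(cv, chi), val / val[1], tolerance = 1e-12)
  cv3 <- fit_permeability_curve(c(0, 0.5, 1), c(1, 10, 2))
  expect_equal(eval_curve(cv3, 0.25), 7.625, tolerance = 1e-12)
  # collinear points collapse to a degree-1 polynomial
  lin <- fit_permeability_curve(c(0, 0.5, 1), c(2, 3, 4))
  expect_lt(abs(curve_coefficients(lin)[3]), 1e-12)
  expect_error(fit_permeability_curve(c(0, 0.5, 0.5, 1), 1:4),
               "duplicate")
  expect_error(fit_permeability_curve(c(0, 1), c(1, 2)), "3 points")
})

test_that("trace CSV round-trips through the column contract", {
  traces <- list(gen_release_trace(k_true = 0.01, seed = 1,
                                   composition = "LA/GML 3:1"),
                 gen_release_trace(k_true = 0.04, seed = 2,
                                   composition = "LA/GML 1:1"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(traces, path)
  back <- read_traces_csv(path)
  expect_length(back, 2)
  comps <- unname(vapply(back, function(x) x$composition,
                         character(1)))
  expect_identical(sort(comps), c("LA/GML 1:1", "LA/GML 3:1"))
  b1 <- back[[which(comps == "LA/GML 3:1")]]
  expect_equal(b1$fraction_released, traces[[1]]$fraction_released,
               tolerance = 1e-12)
})
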