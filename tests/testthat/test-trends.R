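# Thermophilisation rates, lapse, NES and the isotherm expectation.

test_that("per-plot trend is the OLS slope", {
  expect_equal(fit_plot_trend(c(2001, 2006, 2011), c(3.00, 3.05, 3.10)), 0.01)
  expect_equal(fit_plot_trend(2001:2004, rep(2.8, 4)), 0)
  expect_true(is.na(fit_plot_trend(2001, 3)))
  expect_true(is.na(fit_plot_trend(c(2001, 2001), c(3, 4))))
  expect_true(is.na(fit_plot_trend(c(2001, 2006), c(3, NA))))
})

test_that("trend slopes agree with the lm oracle on random instances", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    x <- sort(sample(2000:2021, n))
    y <- rnorm(n, 3, 0.5)
    expect_equal(fit_plot_trend(x, y), unname(coef(lm(y ~ x))[2]),
                 tolerance = 1e-6)
  }
})

test_that("lapse estimation recovers a known gradient", {
  est <- estimate_lapse(c(3.0, 2.5, 2.0), c(500, 1000, 1500))
  expect_equal(est$lapse_per_100m, -0.1)
  expect_equal(est$r_squared, 1)

  flat <- estimate_lapse(rep(2.5, 5), c(300, 700, 1200, 1900, 2500))
  expect_equal(flat$lapse_per_100m, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(estimate_lapse(c(3, 2), c(500, 1500)), ">= 3 plots")
  expect_error(estimate_lapse(c(3, 2, 1), c(500, 500, 500)), "elevation")
})

test_that("NES formula, linearity and scale equivariance", {
  expect_equal(compute_nes(0.01, 0.1), 100)
  expect_equal(compute_nes(0, 0.25), 0)
  expect_equal(compute_nes(0.00244, 0.082), 29.7561, tolerance = 1e-4)
  # linearity in the slope
  expect_equal(compute_nes(3 * 0.004, 0.09), 3 * compute_nes(0.004, 0.09))
  # scaling slope and lapse together leaves the NES unchanged
  set.seed(2)
  s <- rnorm(10, 0, 0.01); a <- runif(10, 0.5, 2)
  expect_equal(compute_nes(a * s, a * 0.082), compute_nes(s, rep(0.082, 10)))
  expect_error(compute_nes(0.01, 0), "> 0")
  expect_error(compute_nes(0.01, -0.1), "> 0")
})

test_that("warming rate estimation matches a noiseless line and handles edge cases", {
  yrs <- 2001:2021
  w <- estimate_warming(data.frame(year = yrs, mean_temp = 5 + 0.042 * (yrs - 2001)))
  expect_equal(w$warming_per_decade, 0.42)
  expect_equal(w$r_squared, 1)

  flat <- estimate_warming(data.frame(year = yrs, mean_temp = rep(6, 21)))
  expect_equal(flat$warming_per_decade, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(estimate_warming(data.frame(year = 2001:2002, mean_temp = c(5, 6))),
               ">= 3 years")
})

test_that("synthetic warming series recovers the configured trend", {
  dat <- small_scenario(n_plots = 10, seed = 31)
  cfg <- attr(dat, "config")
  w <- estimate_warming(dat$temperature)
  # slope SE for 21 annual points at the configured noise sd (0.48 degC) is
  # about 0.17 degC/decade
  expect_lt(abs(w$warming_per_decade - cfg$warming_true), 2 * 0.175)
})

test_that("isotherm shift converts warming through the adiabatic window", {
  sh <- isotherm_shift(0.42, c(0.5, 0.67))
  expect_equal(round(sh$shift_low, 1), 62.7)
  expect_equal(sh$shift_high, 84)
  expect_equal(c(sh$shift_low_rounded, sh$shift_high_rounded), c(63, 84))

  zero <- isotherm_shift(0, c(0.5, 0.67))
  expect_equal(c(zero$shift_low, zero$shift_high), c(0, 0))
  degen <- isotherm_shift(0.5, c(0.5, 0.5))
  expect_equal(c(degen$shift_low, degen$shift_high), c(100, 100))
  expect_error(isotherm_shift(0.42, c(0, 0.5)), "> 0")
  expect_error(isotherm_shift(0.42, c(0.7, 0.5)), "low <= high")
})

test_that("trend building excludes data-poor communities with reasons", {
  sv <- data.frame(
    plot_id = c("a", "a", "a", "b", "b", "c"),
    lineage = "bryophyte",
    year = c(2001, 2006, 2011, 2001, 2006, 2001),
    n_species = 3L, n_with_t = c(3L, 3L, 3L, 3L, 0L, 3L),
    cti = c(3.0, 3.1, 3.2, 2.5, NA, 2.0),
    n_cryo = 0L, n_meso = 3L, n_thermo = 0L
  )
  tr <- build_trends(sv, list(bryophyte = -0.082))
  expect_equal(tr$plot_id, "a")
  expect_equal(tr$slope_per_yr, 0.02, tolerance = 1e-9)
  expect_equal(tr$nes_m_per_decade, 0.02 / 0.082 * 1000)
  excl <- attr(tr, "exclusions")
  expect_setequal(excl$plot_id, c("b", "c"))
  expect_true(all(grepl("fewer than 2 CTI values", excl$reason)))

  # a non-negative lapse cannot normalise the NES
  expect_error(build_trends(sv, list(bryophyte = 0.05)), "not negative")
})

test_that("default scenario NES recovery per stratum is unbiased", {
  dat <- small_scenario(n_plots = 400, seed = 19)
  cfg <- attr(dat, "config")
  sv <- build_surveys(dat$plots, dat$traits, dat$occurrences, verbose = FALSE)
  tr <- build_trends(sv, lapse_by_lineage(sv, dat$plots))
  for (l in c("bryophyte", "vascular")) {
    v <- tr$nes_m_per_decade[tr$lineage == l]
    expect_lt(abs(mean(v) - cfg$nes_true[[l]]), 2 * sd(v) / sqrt(length(v)))
  }
})
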