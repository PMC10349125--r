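# Synthetic generator: determinism, truth table, and the statistical
# structure the downstream stages assume.

test_that("identical seeds give identical output, different seeds differ", {
  a <- small_scenario(n_plots = 40, seed = 1)
  b <- small_scenario(n_plots = 40, seed = 1)
  c <- small_scenario(n_plots = 40, seed = 2)
  expect_identical(a$occurrences, b$occurrences)
  expect_identical(a$plots, b$plots)
  expect_identical(a$temperature, b$temperature)
  expect_false(identical(a$occurrences, c$occurrences))
})

test_that("truth table is pure algebra of the configuration", {
  cfg <- scenario_config(lapse_true = c(bryophyte = 0.1, vascular = 0.1),
                         nes_true = c(bryophyte = 100, vascular = 100),
                         warming_true = 0.42)
  tr <- truth_table(cfg)
  expect_equal(unique(tr$strata$slope_per_yr), 0.01)
  expect_equal(tr$warming_slope_per_yr, 0.042)
  expect_equal(tr$lapse_true, c(bryophyte = -0.1, vascular = -0.1))

  cfg2 <- scenario_config(infill = TRUE,
                          nes_true = c(bryophyte = 0, vascular = 0))
  tr2 <- truth_table(cfg2)
  expect_equal(tr2$count_trend$trend[tr2$count_trend$affinity == "cryophilic"],
               "flat")
})

test_that("config validation rejects impossible scenarios", {
  expect_error(scenario_config(survey_years = integer(0)), "empty")
  expect_error(scenario_config(survey_years = c(2001, 2001)), "increasing")
  expect_error(scenario_config(richness_mean = c(bryophyte = -1, vascular = 2)),
               "richness")
  expect_error(scenario_config(lapse_true = c(bryophyte = 0, vascular = 0.1)),
               "lapse_true")
})

test_that("trait missingness and richness match the configuration", {
  dat <- small_scenario(n_plots = 200, seed = 5)
  cfg <- attr(dat, "config")
  for (l in c("bryophyte", "vascular")) {
    tr <- dat$traits[dat$traits$lineage == l, ]
    frac <- mean(is.na(tr$temperature_value))
    p <- cfg$trait_missingness[[l]]
    # binomial tolerance, 3 sd
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / nrow(tr)))
    sv <- dat$occurrences
    sv <- sv[sv$species_id %in% tr$species_id, ]
    rich <- nrow(sv) / length(unique(paste(sv$plot_id, sv$year)))
    expect_lt(abs(rich - cfg$richness_mean[[l]]) / cfg$richness_mean[[l]], 0.15)
  }
  # clamping of latent community means is rare at default settings
  expect_lt(attr(dat, "clamped_fraction"), 0.01)
})

test_that("generated CTI declines with elevation at the configured lapse", {
  dat <- small_scenario(n_plots = 300, seed = 11)
  cfg <- attr(dat, "config")
  sv <- build_surveys(dat$plots, dat$traits, dat$occurrences, verbose = FALSE)
  lp <- lapse_by_lineage(sv, dat$plots)
  for (l in c("bryophyte", "vascular")) {
    est <- lp[[l]]
    expect_lt(abs(est$lapse_per_100m - (-cfg$lapse_true[[l]])),
              2 * est$se_per_100m)
  }
})

test_that("zero-signal scenario has no CTI trend; worked-example scenario has slope 0.01/yr", {
  null_cfg <- scenario_config(n_plots = 250, seed = 9,
                              nes_true = c(bryophyte = 0, vascular = 0),
                              sd_nes_plot = 0)
  dat <- generate_scenario(null_cfg)
  sv <- build_surveys(dat$plots, dat$traits, dat$occurrences, verbose = FALSE)
  tr <- build_trends(sv, lapse_by_lineage(sv, dat$plots))
  s <- tr$slope_per_yr
  expect_lt(abs(mean(s)), 2 * sd(s) / sqrt(length(s)))

  ex_cfg <- scenario_config(n_plots = 250, seed = 9,
                            lapse_true = c(bryophyte = 0.1, vascular = 0.1),
                            nes_true = c(bryophyte = 100, vascular = 100),
                            sd_nes_plot = 0)
  dat <- generate_scenario(ex_cfg)
  sv <- build_surveys(dat$plots, dat$traits, dat$occurrences, verbose = FALSE)
  tr <- build_trends(sv, lapse_by_lineage(sv, dat$plots))
  for (l in c("bryophyte", "vascular")) {
    s <- tr$slope_per_yr[tr$lineage == l]
    expect_lt(abs(mean(s) - 0.01), 2 * sd(s) / sqrt(length(s)))
  }
})

test_that("species persist between surveys at roughly the configured rate", {
  dat <- small_scenario(n_plots = 150, seed = 13)
  cfg <- attr(dat, "config")
  occ <- dat$occurrences
  yrs <- sort(unique(occ$year))
  kept <- 0; present <- 0
  for (k in seq_along(yrs)[-1]) {
    a <- occ[occ$year == yrs[k - 1], ]
    b <- occ[occ$year == yrs[k], ]
    ka <- paste(a$plot_id, a$species_id)
    kb <- paste(b$plot_id, b$species_id)
    present <- present + length(ka)
    kept <- kept + sum(ka %in% kb)
  }
  expect_lt(abs(kept / present - cfg$persistence), 0.03)
})

test_that("infill adds mesophilic/thermophilic species while cryophilic counts stay flat", {
  cfg <- scenario_config(n_plots = 250, seed = 21, infill = TRUE,
                         infill_rate = 0.15,
                         nes_true = c(bryophyte = 0, vascular = 0),
                         sd_nes_plot = 0)
  dat <- generate_scenario(cfg)
  sv <- build_surveys(dat$plots, dat$traits, dat$occurrences, verbose = FALSE)
  yr <- sv$year - min(sv$year)
  cryo_slope <- coef(lm(sv$n_cryo ~ yr))[[2]]
  warm_slope <- coef(lm(I(sv$n_meso + sv$n_thermo) ~ yr))[[2]]
  se_cryo <- summary(lm(sv$n_cryo ~ yr))$coefficients[2, 2]
  expect_lt(abs(cryo_slope), 3 * se_cryo)
  # 0.15 extra species/yr go to warm classes; part is invisible (missing
  # trait values), so expect a clearly positive trend of similar magnitude
  expect_gt(warm_slope, 0.05)
})
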