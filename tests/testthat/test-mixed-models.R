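# Mixed-model families: CTI trend LMMs with cluster bootstrap, NES models
# with the power variance function, Poisson count models, life-strategy
# contrast.

test_that("CTI trend model recovers a known slope and honours the plot minimum", {
  set.seed(101)
  d <- sim_cti_stratum(n_plots = 150, slope = 0.008)
  fit <- fit_cti_trend(d, B = 0)
  sl <- fit$coefficients[fit$coefficients$term == "year", ]
  expect_lt(abs(sl$estimate - 0.008), 2 * sl$se)
  expect_equal(fit$n_groups, 150L)

  small <- sim_cti_stratum(n_plots = 13, slope = 0)
  sk <- fit_cti_trend(small, B = 0)
  expect_s3_class(sk, "thermo_skip")
  expect_match(sk$reason, "13 plots")
})

test_that("with one observation per plot the fixed effect equals plain OLS", {
  set.seed(7)
  d <- data.frame(plot_id = sprintf("q%02d", 1:30),
                  year = sample(2001:2021, 30, replace = TRUE),
                  cti = rnorm(30, 3, 0.3))
  fit <- fit_cti_trend(d, B = 0)
  oracle <- unname(coef(lm(cti ~ year, data = d))[2])
  sl <- fit$coefficients$estimate[fit$coefficients$term == "year"]
  expect_equal(sl, oracle, tolerance = 1e-6)
})

test_that("bootstrap interval covers the estimate and narrows with more plots", {
  set.seed(55)
  d50 <- sim_cti_stratum(n_plots = 50, slope = 0.005)
  d200 <- sim_cti_stratum(n_plots = 200, slope = 0.005)
  f50 <- fit_cti_trend(d50, B = 99, engine = "lm")
  f200 <- fit_cti_trend(d200, B = 99, engine = "lm")
  expect_true(f50$ci$lower < f50$coefficients$estimate[2] &
                f50$coefficients$estimate[2] < f50$ci$upper)
  expect_lt(f200$ci$upper - f200$ci$lower, f50$ci$upper - f50$ci$lower)
})

test_that("NES lineage model: null contrast, homoscedastic exponent, recovery", {
  set.seed(70)
  # equal true NES in both lineages -> lineage effect compatible with 0
  tr0 <- sim_trends(400, nes = c(bryophyte = 25, vascular = 25))
  f0 <- fit_nes_lineage(tr0)
  cf <- f0$coefficients
  eff <- cf[cf$term == "lineagevascular", ]
  expect_lt(abs(eff$estimate), 2 * eff$se)

  # homoscedastic residuals -> variance-function exponent near zero
  tr1 <- sim_trends(500, nes = c(bryophyte = 30, vascular = 15))
  f1 <- fit_nes_lineage(tr1)
  expect_lt(abs(f1$variance_power), 0.2)

  # recovery of distinct lineage means
  int <- f1$coefficients[f1$coefficients$term == "(Intercept)", ]
  expect_lt(abs(int$estimate - 30), 2 * int$se)
  eff <- f1$coefficients[f1$coefficients$term == "lineagevascular", ]
  expect_lt(abs(eff$estimate - (-15)), 2 * eff$se)

  expect_error(fit_nes_lineage(tr1[tr1$lineage == "bryophyte", ]),
               "both lineages")
})

test_that("lineage ratio helper reproduces the intercept arithmetic", {
  expect_equal(nes_lineage_ratio(30, -15), 2)
  set.seed(12)
  tr <- sim_trends(300, nes = c(bryophyte = 40, vascular = 20))
  f <- fit_nes_lineage(tr)
  cf <- coef(f)
  expect_equal(nes_lineage_ratio(f),
               cf[["(Intercept)"]] / (cf[["(Intercept)"]] + cf[["lineagevascular"]]))
})

test_that("full NES model prunes interactions in one step and keeps main effects", {
  dat <- small_scenario(n_plots = 300, seed = 23)
  sv <- build_surveys(dat$plots, dat$traits, dat$occurrences, verbose = FALSE)
  tr <- build_trends(sv, lapse_by_lineage(sv, dat$plots))
  res <- fit_nes_full(tr, dat$plots)
  expect_s3_class(res$full, "thermo_fit")
  expect_true(all(c("lineage", "elev_z", "land_use") %in% res$reduced$anova$term))
  # marginal F table covers every requested term of the full model
  expect_true(any(grepl(":", res$full$anova$term)))

  # when the truth has no interactions the reduced model drops them all and
  # agrees with a directly fitted main-effects model
  if (!any(grepl(":", res$reduced$anova$term))) {
    d <- tr[!is.na(tr$nes_m_per_decade), ]
    d$nes <- d$nes_m_per_decade
    i <- match(d$plot_id, dat$plots$plot_id)
    d$elev_z <- (dat$plots$elevation[i] - 514) / 100
    d$land_use <- droplevels(dat$plots$land_use[i])
    direct <- nlme::lme(nes ~ lineage + elev_z + land_use, random = ~ 1 | plot_id,
                        data = d, weights = nlme::varPower(form = ~ mean_n_species),
                        method = "REML",
                        control = nlme::lmeControl(returnObject = TRUE,
                                                   maxIter = 100, msMaxIter = 100))
    expect_equal(coef(res$reduced), nlme::fixef(direct), tolerance = 1e-6)
  }
})

test_that("an injected elevation effect on the NES is retained in the reduced model", {
  cfg <- scenario_config(n_plots = 400, seed = 29, nes_per_100m = 8)
  dat <- generate_scenario(cfg)
  sv <- build_surveys(dat$plots, dat$traits, dat$occurrences, verbose = FALSE)
  tr <- build_trends(sv, lapse_by_lineage(sv, dat$plots))
  res <- fit_nes_full(tr, dat$plots)
  an <- res$reduced$anova
  expect_lt(an$p_value[an$term == "elev_z"], 0.05)
})

test_that("Poisson count model recovers log-linear trends", {
  set.seed(31)
  n_plots <- 150; years <- seq(2001, 2021, 5)
  b <- rnorm(n_plots, 0, 0.3)
  d <- expand.grid(plot = seq_len(n_plots), year = years)
  d <- data.frame(plot_id = sprintf("q%03d", d$plot), year = d$year,
                  n = rpois(nrow(d), exp(log(8) + b[d$plot] +
                                           0.05 * (d$year - 2001))))
  fit <- fit_count_trend(d)
  sl <- fit$coefficients[fit$coefficients$term == "year", ]
  expect_lt(abs(sl$estimate - 0.05), 2 * sl$se)

  d0 <- d; d0$n <- rpois(nrow(d0), 6)
  f0 <- fit_count_trend(d0)
  sl0 <- f0$coefficients[f0$coefficients$term == "year", ]
  expect_lt(abs(sl0$estimate), 2 * sl0$se)

  dz <- d; dz$n <- 0L
  expect_s3_class(fit_count_trend(dz), "thermo_skip")
  dneg <- d; dneg$n[1] <- -1L
  expect_error(fit_count_trend(dneg), "non-negative")
})

test_that("life-strategy model contrasts longevity classes within a lineage", {
  dat <- small_scenario(n_plots = 250, seed = 37)
  sv_s <- build_surveys(dat$plots, dat$traits, dat$occurrences,
                        longevity = "short_lived", verbose = FALSE)
  sv_l <- build_surveys(dat$plots, dat$traits, dat$occurrences,
                        longevity = "long_lived", verbose = FALSE)
  lp <- lapse_by_lineage(build_surveys(dat$plots, dat$traits, dat$occurrences,
                                       verbose = FALSE), dat$plots)
  tr <- rbind(build_trends(sv_s, lp, subset = "short_lived"),
              build_trends(sv_l, lp, subset = "long_lived"))
  fit <- fit_life_strategy(tr, dat$plots, "vascular")
  cf <- fit$coefficients
  eff <- cf[cf$term == "subsetlong_lived", ]
  # generator gives both strategy groups identical dynamics
  expect_lt(abs(eff$estimate), 2.5 * eff$se)

  expect_error(fit_life_strategy(tr[tr$subset != "long_lived", ],
                                 dat$plots, "vascular"),
               "long_lived")
})
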