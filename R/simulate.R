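# Synthetic plot-network generator.
#
# Emulates the statistical structure of a national permanent-plot
# monitoring network: ~1146 plots along a 268-3060 m elevational gradient,
# three land-use types, five-yearly surveys of two plant lineages with
# distinct richness, ordinal species temperature values with partial
# availability, a CTI that declines with elevation, and a warming-driven
# upward CTI trend expressed as a target NES per stratum.

.default_land_use_rule <- function() {
  # zone x land-use probabilities; unmanaged open areas essentially alpine,
  # forests essentially absent from the alpine zone
  m <- rbind(
    colline   = c(0.52, 0.46, 0.02),
    montane   = c(0.45, 0.53, 0.02),
    subalpine = c(0.55, 0.42, 0.03),
    alpine    = c(0.42, 0.01, 0.57)
  )
  colnames(m) <- .land_use_levels
  m
}

.default_strategy_mix <- function() {
  rbind(bryophyte = c(short_lived = 0.45, long_lived = 0.45, other = 0.10),
        vascular  = c(short_lived = 0.20, long_lived = 0.55, other = 0.25))
}

#' Scenario configuration for the synthetic generator
#'
#' Collects every knob of the generator with validated defaults that mirror
#' the monitoring design the package targets: 1146 plots spanning
#' 268-3060 m, surveys every 5 years over 2001-2021, lineage richness means
#' 12.9 (bryophytes) and 27.3 (vascular plants) species per survey,
#' indicator-value missingness 0.26 / 0.04, elevational CTI lapses 0.082 /
#' 0.098 per 100 m, true NES 29.8 / 14.0 m per decade and a warming trend
#' of 0.42 degC per decade.
#'
#' @param n_plots number of permanent plots.
#' @param elevation_range (min, max) elevation in metres.
#' @param survey_years strictly increasing integer survey years.
#' @param land_use_rule zone x land-use probability matrix (rows sum to 1).
#' @param richness_mean named per-lineage mean species per survey.
#' @param sd_log_richness log-scale SD of the per-plot richness multiplier
#'   (between-plot richness heterogeneity).
#' @param pool_size per-lineage species-pool sizes.
#' @param lapse_true per-lineage magnitude of the latent CTI decline per
#'   100 m (> 0).
#' @param beta0 per-lineage latent CTI at 0 m elevation.
#' @param nes_true per-lineage true NES in metres per decade.
#' @param nes_land_use additive NES offsets (m/decade) per land-use type.
#' @param nes_per_100m additive NES increment per 100 m above 514 m.
#' @param sd_nes_plot SD (m/decade) of a plot-level NES deviation shared by
#'   both lineages of a plot.
#' @param sd_species_t SD of species temperature values around the latent
#'   community mean (selection width).
#' @param sd_plot_cti per-lineage SD of the plot-level CTI intercept.
#' @param persistence probability that a species present at one survey is
#'   present again at the next.
#' @param trait_missingness per-lineage fraction of pool species without a
#'   temperature value in the trait table.
#' @param strategy_mix lineage x (short_lived, long_lived, other)
#'   proportions of life-strategy codes.
#' @param infill when TRUE, richness grows over time and the growth is
#'   allocated to mesophilic/thermophilic species only (in-filling).
#' @param infill_rate extra expected species per year under infill.
#' @param warming_true warming trend of the temperature series, degC per
#'   decade.
#' @param temp_base mean annual temperature in the first year, degC.
#' @param sd_temp SD of the annual temperature noise, degC.
#' @param zone_thresholds passed to [assign_zone()].
#' @param seed integer RNG seed; identical seed, identical output.
#' @return object of class \code{scenario_config} (a validated list).
#' @export
scenario_config <- function(n_plots = 1146L,
                            elevation_range = c(268, 3060),
                            survey_years = c(2001L, 2006L, 2011L, 2016L, 2021L),
                            land_use_rule = .default_land_use_rule(),
                            richness_mean = c(bryophyte = 12.9, vascular = 27.3),
                            sd_log_richness = c(bryophyte = 0.6, vascular = 0.5),
                            pool_size = c(bryophyte = 546L, vascular = 1244L),
                            lapse_true = c(bryophyte = 0.082, vascular = 0.098),
                            beta0 = c(bryophyte = 4.37, vascular = 4.63),
                            nes_true = c(bryophyte = 29.8, vascular = 14.0),
                            nes_land_use = c(managed_grassland = 0, forest = 0,
                                             unmanaged_open = 0),
                            nes_per_100m = 0,
                            sd_nes_plot = 15,
                            sd_species_t = 0.5,
                            sd_plot_cti = c(bryophyte = 0.45, vascular = 0.28),
                            persistence = 0.8,
                            trait_missingness = c(bryophyte = 0.26, vascular = 0.04),
                            strategy_mix = .default_strategy_mix(),
                            infill = FALSE,
                            infill_rate = 0.1,
                            warming_true = 0.42,
                            temp_base = 5.5,
                            sd_temp = 0.48,
                            zone_thresholds = .default_zone_thresholds,
                            seed = 1L) {
  cfg <- list(n_plots = as.integer(n_plots), elevation_range = elevation_range,
              survey_years = as.integer(survey_years),
              land_use_rule = land_use_rule, richness_mean = richness_mean,
              sd_log_richness = sd_log_richness, pool_size = pool_size,
              lapse_true = lapse_true, beta0 = beta0, nes_true = nes_true,
              nes_land_use = nes_land_use, nes_per_100m = nes_per_100m,
              sd_nes_plot = sd_nes_plot, sd_species_t = sd_species_t,
              sd_plot_cti = sd_plot_cti, persistence = persistence,
              trait_missingness = trait_missingness,
              strategy_mix = strategy_mix, infill = isTRUE(infill),
              infill_rate = infill_rate, warming_true = warming_true,
              temp_base = temp_base, sd_temp = sd_temp,
              zone_thresholds = zone_thresholds, seed = as.integer(seed))
  if (cfg$n_plots < 1L) stop("n_plots must be >= 1")
  if (!length(cfg$survey_years)) stop("survey_years must not be empty")
  if (is.unsorted(cfg$survey_years, strictly = TRUE)) {
    stop("survey_years must be strictly increasing")
  }
  for (nm in c("richness_mean", "pool_size", "lapse_true", "beta0", "nes_true",
               "sd_log_richness", "sd_plot_cti", "trait_missingness")) {
    if (!all(.lineage_levels %in% names(cfg[[nm]]))) {
      stop(nm, " must be named for both lineages")
    }
  }
  if (any(cfg$richness_mean <= 0)) stop("richness_mean must be > 0")
  if (any(cfg$lapse_true <= 0)) stop("lapse_true must be > 0 (magnitude of the decline)")
  if (any(abs(rowSums(cfg$land_use_rule) - 1) > 1e-8)) {
    stop("land_use_rule rows must sum to 1")
  }
  if (cfg$persistence < 0 || cfg$persistence >= 1) {
    stop("persistence must be in [0, 1)")
  }
  if (cfg$sd_species_t <= 0) stop("sd_species_t must be > 0")
  class(cfg) <- "scenario_config"
  cfg
}

# Mean species temperature value selected from a pool with `counts` species
# per grid value, when selection weights are the normal density centred at
# latent mean mu_star with sd `sd`. Tabulated over mu_star and numerically
# inverted so that a target community mean is achieved exactly in
# expectation, including near the ends of the [1, 5] grid.
.cti_calibration <- function(counts, sd) {
  mu_star <- seq(-1.5, 7.5, by = 0.02)
  W <- outer(.temperature_grid, mu_star, function(g, m) dnorm(g - m, sd = sd)) * counts
  m <- colSums(W * .temperature_grid) / colSums(W)
  list(mu_star = mu_star, mean = m, lo = min(m), hi = max(m))
}

.calibration_invert <- function(cal, target) {
  clamped <- target < cal$lo | target > cal$hi
  target <- pmin(pmax(target, cal$lo), cal$hi)
  list(mu_star = approx(cal$mean, cal$mu_star, xout = target, rule = 2)$y,
       n_clamped = sum(clamped))
}

#' True quantities implied by a scenario configuration
#'
#' Pure function of the configuration, used by recovery tests: the true
#' per-stratum NES and CTI slope, the true lapse, the true warming slope,
#' and the qualitative direction of the affinity-class count trends.
#'
#' @param config a [scenario_config()].
#' @return list with \code{strata} (data frame: lineage, land_use,
#'   nes_true, slope_per_yr at 514 m), \code{lapse_true} (signed, per
#'   100 m), \code{warming_slope_per_yr}, \code{count_trend} (data frame of
#'   qualitative trends per affinity class).
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- expand.grid(lineage = .lineage_levels, land_use = .land_use_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$nes_true <- config$nes_true[grid$lineage] +
    config$nes_land_use[grid$land_use]
  grid$slope_per_yr <- grid$nes_true * config$lapse_true[grid$lineage] / 1000
  warm_trend <- if (config$infill) "increasing" else
    ifelse(any(grid$nes_true != 0), "increasing", "flat")
  count_trend <- data.frame(
    affinity = c("cryophilic", "mesophilic", "thermophilic"),
    trend = c(if (config$infill || all(grid$nes_true == 0)) "flat" else "decreasing",
              warm_trend, warm_trend),
    stringsAsFactors = FALSE
  )
  list(strata = grid,
       lapse_true = -config$lapse_true,
       warming_slope_per_yr = config$warming_true / 10,
       count_trend = count_trend)
}

#' Generate a synthetic monitoring scenario
#'
#' Draws a plot network, species traits, occurrence records and an annual
#' temperature series with the statistical structure the analysis assumes.
#'
#' The latent community mean for plot p, lineage l at survey year t is
#' \deqn{\mu(p,l,t) = \beta_0(l) - lapse(l)\,elev(p)/100 + b_p +
#'   slope(p,l)\,(t - t_1),}
#' with \eqn{slope = NES_{true} \times lapse / 1000}. Each pool species
#' carries a fixed temperature value; a community includes species
#' independently with probability proportional to the normal selection
#' weight of their value around \eqn{\mu}, scaled so the expected richness
#' matches the lineage mean times a per-plot lognormal multiplier. The
#' selection mean is numerically calibrated so the expected CTI equals
#' \eqn{\mu} exactly even near the grid edges; latent means outside the
#' attainable range are clamped and counted (attribute
#' \code{"clamped_fraction"}). Between consecutive surveys a present
#' species stays present with probability \code{persistence}; the
#' complementary entry probability is solved so the cross-sectional
#' inclusion probability stays exact at every survey, which keeps the CTI
#' trend unbiased while communities turn over gradually.
#'
#' @param config a [scenario_config()].
#' @return list with validated \code{plots}, \code{traits},
#'   \code{occurrences}, \code{temperature}, plus attributes
#'   \code{"truth"} (flattened [truth_table()] strata) and
#'   \code{"clamped_fraction"}. Identical seed gives identical output.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  years <- config$survey_years
  n <- config$n_plots

  # plot network
  elevation <- runif(n, config$elevation_range[1L], config$elevation_range[2L])
  zone <- assign_zone(elevation, config$zone_thresholds)
  land_use <- character(n)
  for (z in .zone_levels) {
    i <- which(zone == z)
    if (length(i)) {
      land_use[i] <- sample(.land_use_levels, length(i), replace = TRUE,
                            prob = config$land_use_rule[z, ])
    }
  }
  plots <- data.frame(plot_id = sprintf("P%04d", seq_len(n)),
                      elevation = elevation,
                      land_use = factor(land_use, levels = .land_use_levels),
                      zone = zone, stringsAsFactors = FALSE)

  # plot-level random structure shared across lineages
  nes_dev <- rnorm(n, 0, config$sd_nes_plot)

  traits_list <- list()
  occ_list <- list()
  clamped <- 0; draws <- 0

  for (l in .lineage_levels) {
    pool <- config$pool_size[[l]]
    sp_id <- sprintf("%s%04d", toupper(substr(l, 1, 1)), seq_len(pool))
    tval <- sample(.temperature_grid, pool, replace = TRUE)
    miss <- runif(pool) < config$trait_missingness[[l]]
    mix <- config$strategy_mix[l, ]
    grp <- sample(colnames(config$strategy_mix), pool, replace = TRUE, prob = mix)
    code <- character(pool)
    code[grp == "short_lived"] <- sample(
      if (l == "bryophyte") .bryo_short else .vasc_short,
      sum(grp == "short_lived"), replace = TRUE)
    code[grp == "long_lived"] <- sample(
      if (l == "bryophyte") .bryo_long else .vasc_long,
      sum(grp == "long_lived"), replace = TRUE)
    code[grp == "other"] <- if (l == "bryophyte") NA_character_ else
      sample(c("sss", "css", "rss", "crs"), sum(grp == "other"), replace = TRUE)
    traits_list[[l]] <- data.frame(
      species_id = sp_id, lineage = l,
      temperature_value = ifelse(miss, NA_real_, tval),
      strategy_code = code, stringsAsFactors = FALSE
    )

    counts <- tabulate(match(tval, .temperature_grid), length(.temperature_grid))
    cal <- .cti_calibration(counts, config$sd_species_t)

    b_plot <- rnorm(n, 0, config$sd_plot_cti[[l]])
    lam <- rlnorm(n, -config$sd_log_richness[[l]]^2 / 2, config$sd_log_richness[[l]])
    nes_p <- config$nes_true[[l]] + config$nes_land_use[land_use] +
      config$nes_per_100m * (elevation - 514) / 100 + nes_dev
    slope_p <- nes_p * config$lapse_true[[l]] / 1000
    mu0 <- config$beta0[[l]] - config$lapse_true[[l]] * elevation / 100 + b_plot

    warm <- tval >= 3 # infill growth goes to these species only
    prev_pi <- NULL; prev_inc <- NULL
    for (k in seq_along(years)) {
      mu <- mu0 + slope_p * (years[k] - years[1L])
      inv <- .calibration_invert(cal, mu)
      clamped <- clamped + inv$n_clamped; draws <- draws + n
      w <- outer(tval, inv$mu_star, function(g, m) dnorm(g - m, sd = config$sd_species_t))
      pi_k <- sweep(w, 2L, config$richness_mean[[l]] * lam / colSums(w), `*`)
      if (config$infill) {
        extra <- config$infill_rate * (years[k] - years[1L])
        if (extra > 0) {
          ww <- w * warm
          pi_add <- sweep(ww, 2L, extra * lam / colSums(ww), `*`)
          pi_k <- 1 - (1 - pi_k) * (1 - pi_add)
        }
      }
      pi_k <- pmin(pi_k, 1)
      if (is.null(prev_inc)) {
        inc <- matrix(runif(length(pi_k)) < pi_k, nrow = pool)
      } else {
        # marginal-preserving Markov persistence: stay prob = persistence,
        # entry prob solved so P(present at k) = pi_k exactly
        p_stay <- config$persistence
        denom <- pmax(1 - prev_pi, 1e-12)
        b_in <- (pi_k - p_stay * prev_pi) / denom
        low <- b_in < 0 # pi dropped faster than persistence allows
        stay <- matrix(p_stay, nrow = pool, ncol = n)
        if (any(low)) {
          stay[low] <- pi_k[low] / pmax(prev_pi[low], 1e-12)
          b_in[low] <- 0
        }
        b_in <- pmin(b_in, 1)
        u <- matrix(runif(length(pi_k)), nrow = pool)
        inc <- ifelse(prev_inc, u < stay, u < b_in)
      }
      prev_pi <- pi_k; prev_inc <- inc
      hit <- which(inc, arr.ind = TRUE)
      if (nrow(hit)) {
        occ_list[[paste(l, k)]] <- data.frame(
          plot_id = plots$plot_id[hit[, 2L]],
          year = years[k],
          species_id = sp_id[hit[, 1L]],
          stringsAsFactors = FALSE
        )
      }
    }
  }

  traits <- do.call(rbind, traits_list)
  occurrences <- do.call(rbind, occ_list)
  occurrences <- occurrences[order(occurrences$plot_id, occurrences$year,
                                   occurrences$species_id), , drop = FALSE]
  rownames(occurrences) <- NULL

  yr_seq <- seq(min(years), max(years))
  temperature <- data.frame(
    year = yr_seq,
    mean_temp = config$temp_base + config$warming_true / 10 * (yr_seq - yr_seq[1L]) +
      rnorm(length(yr_seq), 0, config$sd_temp)
  )

  truth <- truth_table(config)
  out <- list(plots = validate_plots(plots),
              traits = validate_traits(traits),
              occurrences = validate_occurrences(occurrences, plots),
              temperature = validate_temperature(temperature))
  attr(out, "truth") <- truth$strata
  attr(out, "clamped_fraction") <- clamped / draws
  attr(out, "config") <- config
  out
}
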