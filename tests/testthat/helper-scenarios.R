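# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default run stays fast.

tiny_tables <- function() {
  plots <- data.frame(
    plot_id = c("p1", "p2", "p3"),
    elevation_m = c(514, 1200, 3060),
    land_use = c("managed_grassland", "forest", "unmanaged_open")
  )
  traits <- data.frame(
    species_id = c("b1", "b2", "v1", "v2", "v3"),
    lineage = c("bryophyte", "bryophyte", "vascular", "vascular", "vascular"),
    temperature_value = c(2, 4, 1, 3, NA),
    strategy_code = c("colonist", "perennial", "rrr", "ccc", "crs")
  )
  occurrences <- data.frame(
    plot_id = c("p1", "p1", "p1", "p1", "p1", "p2", "p2", "p3"),
    year = c(2001, 2001, 2001, 2001, 2001, 2001, 2006, 2006),
    species_id = c("b1", "b2", "v1", "v2", "v3", "b1", "b1", "v2")
  )
  list(plots = plots, traits = traits, occurrences = occurrences)
}

write_tiny_csvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tt <- tiny_tables()
  paths <- list(plots = file.path(dir, "plots.csv"),
                traits = file.path(dir, "traits.csv"),
                occurrences = file.path(dir, "occurrences.csv"))
  write.csv(tt$plots, paths$plots, row.names = FALSE)
  write.csv(tt$traits, paths$traits, row.names = FALSE)
  write.csv(tt$occurrences, paths$occurrences, row.names = FALSE)
  paths
}

small_scenario <- function(n_plots = 120, seed = 7, ...) {
  generate_scenario(scenario_config(n_plots = n_plots, seed = seed, ...))
}

# simulated per-plot data for the CTI trend model: random intercept + linear
# year trend + noise
sim_cti_stratum <- function(n_plots, slope, years = seq(2001, 2021, 5),
                            sd_plot = 0.2, sd_res = 0.1, intercept = 3) {
  plot_id <- rep(sprintf("q%03d", seq_len(n_plots)), each = length(years))
  year <- rep(years, n_plots)
  b <- rep(rnorm(n_plots, 0, sd_plot), each = length(years))
  data.frame(plot_id = plot_id, year = year,
             cti = intercept + b + slope * (year - years[1]) +
               rnorm(length(year), 0, sd_res))
}

# simulated community-trend table for the NES models
sim_trends <- function(n_plots, nes = c(bryophyte = 30, vascular = 15),
                       sd_plot = 10, sd_res = c(bryophyte = 40, vascular = 40),
                       mean_nsp = NULL) {
  plot_id <- sprintf("q%03d", seq_len(n_plots))
  b <- rnorm(n_plots, 0, sd_plot)
  if (is.null(mean_nsp)) {
    mean_nsp <- list(bryophyte = pmax(2, rpois(n_plots, 10)),
                     vascular = pmax(2, rpois(n_plots, 25)))
  }
  do.call(rbind, lapply(names(nes), function(l) {
    data.frame(plot_id = plot_id, lineage = l, subset = "all",
               n_surveys_used = 5L,
               slope_per_yr = NA_real_,
               nes_m_per_decade = nes[[l]] + b + rnorm(n_plots, 0, sd_res[[l]]),
               mean_n_species = mean_nsp[[l]])
  }))
}
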