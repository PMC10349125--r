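# Full-run orchestration: simulate (or read) -> CTI -> trends -> models ->
# report, with a single seed, flat CSV outputs and a run manifest.

#' Run configuration for a full analysis
#'
#' Either paths to real input tables or a scenario configuration for the
#' synthetic generator must be given (not both unset).
#'
#' @param scenario a [scenario_config()], or NULL when reading real data.
#' @param paths named list/vector with \code{plots}, \code{traits},
#'   \code{occurrences} and optionally \code{temperature} CSV paths.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed governing every random draw of the run.
#' @param bootstrap_b bootstrap resamples for the CTI trend models.
#' @param min_plots minimum plot count per CTI stratum.
#' @param adiabatic adiabatic lapse-rate bounds, degC per 100 m.
#' @param life_strategy also fit the life-strategy models?
#' @param counts also fit the affinity-class count models?
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(scenario = NULL, paths = NULL, out_dir = "thermoshift-run",
                       seed = 1L, bootstrap_b = 1000L, min_plots = 14L,
                       adiabatic = c(0.5, 0.67), life_strategy = TRUE,
                       counts = TRUE) {
  if (is.null(scenario) && is.null(paths)) {
    stop("either a scenario config or input paths must be given")
  }
  if (!is.null(paths)) {
    need <- c("plots", "traits", "occurrences")
    missing <- setdiff(need, names(paths))
    if (length(missing)) {
      stop("paths must name: ", paste(missing, collapse = ", "))
    }
    for (p in unlist(paths[intersect(c(need, "temperature"), names(paths))])) {
      if (!file.exists(p)) stop("input file does not exist: '", p, "'")
    }
  }
  structure(list(scenario = scenario, paths = paths, out_dir = out_dir,
                 seed = as.integer(seed), bootstrap_b = as.integer(bootstrap_b),
                 min_plots = as.integer(min_plots), adiabatic = adiabatic,
                 life_strategy = isTRUE(life_strategy),
                 counts = isTRUE(counts)),
            class = "run_config")
}

.fit_coef_csv <- function(fit) {
  cbind(model_id = fit$model_id, fit$coefficients,
        variance_power = fit$variance_power, n_groups = fit$n_groups,
        n_obs = fit$n_obs, engine = fit$engine)
}

.fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)

#' Run the full thermophilisation pipeline
#'
#' Composes every stage into one reproducible run: data (simulated under
#' the run seed, or read from CSV), community surveys, lapse estimates,
#' per-community NES, the four model families, and a human-readable
#' report. All stage outputs are flat CSVs plus a YAML manifest capturing
#' configuration, seed and package version; rerunning with the same
#' configuration and seed reproduces the bundle byte for byte.
#'
#' @param config a [run_config()].
#' @param verbose emit stage messages?
#' @return invisibly, a list with the in-memory results (\code{tables},
#'   \code{analysis}, \code{cti_models}, \code{count_models},
#'   \code{life_strategy_models}, \code{stratum_means}, \code{files}).
#' @export
run_full_analysis <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, ...) if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage: data
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    sc$seed <- config$seed
    say("simulate", "generating scenario (%d plots, seed %d)", sc$n_plots, sc$seed)
    tables <- generate_scenario(sc)
  } else {
    say("read", "reading input tables")
    tables <- read_tables(config$paths[["plots"]], config$paths[["traits"]],
                          config$paths[["occurrences"]],
                          if ("temperature" %in% names(config$paths))
                            config$paths[["temperature"]] else NULL)
  }
  files <- write_tables(tables, config$out_dir)

  # stage: core analysis (surveys, lapse, NES, lineage + full models)
  say("cti", "building surveys and trends")
  ana <- thermophilisation(tables$plots, tables$traits, tables$occurrences,
                           tables$temperature, adiabatic = config$adiabatic,
                           verbose = verbose)
  files["surveys"] <- file.path(config$out_dir, "surveys.csv")
  write.csv(ana$surveys, files["surveys"], row.names = FALSE, quote = FALSE, na = "")
  files["trends"] <- file.path(config$out_dir, "trends.csv")
  write.csv(ana$trends, files["trends"], row.names = FALSE, quote = FALSE, na = "")
  lapse_df <- do.call(rbind, lapply(names(ana$lapse), function(l) {
    e <- ana$lapse[[l]]
    data.frame(lineage = l, lapse_per_100m = e$lapse_per_100m,
               se_per_100m = e$se_per_100m, r_squared = e$r_squared,
               p_value = e$p_value, n_plots = e$n_plots)
  }))
  files["lapse"] <- file.path(config$out_dir, "lapse.csv")
  write.csv(lapse_df, files["lapse"], row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(ana$isotherm)) {
    iso_df <- data.frame(warming_per_decade = ana$warming$warming_per_decade,
                         r_squared = ana$warming$r_squared,
                         p_value = ana$warming$p_value,
                         adiabatic_low = ana$isotherm$adiabatic[1L],
                         adiabatic_high = ana$isotherm$adiabatic[2L],
                         shift_low = ana$isotherm$shift_low,
                         shift_high = ana$isotherm$shift_high,
                         shift_low_rounded = ana$isotherm$shift_low_rounded,
                         shift_high_rounded = ana$isotherm$shift_high_rounded)
    files["isotherms"] <- file.path(config$out_dir, "isotherms.csv")
    write.csv(iso_df, files["isotherms"], row.names = FALSE, quote = FALSE, na = "")
  }

  # stage: CTI trend models per stratum
  say("models", "fitting per-stratum CTI trend models (B = %d)", config$bootstrap_b)
  cti_models <- cti_trend_by_stratum(ana$surveys, tables$plots,
                                     min_plots = config$min_plots,
                                     B = config$bootstrap_b)
  coef_rows <- lapply(cti_models$fits, .fit_coef_csv)

  # stage: count models (entire gradient, per lineage x affinity class)
  count_models <- list()
  if (config$counts) {
    say("models", "fitting affinity-class count models")
    for (l in .lineage_levels) {
      s <- ana$surveys[ana$surveys$lineage == l, ]
      if (!nrow(s)) next
      for (aff in c("cryo", "meso", "thermo")) {
        d <- data.frame(plot_id = s$plot_id, year = s$year,
                        n = s[[paste0("n_", aff)]])
        id <- paste("counts", l, aff, sep = ".")
        res <- fit_count_trend(d, model_id = id)
        count_models[[id]] <- res
        if (inherits(res, "thermo_fit")) coef_rows[[id]] <- .fit_coef_csv(res)
      }
    }
  }

  # stage: life-strategy models
  ls_models <- list()
  if (config$life_strategy) {
    say("models", "fitting life-strategy models")
    ls_trends <- do.call(rbind, lapply(c("short_lived", "long_lived"), function(s) {
      sv <- build_surveys(tables$plots, tables$traits, tables$occurrences,
                          longevity = s, verbose = FALSE)
      build_trends(sv, ana$lapse, subset = s)
    }))
    for (l in .lineage_levels) {
      id <- paste0("life_strategy.", l)
      res <- tryCatch(fit_life_strategy(ls_trends, tables$plots, l),
                      error = function(e) .skipped(id, conditionMessage(e)))
      ls_models[[id]] <- res
      if (inherits(res, "thermo_fit")) coef_rows[[id]] <- .fit_coef_csv(res)
    }
  }

  if (!is.null(ana$nes_lineage)) {
    coef_rows[["nes_lineage"]] <- .fit_coef_csv(ana$nes_lineage)
  }
  if (!is.null(ana$nes_full)) {
    coef_rows[["nes_full"]] <- .fit_coef_csv(ana$nes_full$full)
    coef_rows[["nes_reduced"]] <- .fit_coef_csv(ana$nes_full$reduced)
  }
  coefs <- do.call(rbind, coef_rows)
  files["model_coefficients"] <- file.path(config$out_dir, "model_coefficients.csv")
  write.csv(coefs, files["model_coefficients"], row.names = FALSE, quote = FALSE, na = "")
  files["skipped_strata"] <- file.path(config$out_dir, "skipped_strata.csv")
  write.csv(cti_models$skipped, files["skipped_strata"], row.names = FALSE,
            quote = FALSE, na = "")

  means <- nes_stratum_means(ana)
  files["nes_stratum_means"] <- file.path(config$out_dir, "nes_stratum_means.csv")
  write.csv(means, files["nes_stratum_means"], row.names = FALSE, quote = FALSE, na = "")

  # stage: report + manifest
  files["report"] <- file.path(config$out_dir, "report.md")
  writeLines(.render_report(config, tables, ana, cti_models, count_models,
                            ls_models, means), files["report"])
  manifest <- list(
    package = "thermoshift",
    version = as.character(packageVersion("thermoshift")),
    seed = config$seed,
    bootstrap_b = config$bootstrap_b,
    min_plots = config$min_plots,
    adiabatic = config$adiabatic,
    data_source = if (is.null(config$scenario)) "csv" else "synthetic",
    n_plots = nrow(tables$plots),
    survey_years = sort(unique(ana$surveys$year))
  )
  files["manifest"] <- file.path(config$out_dir, "manifest.yaml")
  writeLines(yaml::as.yaml(manifest), files["manifest"])
  say("report", "bundle written to %s", config$out_dir)

  invisible(list(tables = tables, analysis = ana, cti_models = cti_models,
                 count_models = count_models, life_strategy_models = ls_models,
                 stratum_means = means, files = files))
}

.render_report <- function(config, tables, ana, cti_models, count_models,
                           ls_models, means) {
  cf <- if (!is.null(ana$nes_lineage)) coef(ana$nes_lineage) else NULL
  out <- c(
    "# Thermophilisation run report", "",
    sprintf("- plots: %d; community surveys: %d; community trends: %d (excluded: %d)",
            nrow(tables$plots), nrow(ana$surveys), nrow(ana$trends),
            nrow(ana$exclusions)),
    sprintf("- seed: %d; data source: %s", config$seed,
            if (is.null(config$scenario)) "csv" else "synthetic"),
    "", "## Elevational CTI lapse", ""
  )
  for (l in names(ana$lapse)) {
    e <- ana$lapse[[l]]
    out <- c(out, sprintf("- %s: %s per 100 m (R^2 = %s, n = %d plots)", l,
                          .fmt(e$lapse_per_100m, 4), .fmt(e$r_squared, 2),
                          e$n_plots))
  }
  if (!is.null(cf)) {
    out <- c(out, "", "## NES lineage model", "",
             sprintf("- bryophyte mean NES (intercept): %s m/decade", .fmt(cf[[1L]], 1)),
             sprintf("- vascular minus bryophyte: %s m/decade", .fmt(cf[[2L]], 1)),
             sprintf("- bryophyte:vascular ratio: %s", .fmt(nes_lineage_ratio(ana$nes_lineage), 1)))
  }
  if (!is.null(ana$isotherm)) {
    out <- c(out, "", "## Isotherm shift", "",
             sprintf("- warming %s degC/decade -> expected shift %.0f to %.0f m/decade",
                     .fmt(ana$warming$warming_per_decade, 2),
                     ana$isotherm$shift_low_rounded, ana$isotherm$shift_high_rounded))
  }
  out <- c(out, "", "## Mean NES per stratum", "",
           "| lineage | land use | zone | n | mean | sd |",
           "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(means))) {
    out <- c(out, sprintf("| %s | %s | %s | %d | %s | %s |",
                          means$lineage[i], means$land_use[i], means$zone[i],
                          as.integer(means$n[i]), .fmt(means$mean[i], 1),
                          .fmt(means$sd[i], 1)))
  }
  out <- c(out, "", "## CTI trend models", "")
  for (id in names(cti_models$fits)) {
    f <- cti_models$fits[[id]]
    sl <- f$coefficients[f$coefficients$term == "year", ]
    ci_txt <- if (!is.null(f$ci)) sprintf(" [%s, %s]", .fmt(f$ci$lower, 4),
                                          .fmt(f$ci$upper, 4)) else ""
    out <- c(out, sprintf("- %s: slope %s CTI/yr%s (p = %s, %d plots)%s",
                          id, .fmt(sl$estimate, 4), ci_txt, .fmt(sl$p_value, 3),
                          f$n_groups,
                          if (length(f$notes)) paste0(" — ", f$notes[1L]) else ""))
  }
  if (nrow(cti_models$skipped)) {
    out <- c(out, "", "Skipped strata:", "")
    for (i in seq_len(nrow(cti_models$skipped))) {
      out <- c(out, sprintf("- %s: %s", cti_models$skipped$model_id[i],
                            cti_models$skipped$reason[i]))
    }
  }
  if (length(count_models)) {
    out <- c(out, "", "## Affinity-class count models (log-scale trend per year)", "")
    for (id in names(count_models)) {
      f <- count_models[[id]]
      if (inherits(f, "thermo_skip")) {
        out <- c(out, sprintf("- %s: skipped (%s)", id, f$reason)); next
      }
      sl <- f$coefficients[f$coefficients$term == "year", ]
      out <- c(out, sprintf("- %s: %s (SE %s, p = %s)", id, .fmt(sl$estimate, 4),
                            .fmt(sl$se, 4), .fmt(sl$p_value, 3)))
    }
  }
  if (length(ls_models)) {
    out <- c(out, "", "## Life-strategy models", "")
    for (id in names(ls_models)) {
      f <- ls_models[[id]]
      if (inherits(f, "thermo_skip")) {
        out <- c(out, sprintf("- %s: skipped (%s)", id, f$reason)); next
      }
      sl <- f$coefficients[f$coefficients$term == "subsetlong_lived", ]
      out <- c(out, sprintf("- %s: long vs short-lived contrast %s m/decade (SE %s, p = %s)",
                            id, .fmt(sl$estimate, 1), .fmt(sl$se, 1),
                            .fmt(sl$p_value, 3)))
    }
  }
  warn <- attr(tables, "clamped_fraction")
  if (!is.null(warn)) {
    out <- c(out, "", sprintf("Generator note: %.2f%% of latent community means clamped to the attainable CTI range.",
                              100 * warn))
  }
  out
}
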