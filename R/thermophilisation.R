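# Main model-fitting interface: one call from the three input tables to
# surveys, lapses, per-community NES, the lineage and full NES models and
# the isotherm expectation.

#' Thermophilisation analysis of a plot network
#'
#' Runs the core analysis chain on validated (or raw) input tables:
#' assembles per-survey communities and their CTI, estimates the
#' elevational CTI lapse per lineage, converts per-plot CTI trends into
#' notional elevation shifts (NES, m/decade), fits the NES lineage model
#' and, when both lineages and covariates allow, the NES full model with
#' single-step interaction pruning. If an annual temperature series is
#' supplied, the warming rate and the expected isotherm shift are computed
#' for comparison with the fitted NES.
#'
#' @param plots,traits,occurrences input tables (data frames or validated
#'   record sets; see [read_tables()]).
#' @param temperature optional annual temperature series.
#' @param adiabatic adiabatic lapse-rate bounds, degC per 100 m.
#' @param min_surveys minimum surveys with a defined CTI per community.
#' @param fit_full also fit the NES full model?
#' @param var_power use the power variance function in the NES models?
#' @param verbose emit progress messages?
#' @return object of class \code{thermophilisation}: list with
#'   \code{surveys}, \code{lapse} (per lineage), \code{trends},
#'   \code{nes_lineage}, \code{nes_full} (list full/reduced or NULL),
#'   \code{warming}, \code{isotherm}, \code{exclusions}, \code{call}.
#' @examples
#' \donttest{
#' cfg <- scenario_config(n_plots = 150, seed = 7)
#' dat <- generate_scenario(cfg)
#' fit <- thermophilisation(dat$plots, dat$traits, dat$occurrences,
#'                          dat$temperature, verbose = FALSE)
#' summary(fit)
#' }
#' @export
thermophilisation <- function(plots, traits, occurrences, temperature = NULL,
                              adiabatic = c(0.5, 0.67), min_surveys = 2L,
                              fit_full = TRUE, var_power = TRUE,
                              verbose = TRUE) {
  cl <- match.call()
  plots <- validate_plots(plots)
  traits <- validate_traits(traits)
  occurrences <- validate_occurrences(occurrences, plots)

  surveys <- build_surveys(plots, traits, occurrences, verbose = verbose)
  lapse <- lapse_by_lineage(surveys, plots)
  trends <- build_trends(surveys, lapse, min_surveys = min_surveys)
  both <- length(unique(as.character(trends$lineage))) == 2L

  nes_lineage <- if (both) fit_nes_lineage(trends, var_power = var_power) else NULL
  nes_full <- if (both && fit_full) {
    fit_nes_full(trends, plots, var_power = var_power)
  } else NULL

  warming <- NULL; isotherm <- NULL
  if (!is.null(temperature)) {
    warming <- estimate_warming(temperature)
    isotherm <- isotherm_shift(warming$warming_per_decade, adiabatic)
  }

  structure(list(surveys = surveys, lapse = lapse, trends = trends,
                 nes_lineage = nes_lineage, nes_full = nes_full,
                 warming = warming, isotherm = isotherm,
                 exclusions = attr(trends, "exclusions"),
                 plots = plots, call = cl),
            class = "thermophilisation")
}

#' @export
print.thermophilisation <- function(x, ...) {
  cat("Thermophilisation analysis\n")
  cat(sprintf("  %d plots, %d community surveys, %d community trends (%d excluded)\n",
              length(unique(x$surveys$plot_id)), nrow(x$surveys),
              nrow(x$trends), nrow(x$exclusions)))
  for (l in names(x$lapse)) {
    cat(sprintf("  %s lapse: %.3f CTI per 100 m (R^2 = %.2f)\n",
                l, x$lapse[[l]]$lapse_per_100m, x$lapse[[l]]$r_squared))
  }
  if (!is.null(x$nes_lineage)) {
    cf <- coef(x$nes_lineage)
    cat(sprintf("  mean NES: bryophytes %.1f, vascular plants %.1f m/decade (ratio %.1f)\n",
                cf[["(Intercept)"]], cf[["(Intercept)"]] + cf[["lineagevascular"]],
                nes_lineage_ratio(x$nes_lineage)))
  }
  if (!is.null(x$isotherm)) {
    cat(sprintf("  expected isotherm shift: %.0f to %.0f m/decade\n",
                x$isotherm$shift_low_rounded, x$isotherm$shift_high_rounded))
  }
  invisible(x)
}

#' @export
summary.thermophilisation <- function(object, ...) {
  structure(list(object = object), class = "summary.thermophilisation")
}

#' @export
print.summary.thermophilisation <- function(x, ...) {
  o <- x$object
  print(o)
  cat("\nElevational CTI lapse per lineage:\n")
  for (l in names(o$lapse)) print(o$lapse[[l]])
  if (!is.null(o$nes_lineage)) {
    cat("\nNES lineage model:\n")
    print(o$nes_lineage)
  }
  if (!is.null(o$nes_full)) {
    cat("\nNES full model, marginal F-tests:\n")
    print(format(o$nes_full$full$anova, digits = 3))
    cat("\nNES reduced model (non-significant interactions removed):\n")
    print(o$nes_full$reduced)
  }
  if (!is.null(o$warming)) {
    cat(sprintf("\nWarming: %.2f degC/decade (R^2 = %.4f, p = %.3g)\n",
                o$warming$warming_per_decade, o$warming$r_squared,
                o$warming$p_value))
    print(o$isotherm)
  }
  invisible(x)
}

#' @export
coef.thermophilisation <- function(object, ...) {
  if (is.null(object$nes_lineage)) return(NULL)
  coef(object$nes_lineage)
}

#' Mean NES per lineage, land-use type and elevational zone
#'
#' The descriptive stratum summary accompanying the models: mean, SD and a
#' normal-theory 95% interval of the per-community NES in every stratum
#' with at least one trend.
#'
#' @param x a \code{thermophilisation} object.
#' @param by stratification columns, any of "lineage", "land_use", "zone".
#' @return data frame of stratum means.
#' @export
nes_stratum_means <- function(x, by = c("lineage", "land_use", "zone")) {
  stopifnot(inherits(x, "thermophilisation"))
  tr <- x$trends
  i <- match(tr$plot_id, x$plots$plot_id)
  tr$land_use <- x$plots$land_use[i]
  tr$zone <- x$plots$zone[i]
  key <- interaction(tr[by], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(tr$nes_m_per_decade, key), function(v) {
    c(n = length(v), mean = mean(v), sd = sd(v),
      se = sd(v) / sqrt(length(v)))
  })
  lab <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
  out <- data.frame(lab, do.call(rbind, agg), row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[seq_along(by)] <- by
  out$lower <- out$mean - qnorm(0.975) * out$se
  out$upper <- out$mean + qnorm(0.975) * out$se
  out
}

#' @describeIn thermophilisation plot mean CTI per survey year and lineage
#'   with the fitted linear trend (base graphics).
#' @param x a \code{thermophilisation} object.
#' @param ... ignored.
#' @export
plot.thermophilisation <- function(x, ...) {
  s <- x$surveys[!is.na(x$surveys$cti), ]
  lins <- unique(as.character(s$lineage))
  op <- par(mfrow = c(1, length(lins)), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (l in lins) {
    d <- s[s$lineage == l, ]
    m <- tapply(d$cti, d$year, mean)
    yrs <- as.integer(names(m))
    plot(yrs, m, xlab = "survey year", ylab = "mean CTI", main = l,
         pch = 19)
    fit <- lm(cti ~ year, data = d)
    lines(yrs, predict(fit, data.frame(year = yrs)), lty = 2)
  }
  invisible(x)
}
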