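# Mixed-effects model families: CTI trend models with cluster-bootstrap
# intervals, NES models with a power variance function, Poisson models for
# affinity-class species counts, and the life-strategy contrast.

.new_thermo_fit <- function(model_id, formula_str, coefficients, anova = NULL,
                            ci = NULL, variance_power = NA_real_,
                            n_groups = NA_integer_, n_obs = NA_integer_,
                            converged = TRUE, engine = NA_character_,
                            notes = character(0), fit = NULL) {
  structure(list(model_id = model_id, formula = formula_str,
                 coefficients = coefficients, anova = anova, ci = ci,
                 variance_power = variance_power, n_groups = n_groups,
                 n_obs = n_obs, converged = converged, engine = engine,
                 notes = notes, fit = fit),
            class = "thermo_fit")
}

.skipped <- function(model_id, reason) {
  structure(list(model_id = model_id, reason = reason), class = "thermo_skip")
}

#' @export
print.thermo_skip <- function(x, ...) {
  cat(sprintf("<skipped model %s: %s>\n", x$model_id, x$reason))
  invisible(x)
}

#' @export
print.thermo_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Model %s (%s): %s\n", x$model_id, x$engine, x$formula))
  cat(sprintf("  %d observations, %d groups%s\n", x$n_obs, x$n_groups,
              if (!is.na(x$variance_power))
                sprintf(", variance power delta = %.3f", x$variance_power) else ""))
  print(format(x$coefficients, digits = digits), ...)
  if (!is.null(x$ci)) {
    cat(sprintf("  %s CI:\n", x$ci$method[1L]))
    print(format(x$ci, digits = digits))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.thermo_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

.lme_coef_table <- function(fit) {
  tt <- summary(fit)$tTable
  data.frame(term = rownames(tt), estimate = tt[, "Value"],
             se = tt[, "Std.Error"], df = tt[, "DF"],
             statistic = tt[, "t-value"], p_value = tt[, "p-value"],
             row.names = NULL, stringsAsFactors = FALSE)
}

.lme_wald_ci <- function(fit, level = 0.95) {
  iv <- tryCatch(intervals(fit, level = level, which = "fixed")$fixed,
                 error = function(e) NULL)
  if (!is.null(iv)) {
    return(data.frame(term = rownames(iv), lower = iv[, "lower"],
                      upper = iv[, "upper"], method = "wald",
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  tt <- summary(fit)$tTable
  q <- qt(1 - (1 - level) / 2, tt[, "DF"])
  data.frame(term = rownames(tt), lower = tt[, "Value"] - q * tt[, "Std.Error"],
             upper = tt[, "Value"] + q * tt[, "Std.Error"], method = "wald",
             row.names = NULL, stringsAsFactors = FALSE)
}

.var_power <- function(fit) {
  vs <- fit$modelStruct$varStruct
  if (is.null(vs)) return(NA_real_)
  unname(coef(vs, unconstrained = FALSE))
}

#' CTI trend model for one stratum
#'
#' Linear mixed model CTI ~ year with a random intercept per plot, fitted
#' to one lineage x zone x land-use stratum, with a nonparametric cluster
#' bootstrap (plots resampled with replacement) for the confidence interval
#' of the year coefficient. Strata with fewer plots than \code{min_plots}
#' are not fitted; a skip record is returned instead. When the mixed fit
#' fails (e.g. zero between-plot variance making the random intercept
#' unidentifiable), the model falls back to a plain linear regression and
#' says so in its notes.
#'
#' @param data data frame with columns plot_id, year, cti (NA cti dropped).
#' @param min_plots minimum number of plots with a usable CTI (default 14).
#' @param B number of bootstrap resamples (default 1000; 0 disables the
#'   bootstrap CI).
#' @param level confidence level.
#' @param engine "auto" (lme with lm fallback), "lme" or "lm".
#' @param model_id label for the fit.
#' @return a \code{thermo_fit}, or a \code{thermo_skip} when the stratum is
#'   too small.
#' @export
fit_cti_trend <- function(data, min_plots = 14L, B = 1000L, level = 0.95,
                          engine = c("auto", "lme", "lm"),
                          model_id = "cti_trend") {
  engine <- match.arg(engine)
  d <- data[!is.na(data$cti), c("plot_id", "year", "cti")]
  n_plots <- length(unique(d$plot_id))
  if (n_plots < min_plots) {
    return(.skipped(model_id, sprintf("only %d plots (< %d)", n_plots, min_plots)))
  }
  fit1 <- .fit_year_slope(d, engine)
  ci <- NULL
  if (B > 0L) {
    ids <- unique(d$plot_id)
    blocks <- split(seq_len(nrow(d)), d$plot_id)
    slopes <- vapply(seq_len(B), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      rows <- unlist(blocks[take], use.names = FALSE)
      db <- d[rows, ]
      db$plot_id <- rep(seq_along(take), lengths(blocks[take]))
      fb <- tryCatch(.fit_year_slope(db, engine), error = function(e) NULL)
      if (is.null(fb)) NA_real_ else fb$slope
    }, numeric(1))
    qs <- quantile(slopes, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
    ci <- data.frame(term = "year", lower = unname(qs[1L]), upper = unname(qs[2L]),
                     method = "bootstrap", stringsAsFactors = FALSE)
  }
  .new_thermo_fit(model_id, "cti ~ year + (1 | plot_id)", fit1$coefficients,
                  ci = ci, n_groups = n_plots, n_obs = nrow(d),
                  engine = fit1$engine, notes = fit1$notes, fit = fit1$fit)
}

# year-slope engine shared by fit_cti_trend and its bootstrap
.fit_year_slope <- function(d, engine) {
  notes <- character(0)
  if (engine %in% c("auto", "lme")) {
    fit <- tryCatch(
      lme(cti ~ year, random = ~ 1 | plot_id, data = d, method = "REML",
          control = lmeControl(returnObject = TRUE)),
      error = function(e) e
    )
    if (!inherits(fit, "error")) {
      tab <- .lme_coef_table(fit)
      return(list(coefficients = tab, slope = tab$estimate[tab$term == "year"],
                  engine = "lme", notes = notes, fit = fit))
    }
    if (engine == "lme") stop(conditionMessage(fit))
    notes <- sprintf("mixed fit failed (%s); ordinary regression fallback",
                     conditionMessage(fit))
  }
  fit <- lm(cti ~ year, data = d)
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                    df = fit$df.residual, statistic = sm[, 3L],
                    p_value = sm[, 4L], row.names = NULL,
                    stringsAsFactors = FALSE)
  list(coefficients = tab, slope = tab$estimate[tab$term == "year"],
       engine = "lm", notes = notes, fit = fit)
}

#' CTI trend models for every adequately sampled stratum
#'
#' Applies [fit_cti_trend()] to each lineage x elevational zone x land-use
#' combination; combinations below the minimum plot count are skipped and
#' reported.
#'
#' @param surveys output of [build_surveys()].
#' @param plots validated plot table.
#' @inheritParams fit_cti_trend
#' @return list with \code{fits} (named list of \code{thermo_fit}) and
#'   \code{skipped} (data frame with stratum and reason).
#' @export
cti_trend_by_stratum <- function(surveys, plots, min_plots = 14L, B = 1000L,
                                 engine = "auto") {
  plots <- validate_plots(plots)
  surveys$zone <- plots$zone[match(surveys$plot_id, plots$plot_id)]
  surveys$land_use <- plots$land_use[match(surveys$plot_id, plots$plot_id)]
  fits <- list(); skipped <- NULL
  for (l in .lineage_levels) for (z in .zone_levels) for (u in .land_use_levels) {
    d <- surveys[surveys$lineage == l & surveys$zone == z &
                   surveys$land_use == u & !is.na(surveys$cti), , drop = FALSE]
    id <- paste(l, z, u, sep = ".")
    if (!nrow(d)) next
    res <- fit_cti_trend(d, min_plots = min_plots, B = B, engine = engine,
                         model_id = id)
    if (inherits(res, "thermo_skip")) {
      skipped <- rbind(skipped, data.frame(
        model_id = id, lineage = l, zone = z, land_use = u,
        reason = res$reason, stringsAsFactors = FALSE
      ))
    } else {
      fits[[id]] <- res
    }
  }
  list(fits = fits,
       skipped = if (is.null(skipped))
         data.frame(model_id = character(0), lineage = character(0),
                    zone = character(0), land_use = character(0),
                    reason = character(0)) else skipped)
}

.nes_lme <- function(formula, data, model_id, var_power = TRUE) {
  wts <- if (var_power) varPower(form = ~ mean_n_species) else NULL
  notes <- character(0)
  fit <- tryCatch(
    lme(formula, random = ~ 1 | plot_id, data = data, weights = wts,
        method = "REML", control = lmeControl(returnObject = TRUE,
                                              maxIter = 100, msMaxIter = 100)),
    error = function(e) e
  )
  if (inherits(fit, "error") && var_power) {
    notes <- c(notes, sprintf("power variance fit failed (%s); refitted without it",
                              conditionMessage(fit)))
    fit <- lme(formula, random = ~ 1 | plot_id, data = data, method = "REML",
               control = lmeControl(returnObject = TRUE))
  } else if (inherits(fit, "error")) {
    stop(conditionMessage(fit))
  }
  list(fit = fit, notes = notes)
}

#' NES lineage model
#'
#' Linear mixed model NES ~ lineage with a random intercept per plot and a
#' power variance function of the mean number of species contributing to
#' the CTI, quantifying the average NES of bryophyte communities (the
#' intercept) and the vascular-minus-bryophyte difference (the lineage
#' effect).
#'
#' @param trends output of [build_trends()] containing both lineages.
#' @param var_power model residual SD as sigma * |mean_n_species|^delta?
#' @return a \code{thermo_fit} whose \code{variance_power} is the estimated
#'   exponent delta.
#' @export
fit_nes_lineage <- function(trends, var_power = TRUE) {
  d <- trends[!is.na(trends$nes_m_per_decade), , drop = FALSE]
  if (length(unique(as.character(d$lineage))) < 2L) {
    stop("NES lineage model needs trends for both lineages")
  }
  d$lineage <- factor(as.character(d$lineage), levels = .lineage_levels)
  d$nes <- d$nes_m_per_decade
  res <- .nes_lme(nes ~ lineage, d, "nes_lineage", var_power)
  .new_thermo_fit("nes_lineage", "nes ~ lineage + (1 | plot_id), varPower(~mean_n_species)",
                  .lme_coef_table(res$fit), ci = .lme_wald_ci(res$fit),
                  variance_power = .var_power(res$fit),
                  n_groups = length(unique(d$plot_id)), n_obs = nrow(d),
                  engine = "lme", notes = res$notes, fit = res$fit)
}

#' Bryophyte-to-vascular mean NES ratio
#'
#' Ratio implied by the lineage-model coefficients: intercept (bryophyte
#' mean NES) over intercept + lineage effect (vascular mean NES).
#'
#' @param intercept bryophyte mean NES (m/decade), or a \code{thermo_fit}
#'   from [fit_nes_lineage()].
#' @param lineage_effect vascular-minus-bryophyte difference (m/decade);
#'   ignored when a fit is supplied.
#' @return scalar ratio.
#' @examples
#' nes_lineage_ratio(29.8, -15.8) # about 2.1
#' @export
nes_lineage_ratio <- function(intercept, lineage_effect = NULL) {
  if (inherits(intercept, "thermo_fit")) {
    cf <- coef(intercept)
    lineage_effect <- cf[["lineagevascular"]]
    intercept <- cf[["(Intercept)"]]
  }
  intercept / (intercept + lineage_effect)
}

# marginal F-tests for an lme fit (conditional on the estimated variance
# structure; between-within denominator df)
.marginal_anova <- function(fit) {
  a <- anova(fit, type = "marginal")
  data.frame(term = rownames(a), num_df = a$numDF, den_df = a$denDF,
             f_value = a$`F-value`, p_value = a$`p-value`,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' NES full model with single-step interaction pruning
#'
#' Fits NES ~ lineage x elevation x land use (all two- and three-way
#' interactions) with a plot random intercept and a power variance
#' function, computes marginal F-tests, then refits once without every
#' interaction whose F-test is non-significant (p >= alpha). Main effects
#' are always retained, and an interaction kept in the reduced model keeps
#' its lower-order margins. Elevation enters centred at 514 m and scaled to
#' 100 m units, so the intercept is the prediction for a bryophyte
#' community in managed grassland at 514 m a.s.l. and the elevation effect
#' is per 100 m. If the full fixed-effects design is rank deficient (e.g.
#' an empty lineage x zone x land-use cell), the three-way interaction is
#' dropped with a note before fitting.
#'
#' @param trends output of [build_trends()].
#' @param plots validated plot table.
#' @param alpha significance threshold for keeping interactions.
#' @param center_elevation metres subtracted from elevation before scaling
#'   (default 514).
#' @param var_power use the power variance function?
#' @return list with elements \code{full} and \code{reduced}, both
#'   \code{thermo_fit}s; the reduced fit's notes name the dropped terms.
#' @export
fit_nes_full <- function(trends, plots, alpha = 0.05, center_elevation = 514,
                         var_power = TRUE) {
  plots <- validate_plots(plots)
  d <- trends[!is.na(trends$nes_m_per_decade), , drop = FALSE]
  d$lineage <- factor(as.character(d$lineage), levels = .lineage_levels)
  d$nes <- d$nes_m_per_decade
  i <- match(d$plot_id, plots$plot_id)
  d$elev_z <- (plots$elevation[i] - center_elevation) / 100
  d$land_use <- droplevels(plots$land_use[i])

  full_terms <- c("lineage", "elev_z", "land_use",
                  "lineage:elev_z", "lineage:land_use", "elev_z:land_use",
                  "lineage:elev_z:land_use")
  notes <- character(0)
  X <- stats::model.matrix(stats::reformulate(full_terms), d)
  if (qr(X)$rank < ncol(X)) {
    notes <- c(notes, "rank-deficient full design; three-way interaction dropped")
    full_terms <- setdiff(full_terms, "lineage:elev_z:land_use")
  }
  res_full <- .nes_lme(stats::reformulate(full_terms, response = "nes"), d,
                       "nes_full", var_power)
  an <- .marginal_anova(res_full$fit)
  full_fit <- .new_thermo_fit(
    "nes_full", paste("nes ~", paste(full_terms, collapse = " + "),
                      "+ (1 | plot_id), varPower(~mean_n_species)"),
    .lme_coef_table(res_full$fit), anova = an, ci = .lme_wald_ci(res_full$fit),
    variance_power = .var_power(res_full$fit),
    n_groups = length(unique(d$plot_id)), n_obs = nrow(d), engine = "lme",
    notes = c(notes, res_full$notes), fit = res_full$fit
  )

  inter <- grep(":", an$term, value = TRUE)
  drop <- inter[an$p_value[match(inter, an$term)] >= alpha]
  keep_inter <- setdiff(inter, drop)
  # hierarchy: a retained three-way interaction keeps its two-way margins
  if ("lineage:elev_z:land_use" %in% keep_inter) {
    keep_inter <- union(keep_inter,
                        c("lineage:elev_z", "lineage:land_use", "elev_z:land_use"))
  }
  red_terms <- c("lineage", "elev_z", "land_use", keep_inter)
  res_red <- .nes_lme(stats::reformulate(red_terms, response = "nes"), d,
                      "nes_reduced", var_power)
  red_fit <- .new_thermo_fit(
    "nes_reduced", paste("nes ~", paste(red_terms, collapse = " + "),
                         "+ (1 | plot_id), varPower(~mean_n_species)"),
    .lme_coef_table(res_red$fit), anova = .marginal_anova(res_red$fit),
    ci = .lme_wald_ci(res_red$fit), variance_power = .var_power(res_red$fit),
    n_groups = length(unique(d$plot_id)), n_obs = nrow(d), engine = "lme",
    notes = c(res_red$notes,
              if (length(drop)) paste("dropped non-significant interaction(s):",
                                      paste(drop, collapse = ", "))
              else "no interaction dropped"),
    fit = res_red$fit
  )
  list(full = full_fit, reduced = red_fit)
}

#' Poisson trend model for affinity-class species counts
#'
#' Generalised linear mixed model with Poisson error and log link: number
#' of species ~ year with a random intercept per plot. Year is centred at
#' the first survey year, which changes only the intercept; the trend
#' coefficient is per year on the log scale.
#'
#' @param data data frame with columns plot_id, year, n (non-negative
#'   integer counts).
#' @param model_id label for the fit.
#' @return a \code{thermo_fit}, or a \code{thermo_skip} when all counts are
#'   zero.
#' @export
fit_count_trend <- function(data, model_id = "count_trend") {
  d <- data[!is.na(data$n), c("plot_id", "year", "n")]
  if (any(d$n < 0) || any(d$n != round(d$n))) {
    stop("counts must be non-negative integers")
  }
  if (all(d$n == 0)) return(.skipped(model_id, "all counts are zero"))
  # centre at the first survey year and fit on the decade scale for
  # conditioning; the reported trend is converted back to per-year
  d$year_dec <- (d$year - min(d$year)) / 10
  notes <- character(0)
  fit <- withCallingHandlers(
    glmer(n ~ year_dec + (1 | plot_id), data = d, family = "poisson",
          control = glmerControl(optimizer = "bobyqa",
                                 check.conv.singular = "ignore")),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  scale <- ifelse(rownames(sm) == "year_dec", 10, 1)
  tab <- data.frame(term = sub("year_dec", "year", rownames(sm)),
                    estimate = sm[, 1L] / scale, se = sm[, 2L] / scale,
                    df = NA_real_, statistic = sm[, 3L], p_value = sm[, 4L],
                    row.names = NULL, stringsAsFactors = FALSE)
  q <- qnorm(0.975)
  ci <- data.frame(term = tab$term, lower = tab$estimate - q * tab$se,
                   upper = tab$estimate + q * tab$se, method = "wald",
                   stringsAsFactors = FALSE)
  .new_thermo_fit(model_id, "n ~ year + (1 | plot_id), poisson(log)", tab,
                  ci = ci, n_groups = length(unique(d$plot_id)),
                  n_obs = nrow(d), engine = "glmer",
                  converged = !any(grepl("failed to converge", notes)),
                  notes = notes, fit = fit)
}

#' Life-strategy NES model for one lineage
#'
#' Linear mixed model NES ~ longevity class + elevation + land use with a
#' plot random intercept and a power variance function, fitted separately
#' per lineage to trends computed on the short-lived and long-lived species
#' subsets. The longevity coefficient is the long- vs short-lived
#' contrast.
#'
#' @param trends row-bound output of [build_trends()] for the two
#'   longevity subsets (column \code{subset} holding "short_lived" /
#'   "long_lived").
#' @param plots validated plot table (must carry land_use).
#' @param lineage "bryophyte" or "vascular".
#' @param center_elevation as in [fit_nes_full()].
#' @param var_power use the power variance function?
#' @return a \code{thermo_fit}.
#' @export
fit_life_strategy <- function(trends, plots, lineage, center_elevation = 514,
                              var_power = TRUE) {
  plots <- validate_plots(plots)
  d <- trends[as.character(trends$lineage) == lineage &
                !is.na(trends$nes_m_per_decade), , drop = FALSE]
  for (s in c("short_lived", "long_lived")) {
    if (!any(d$subset == s)) {
      stop(sprintf("no %s trends for lineage %s", s, lineage))
    }
  }
  d$subset <- factor(d$subset, levels = c("short_lived", "long_lived"))
  d$nes <- d$nes_m_per_decade
  i <- match(d$plot_id, plots$plot_id)
  d$elev_z <- (plots$elevation[i] - center_elevation) / 100
  d$land_use <- droplevels(plots$land_use[i])
  res <- .nes_lme(nes ~ subset + elev_z + land_use, d,
                  paste0("life_strategy_", lineage), var_power)
  .new_thermo_fit(paste0("life_strategy_", lineage),
                  "nes ~ longevity + elev_z + land_use + (1 | plot_id), varPower(~mean_n_species)",
                  .lme_coef_table(res$fit), ci = .lme_wald_ci(res$fit),
                  variance_power = .var_power(res$fit),
                  n_groups = length(unique(d$plot_id)), n_obs = nrow(d),
                  engine = "lme", notes = res$notes, fit = res$fit)
}
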