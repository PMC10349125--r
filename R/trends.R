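# Thermophilisation statistics: per-plot CTI slopes, the elevational CTI
# lapse, the notional elevation shift (NES) and the isotherm-shift
# expectation.

# closed-form OLS slope; x and y without NA, length >= 2, var(x) > 0
.ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Per-plot thermophilisation rate
#'
#' Ordinary least-squares slope of CTI against survey year for one
#' community: the average change in CTI per year.
#'
#' @param year integer survey years.
#' @param cti CTI values (NA allowed; dropped).
#' @return slope in CTI units per year, or NA when fewer than two usable
#'   surveys (or a single distinct year) remain.
#' @examples
#' fit_plot_trend(c(2001, 2006, 2011), c(3.00, 3.05, 3.10)) # 0.01
#' @export
fit_plot_trend <- function(year, cti) {
  ok <- !is.na(year) & !is.na(cti)
  year <- year[ok]; cti <- cti[ok]
  if (length(year) < 2L || length(unique(year)) < 2L) return(NA_real_)
  .ols_slope(year, cti)
}

#' Elevational CTI lapse
#'
#' Regresses per-plot mean CTI on elevation and expresses the slope per
#' 100 m. Communities become more cryophilic with elevation, so the
#' estimate is expected to be negative; its magnitude is the normalising
#' gradient of the NES.
#'
#' @param mean_cti per-plot mean CTI over all surveys of the plot.
#' @param elevation plot elevations in metres.
#' @return object of class \code{lapse_estimate}: list with
#'   \code{lapse_per_100m}, \code{se_per_100m}, \code{r_squared},
#'   \code{p_value}, \code{n_plots}.
#' @examples
#' estimate_lapse(c(3, 2.5, 2), c(500, 1000, 1500))
#' @export
estimate_lapse <- function(mean_cti, elevation) {
  ok <- !is.na(mean_cti) & !is.na(elevation)
  y <- mean_cti[ok]; x <- elevation[ok]
  if (length(y) < 3L) stop("lapse estimation needs >= 3 plots with a defined mean CTI")
  if (length(unique(x)) < 2L) stop("lapse estimation needs >= 2 distinct elevations")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # exact fixtures trip the perfect-fit warning
  est <- unname(coef(fit)[2L]) * 100
  se <- sm$coefficients[2L, 2L] * 100
  p <- sm$coefficients[2L, 4L]
  r2 <- sm$r.squared
  if (all(y == y[1L])) { # flat response: define lapse 0, R^2 0
    est <- 0; r2 <- 0; p <- 1
  }
  structure(list(lapse_per_100m = est, se_per_100m = se, r_squared = r2,
                 p_value = p, n_plots = length(y)),
            class = "lapse_estimate")
}

#' @export
print.lapse_estimate <- function(x, ...) {
  cat(sprintf("Elevational CTI lapse: %.4f per 100 m (SE %.4f, R^2 = %.2f, p = %.3g, n = %d plots)\n",
              x$lapse_per_100m, x$se_per_100m, x$r_squared, x$p_value, x$n_plots))
  invisible(x)
}

#' Per-lineage lapse estimates from community surveys
#'
#' Convenience wrapper: averages each community's CTI over its surveys and
#' calls [estimate_lapse()] separately per lineage.
#'
#' @param surveys output of [build_surveys()].
#' @param plots validated plot table.
#' @return named list of \code{lapse_estimate} objects, one per lineage
#'   present.
#' @export
lapse_by_lineage <- function(surveys, plots) {
  plots <- validate_plots(plots)
  out <- list()
  for (l in intersect(.lineage_levels, unique(as.character(surveys$lineage)))) {
    sub <- surveys[surveys$lineage == l & !is.na(surveys$cti), , drop = FALSE]
    if (!nrow(sub)) next
    m <- tapply(sub$cti, sub$plot_id, mean)
    elev <- plots$elevation[match(names(m), plots$plot_id)]
    out[[l]] <- estimate_lapse(as.numeric(m), elev)
  }
  out
}

#' Notional elevation shift
#'
#' Converts a thermophilisation rate into the elevation difference at which
#' communities with the same CTI are found after ten years: the rate (CTI
#' per year) divided by the magnitude of the elevational CTI lapse (CTI per
#' 100 m), times 1000, giving metres per decade.
#'
#' @param slope thermophilisation rate, CTI units per year.
#' @param lapse_magnitude positive magnitude of the elevational CTI lapse,
#'   CTI units per 100 m.
#' @return NES in metres per decade.
#' @examples
#' compute_nes(0.01, 0.1) # 100 m per decade
#' @export
compute_nes <- function(slope, lapse_magnitude) {
  if (any(!is.finite(lapse_magnitude)) || any(lapse_magnitude <= 0)) {
    stop("lapse_magnitude must be > 0: the NES presupposes a CTI decline with elevation")
  }
  slope / lapse_magnitude * 1000
}

#' Warming rate from an annual temperature series
#'
#' OLS slope of mean annual temperature on year, scaled to degrees Celsius
#' per decade.
#'
#' @param temperature validated series (columns year, mean_temp), or any
#'   data frame accepted by [validate_temperature()].
#' @return list with \code{warming_per_decade}, \code{r_squared},
#'   \code{p_value}, \code{n_years}.
#' @export
estimate_warming <- function(temperature) {
  temperature <- validate_temperature(temperature)
  if (nrow(temperature) < 3L) stop("warming estimation needs >= 3 years")
  if (length(unique(temperature$year)) < 2L) stop("constant years in temperature series")
  fit <- lm(mean_temp ~ year, data = temperature)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2L])
  r2 <- if (var(temperature$mean_temp) == 0) 0 else sm$r.squared
  p <- if (var(temperature$mean_temp) == 0) 1 else sm$coefficients[2L, 4L]
  list(warming_per_decade = slope * 10, r_squared = r2, p_value = p,
       n_years = nrow(temperature))
}

#' Expected isotherm shift
#'
#' Converts a warming rate into the implied upward shift of isotherms under
#' a range of adiabatic lapse rates: shift = warming / lapse x 100. The low
#' shift corresponds to the steep (high) adiabatic lapse and vice versa.
#' Reported integers use half-up rounding; the raw values are retained.
#'
#' @param warming_per_decade warming rate in degrees C per decade.
#' @param adiabatic numeric length-2, adiabatic lapse-rate bounds in
#'   degrees C per 100 m (low, high); both > 0.
#' @return object of class \code{isotherm_shift}: list with
#'   \code{shift_low}, \code{shift_high} (m per decade),
#'   \code{shift_low_rounded}, \code{shift_high_rounded},
#'   \code{warming_per_decade}, \code{adiabatic}.
#' @examples
#' isotherm_shift(0.42, c(0.5, 0.67)) # 62.7 to 84 m per decade
#' @export
isotherm_shift <- function(warming_per_decade, adiabatic = c(0.5, 0.67)) {
  stopifnot(length(adiabatic) == 2L)
  if (any(adiabatic <= 0)) stop("adiabatic lapse rates must be > 0")
  if (adiabatic[1L] > adiabatic[2L]) stop("adiabatic bounds must satisfy low <= high")
  shift_low <- warming_per_decade / adiabatic[2L] * 100
  shift_high <- warming_per_decade / adiabatic[1L] * 100
  structure(list(shift_low = shift_low, shift_high = shift_high,
                 shift_low_rounded = round_half_up(shift_low),
                 shift_high_rounded = round_half_up(shift_high),
                 warming_per_decade = warming_per_decade,
                 adiabatic = adiabatic),
            class = "isotherm_shift")
}

#' @export
print.isotherm_shift <- function(x, ...) {
  cat(sprintf("Warming %.2f degC/decade over adiabatic lapse %.2f-%.2f degC/100 m\n",
              x$warming_per_decade, x$adiabatic[1L], x$adiabatic[2L]))
  cat(sprintf("Expected isotherm shift: %.0f to %.0f m per decade (raw %.1f, %.1f)\n",
              x$shift_low_rounded, x$shift_high_rounded, x$shift_low, x$shift_high))
  invisible(x)
}

#' Per-community thermophilisation trends and NES
#'
#' Fits the per-plot OLS CTI trend for every community (plot x lineage)
#' with at least \code{min_surveys} surveys having a defined CTI, and
#' normalises it into the NES using the lineage's lapse magnitude.
#' Communities that do not qualify are listed, with reasons, in the
#' \code{"exclusions"} attribute of the result.
#'
#' @param surveys output of [build_surveys()].
#' @param lapse named list of \code{lapse_estimate} objects (or a named
#'   numeric vector of signed lapses) per lineage, e.g. from
#'   [lapse_by_lineage()]. Estimated lapses must be negative; a
#'   non-negative lapse aborts because the NES cannot be normalised by a
#'   non-decreasing gradient.
#' @param subset label stored with the trends ("all", "short_lived",
#'   "long_lived"); purely descriptive, the filtering itself happens in
#'   [build_surveys()].
#' @param min_surveys minimum number of surveys with a defined CTI
#'   (default 2).
#' @return data frame with one row per eligible community: plot_id,
#'   lineage, subset, n_surveys_used, slope_per_yr, nes_m_per_decade,
#'   mean_n_species (mean number of species contributing to the CTI, the
#'   variance covariate of the NES models).
#' @export
build_trends <- function(surveys, lapse, subset = "all", min_surveys = 2L) {
  lapse_mag <- vapply(lapse, function(l) {
    v <- if (inherits(l, "lapse_estimate")) l$lapse_per_100m else as.numeric(l)
    if (!is.finite(v) || v >= 0) {
      stop("estimated lapse is not negative; CTI does not decline with elevation, NES undefined")
    }
    abs(v)
  }, numeric(1))

  sub <- surveys[as.character(surveys$lineage) %in% names(lapse_mag), , drop = FALSE]
  key <- paste(sub$plot_id, sub$lineage, sep = "\r")
  ok <- !is.na(sub$cti)
  # per community: number of usable surveys and distinct usable years
  n_use <- tapply(ok, key, sum)
  rows <- data.frame(key = names(n_use), n = as.integer(n_use),
                     stringsAsFactors = FALSE)
  u <- sub[ok, , drop = FALSE]
  ukey <- paste(u$plot_id, u$lineage, sep = "\r")
  slopes <- vapply(split(seq_len(nrow(u)), ukey), function(i) {
    fit_plot_trend(u$year[i], u$cti[i])
  }, numeric(1))
  mean_nsp <- tapply(u$n_with_t, ukey, mean)

  rows$slope <- slopes[rows$key]
  rows$mean_nsp <- as.numeric(mean_nsp[rows$key])
  parts <- do.call(rbind, strsplit(rows$key, "\r", fixed = TRUE))
  rows$plot_id <- parts[, 1L]
  rows$lineage <- parts[, 2L]

  eligible <- !is.na(rows$slope) & rows$n >= min_surveys
  excl <- rows[!eligible, , drop = FALSE]
  exclusions <- data.frame(
    plot_id = excl$plot_id, lineage = excl$lineage,
    subset = rep(subset, nrow(excl)),
    reason = ifelse(excl$n < min_surveys,
                    sprintf("fewer than %d CTI values", min_surveys),
                    "single distinct survey year"),
    stringsAsFactors = FALSE
  )
  keep <- rows[eligible, , drop = FALSE]
  out <- data.frame(
    plot_id = keep$plot_id,
    lineage = factor(keep$lineage, levels = .lineage_levels),
    subset = subset,
    n_surveys_used = keep$n,
    slope_per_yr = keep$slope,
    nes_m_per_decade = compute_nes(keep$slope, lapse_mag[keep$lineage]),
    mean_n_species = keep$mean_nsp,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$plot_id, out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  attr(out, "lapse_magnitude") <- lapse_mag
  out
}
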