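# Readers, writers and validation for the four input tables.
#
# All tables are plain UTF-8 CSV with a mandatory header row; "" and "NA"
# denote missing values. Column matching is case-insensitive.

#' Assign an elevational vegetation zone
#'
#' Maps elevation to one of the four Swiss vegetation zones (colline,
#' montane, subalpine, alpine) using a single national threshold rule.
#' Regionally varying zone limits are deliberately not modelled; the default
#' cut points (800, 1500, 2200 m) sit inside the roughly reported national
#' ranges of the zone upper limits. Plots above the alpine zone (nival) are
#' pooled into \code{alpine}.
#'
#' @param elevation numeric vector of elevations in metres a.s.l. (>= 0).
#' @param thresholds named numeric vector of zone upper bounds in metres:
#'   \code{c(colline = 800, montane = 1500, subalpine = 2200)}. Must be
#'   strictly increasing.
#' @return factor with levels colline, montane, subalpine, alpine.
#' @examples
#' assign_zone(c(514, 1200, 3060))
#' @export
assign_zone <- function(elevation, thresholds = .default_zone_thresholds) {
  stopifnot(is.numeric(elevation), length(thresholds) == 3L,
            !is.unsorted(thresholds, strictly = TRUE))
  if (any(elevation < 0, na.rm = TRUE)) {
    stop("elevation must be >= 0 m")
  }
  idx <- findInterval(elevation, thresholds) + 1L
  factor(.zone_levels[idx], levels = .zone_levels)
}

.read_one <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s table not found: '%s'", what, path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  names(df) <- tolower(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s table '%s' lacks required column(s): %s",
                 what, path, paste(missing, collapse = ", ")))
  }
  df
}

#' Validate a plot table
#'
#' Checks ids, elevations and land-use categories, and derives the
#' elevational zone when it is not supplied.
#'
#' @param plots data frame with columns \code{plot_id}, \code{elevation}
#'   (or \code{elevation_m}), \code{land_use}, optionally \code{zone}.
#' @param zone_thresholds passed to [assign_zone()].
#' @return validated data frame with columns plot_id, elevation, land_use,
#'   zone.
#' @export
validate_plots <- function(plots, zone_thresholds = .default_zone_thresholds) {
  names(plots) <- tolower(names(plots))
  if ("elevation_m" %in% names(plots) && !"elevation" %in% names(plots)) {
    plots$elevation <- plots$elevation_m
  }
  need <- c("plot_id", "elevation", "land_use")
  missing <- setdiff(need, names(plots))
  if (length(missing)) {
    stop("plot table lacks required column(s): ", paste(missing, collapse = ", "))
  }
  plots$plot_id <- as.character(plots$plot_id)
  if (anyDuplicated(plots$plot_id)) {
    stop("duplicated plot_id in plot table: ",
         paste(unique(plots$plot_id[duplicated(plots$plot_id)]), collapse = ", "))
  }
  plots$elevation <- as.numeric(plots$elevation)
  bad <- is.na(plots$elevation) | plots$elevation < 0 | plots$elevation > 5000
  if (any(bad)) {
    stop("elevation outside [0, 5000] m for plot(s): ",
         paste(head(plots$plot_id[bad], 5L), collapse = ", "))
  }
  unknown <- setdiff(unique(as.character(plots$land_use)), .land_use_levels)
  if (length(unknown)) {
    stop("unknown land_use value(s): ", paste(unknown, collapse = ", "),
         " (expected ", paste(.land_use_levels, collapse = ", "), ")")
  }
  plots$land_use <- factor(plots$land_use, levels = .land_use_levels)
  if (!"zone" %in% names(plots) || all(is.na(plots$zone))) {
    plots$zone <- assign_zone(plots$elevation, zone_thresholds)
  } else {
    unknown <- setdiff(unique(as.character(plots$zone)), c(.zone_levels, NA))
    if (length(unknown)) {
      stop("unknown zone value(s): ", paste(unknown, collapse = ", "))
    }
    plots$zone <- factor(plots$zone, levels = .zone_levels)
  }
  plots[, c("plot_id", "elevation", "land_use", "zone")]
}

#' Validate a species trait table
#'
#' Checks lineages and the 0.5-step indicator grid, and derives the
#' longevity class from the life-strategy code via
#' [classify_life_strategy()].
#'
#' @param traits data frame with columns \code{species_id}, \code{lineage},
#'   \code{temperature_value}, \code{strategy_code}.
#' @return validated data frame with an added \code{longevity} factor.
#' @export
validate_traits <- function(traits) {
  names(traits) <- tolower(names(traits))
  need <- c("species_id", "lineage", "temperature_value", "strategy_code")
  missing <- setdiff(need, names(traits))
  if (length(missing)) {
    stop("trait table lacks required column(s): ", paste(missing, collapse = ", "))
  }
  traits$species_id <- as.character(traits$species_id)
  traits <- unique(traits[, need])
  if (anyDuplicated(traits$species_id)) {
    stop("conflicting duplicate rows for species_id: ",
         paste(unique(traits$species_id[duplicated(traits$species_id)]), collapse = ", "))
  }
  unknown <- setdiff(unique(as.character(traits$lineage)), .lineage_levels)
  if (length(unknown)) {
    stop("unknown lineage value(s): ", paste(unknown, collapse = ", "))
  }
  traits$lineage <- factor(traits$lineage, levels = .lineage_levels)
  traits$temperature_value <- as.numeric(traits$temperature_value)
  off <- !is.na(traits$temperature_value) & !on_grid(traits$temperature_value)
  if (any(off)) {
    stop("temperature_value off the 0.5-step [1, 5] grid for species: ",
         paste(head(traits$species_id[off], 5L), collapse = ", "))
  }
  traits$strategy_code <- as.character(traits$strategy_code)
  traits$longevity <- classify_life_strategy(traits$strategy_code, traits$lineage)
  traits
}

#' Validate an occurrence table
#'
#' Deduplicates (plot, year, species) records and checks referential
#' integrity against the plot table. Species absent from the trait table are
#' allowed here; they simply carry no temperature value downstream.
#'
#' @param occurrences data frame with columns \code{plot_id}, \code{year},
#'   \code{species_id}.
#' @param plots validated plot table, used for the referential check
#'   (optional).
#' @return validated, deduplicated data frame.
#' @export
validate_occurrences <- function(occurrences, plots = NULL) {
  names(occurrences) <- tolower(names(occurrences))
  need <- c("plot_id", "year", "species_id")
  missing <- setdiff(need, names(occurrences))
  if (length(missing)) {
    stop("occurrence table lacks required column(s): ", paste(missing, collapse = ", "))
  }
  occurrences$plot_id <- as.character(occurrences$plot_id)
  occurrences$species_id <- as.character(occurrences$species_id)
  yr <- as.numeric(occurrences$year)
  if (any(is.na(yr)) || any(yr != round(yr))) {
    stop("year must be an integer calendar year")
  }
  occurrences$year <- as.integer(yr)
  occurrences <- unique(occurrences[, need])
  if (!is.null(plots)) {
    orphans <- setdiff(unique(occurrences$plot_id), plots$plot_id)
    if (length(orphans)) {
      stop("occurrence rows reference unknown plot_id(s): ",
           paste(head(orphans, 10L), collapse = ", "))
    }
  }
  rownames(occurrences) <- NULL
  occurrences
}

#' Validate an annual temperature series
#'
#' @param temperature data frame with columns \code{year} and
#'   \code{mean_temp} (or \code{mean_temp_c}).
#' @return validated data frame with columns year, mean_temp.
#' @export
validate_temperature <- function(temperature) {
  names(temperature) <- tolower(names(temperature))
  if ("mean_temp_c" %in% names(temperature) && !"mean_temp" %in% names(temperature)) {
    temperature$mean_temp <- temperature$mean_temp_c
  }
  need <- c("year", "mean_temp")
  missing <- setdiff(need, names(temperature))
  if (length(missing)) {
    stop("temperature table lacks required column(s): ", paste(missing, collapse = ", "))
  }
  temperature$year <- as.integer(temperature$year)
  temperature$mean_temp <- as.numeric(temperature$mean_temp)
  if (is.unsorted(temperature$year, strictly = TRUE)) {
    stop("temperature series years must be strictly increasing")
  }
  temperature[, need]
}

#' Read and validate the input tables
#'
#' Reads the plot, trait and occurrence CSV tables (and optionally an annual
#' mean-temperature series), validates them and returns the record sets
#' used by all downstream stages.
#'
#' @param plot_csv,trait_csv,occurrence_csv paths to the three CSV tables.
#' @param temperature_csv optional path to a year/mean-temperature CSV.
#' @param zone_thresholds passed to [assign_zone()] when the plot table has
#'   no zone column.
#' @return list with elements \code{plots}, \code{traits},
#'   \code{occurrences} and (possibly NULL) \code{temperature}.
#' @export
read_tables <- function(plot_csv, trait_csv, occurrence_csv,
                        temperature_csv = NULL,
                        zone_thresholds = .default_zone_thresholds) {
  plots <- validate_plots(
    .read_one(plot_csv, c("plot_id", "land_use"), "plot"),
    zone_thresholds
  )
  traits <- validate_traits(.read_one(
    trait_csv, c("species_id", "lineage", "temperature_value", "strategy_code"),
    "trait"
  ))
  occurrences <- validate_occurrences(
    .read_one(occurrence_csv, c("plot_id", "year", "species_id"), "occurrence"),
    plots
  )
  temperature <- NULL
  if (!is.null(temperature_csv)) {
    temperature <- validate_temperature(.read_one(temperature_csv, "year", "temperature"))
  }
  list(plots = plots, traits = traits, occurrences = occurrences,
       temperature = temperature)
}

#' Write the input tables to CSV
#'
#' Inverse of [read_tables()]: writes plots.csv, traits.csv,
#' occurrences.csv and (when present) temperature.csv plus truth.csv into a
#' directory. A write-then-read round trip reproduces the records.
#'
#' @param tables list as returned by [read_tables()] or
#'   [generate_scenario()].
#' @param dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- tables$plots
  out <- data.frame(plot_id = p$plot_id, elevation_m = p$elevation,
                    land_use = as.character(p$land_use),
                    zone = as.character(p$zone))
  paths["plots"] <- file.path(dir, "plots.csv")
  write.csv(out, paths["plots"], row.names = FALSE, quote = FALSE, na = "")
  tr <- tables$traits
  out <- data.frame(species_id = tr$species_id,
                    lineage = as.character(tr$lineage),
                    temperature_value = tr$temperature_value,
                    strategy_code = tr$strategy_code)
  paths["traits"] <- file.path(dir, "traits.csv")
  write.csv(out, paths["traits"], row.names = FALSE, quote = FALSE, na = "")
  paths["occurrences"] <- file.path(dir, "occurrences.csv")
  write.csv(tables$occurrences, paths["occurrences"], row.names = FALSE,
            quote = FALSE, na = "")
  if (!is.null(tables$temperature)) {
    out <- data.frame(year = tables$temperature$year,
                      mean_temp_c = tables$temperature$mean_temp)
    paths["temperature"] <- file.path(dir, "temperature.csv")
    write.csv(out, paths["temperature"], row.names = FALSE, quote = FALSE, na = "")
  }
  if (!is.null(attr(tables, "truth"))) {
    paths["truth"] <- file.path(dir, "truth.csv")
    write.csv(attr(tables, "truth"), paths["truth"], row.names = FALSE,
              quote = FALSE, na = "")
  }
  invisible(paths)
}
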