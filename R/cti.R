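# Community temperature index layer: temperature-affinity classes, CTI,
# life-strategy longevity classes and assembly of plot x lineage x year
# community surveys.

#' Classify species by temperature affinity
#'
#' Partitions the ordinal temperature indicator grid into the three
#' affinity classes used for the species-count models: values 1-2.5 are
#' cryophilic, 3 mesophilic and 3.5-5 thermophilic. Missing values map to
#' \code{unclassified}.
#'
#' @param temperature_value numeric vector on the 0.5-step grid in [1, 5],
#'   possibly NA.
#' @return factor with levels cryophilic, mesophilic, thermophilic,
#'   unclassified.
#' @examples
#' classify_affinity(c(2.5, 3, 3.5, NA))
#' @export
classify_affinity <- function(temperature_value) {
  x <- as.numeric(temperature_value)
  off <- !is.na(x) & !on_grid(x)
  if (any(off)) {
    stop("temperature_value off the 0.5-step [1, 5] grid: ",
         paste(head(unique(x[off]), 5L), collapse = ", "))
  }
  out <- rep("unclassified", length(x))
  out[!is.na(x) & x <= 2.5] <- "cryophilic"
  out[!is.na(x) & x == 3] <- "mesophilic"
  out[!is.na(x) & x >= 3.5] <- "thermophilic"
  factor(out, levels = c("cryophilic", "mesophilic", "thermophilic", "unclassified"))
}

#' Community temperature index of one species set
#'
#' The CTI is the unweighted arithmetic mean of the temperature indicator
#' values of the species present (presence/absence data; no abundance
#' weighting). An empty value set yields \code{NA}: the CTI is undefined
#' when no member species carries an indicator value.
#'
#' @param values numeric vector of member-species temperature values on the
#'   0.5-step grid; NAs are dropped.
#' @return scalar CTI in [1, 5], or NA if no usable value.
#' @examples
#' compute_cti(c(1, 2, 3, 3.5)) # 2.375
#' @export
compute_cti <- function(values) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  if (!all(on_grid(v))) {
    stop("temperature values must lie on the 0.5-step [1, 5] grid")
  }
  mean(v)
}

# During life-strategy categories (bryophytes)
.bryo_short <- c("fugitive", "annual_shuttle", "colonist", "ephemeral_colonist",
                 "pioneer_colonist", "short_lived_shuttle")
.bryo_long <- c("long_lived_shuttle", "perennial", "competitive_perennial",
                "stress_tolerant_perennial", "dominant")
# CSR attribute codes (vascular plants); predominantly stress-tolerant codes
# and crs are excluded because longevity is undefined for them
.vasc_short <- c("rrr", "rrs", "crr")
.vasc_long <- c("ccc", "ccs", "ccr")

#' Longevity class from a life-strategy code
#'
#' Maps life-strategy codes to a short-lived vs long-lived dichotomy.
#' Bryophytes use the During system: fugitives, annual shuttles, colonists
#' (incl. ephemeral and pioneer colonists) and short-lived shuttles are
#' short-lived; long-lived shuttles, perennials (incl. competitive and
#' stress-tolerant perennials) and dominants are long-lived. Vascular
#' plants use three-letter CSR attribute codes: predominantly ruderal codes
#' (rrr, rrs, crr) are short-lived and predominantly competitive codes
#' (ccc, ccs, ccr) long-lived; predominantly stress-tolerant codes (sss,
#' css, rss) and crs have no defined longevity and map to
#' \code{unclassified}, as do missing or unknown codes.
#'
#' @param strategy_code character vector of codes (may contain NA).
#' @param lineage character or factor vector, "bryophyte" or "vascular",
#'   recycled if scalar.
#' @return factor with levels short_lived, long_lived, unclassified.
#' @examples
#' classify_life_strategy(c("colonist", "perennial"), "bryophyte")
#' classify_life_strategy(c("rrr", "ccr", "crs"), "vascular")
#' @export
classify_life_strategy <- function(strategy_code, lineage) {
  code <- tolower(as.character(strategy_code))
  lin <- as.character(lineage)
  if (length(lin) == 1L) lin <- rep(lin, length(code))
  stopifnot(length(lin) == length(code))
  out <- rep("unclassified", length(code))
  b <- lin == "bryophyte"
  v <- lin == "vascular"
  out[b & code %in% .bryo_short] <- "short_lived"
  out[b & code %in% .bryo_long] <- "long_lived"
  out[v & code %in% .vasc_short] <- "short_lived"
  out[v & code %in% .vasc_long] <- "long_lived"
  factor(out, levels = .longevity_levels)
}

#' Assemble community surveys
#'
#' Builds one community record per (plot, lineage, survey year) with at
#' least one occurrence of that lineage: species count, number of species
#' carrying a temperature value, CTI, and the cryophilic / mesophilic /
#' thermophilic species counts. Occurrences of species absent from the
#' trait table cannot be assigned a lineage and are dropped (with a
#' message). The optional \code{longevity} filter restricts member species
#' to one longevity class before the CTI is computed, which is how the
#' life-strategy contrast is prepared.
#'
#' @param plots,traits,occurrences validated tables (see [read_tables()];
#'   raw data frames are validated on the fly).
#' @param longevity one of "all", "short_lived", "long_lived".
#' @param verbose emit coverage messages?
#' @return data frame with one row per community survey: plot_id, lineage,
#'   year, n_species, n_with_t, cti, n_cryo, n_meso, n_thermo.
#' @export
build_surveys <- function(plots, traits, occurrences,
                          longevity = c("all", "short_lived", "long_lived"),
                          verbose = TRUE) {
  longevity <- match.arg(longevity)
  plots <- validate_plots(plots)
  if (is.null(traits$longevity)) traits <- validate_traits(traits)
  occurrences <- validate_occurrences(occurrences, plots)

  idx <- match(occurrences$species_id, traits$species_id)
  unknown <- is.na(idx)
  if (any(unknown) && verbose) {
    message(sprintf(
      "build_surveys: dropping %d occurrence(s) of %d species absent from the trait table",
      sum(unknown), length(unique(occurrences$species_id[unknown]))
    ))
  }
  occ <- occurrences[!unknown, , drop = FALSE]
  idx <- idx[!unknown]
  occ$lineage <- traits$lineage[idx]
  occ$tval <- traits$temperature_value[idx]
  occ$longv <- traits$longevity[idx]
  if (longevity != "all") {
    keep <- occ$longv == longevity
    occ <- occ[keep, , drop = FALSE]
  }
  if (!nrow(occ)) {
    stop("no occurrences left after filtering; cannot build surveys")
  }

  grp <- interaction(occ$plot_id, occ$lineage, occ$year, drop = TRUE, lex.order = TRUE)
  first <- !duplicated(grp)
  aff <- classify_affinity(occ$tval)
  has_t <- !is.na(occ$tval)
  agg <- rowsum(cbind(n_species = 1,
                      n_with_t = as.numeric(has_t),
                      sum_t = ifelse(has_t, occ$tval, 0),
                      n_cryo = as.numeric(aff == "cryophilic"),
                      n_meso = as.numeric(aff == "mesophilic"),
                      n_thermo = as.numeric(aff == "thermophilic")),
                group = grp, reorder = FALSE)
  out <- data.frame(
    plot_id = occ$plot_id[first],
    lineage = occ$lineage[first],
    year = occ$year[first],
    n_species = as.integer(agg[, "n_species"]),
    n_with_t = as.integer(agg[, "n_with_t"]),
    cti = ifelse(agg[, "n_with_t"] > 0, agg[, "sum_t"] / agg[, "n_with_t"], NA_real_),
    n_cryo = as.integer(agg[, "n_cryo"]),
    n_meso = as.integer(agg[, "n_meso"]),
    n_thermo = as.integer(agg[, "n_thermo"]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$plot_id, out$lineage, out$year), , drop = FALSE]
  rownames(out) <- NULL
  if (verbose) {
    for (l in levels(out$lineage)) {
      sub <- out[out$lineage == l, ]
      if (!nrow(sub)) next
      message(sprintf(
        "build_surveys [%s]: %d community surveys, mean richness %.1f, %.0f%% of observations with temperature values",
        l, nrow(sub), mean(sub$n_species),
        100 * sum(sub$n_with_t) / sum(sub$n_species)
      ))
    }
  }
  out
}
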