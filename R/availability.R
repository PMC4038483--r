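#' Pond condition during the breeding window
#'
#' Pond condition for a pond-year is the maximum area attained during the
#' 30-day window surrounding the species' breeding peak divided by the maximum
#' area ever recorded for that pond, clipped to `[0, 1]`. A `stat = "mean"`
#' switch averages the window areas instead, for sensitivity analyses.
#'
#' @param hydro tibble with columns `pond_id`, `year` and `area` (maximum --
#'   or mean, see `stat` -- pond area in the breeding window, m^2). A missing
#'   `area` yields a missing condition rather than an error.
#' @param ponds tibble with columns `pond_id`, `max_area_ever` (> 0).
#' @param stat how the window areas were summarised upstream; recorded in the
#'   output for provenance.
#' @return tibble `pond_id`, `year`, `condition`.
#' @export
pond_condition <- function(hydro, ponds, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  if (any(ponds$max_area_ever <= 0)) stop("max_area_ever must be positive")
  out <- dplyr::left_join(
    dplyr::select(hydro, "pond_id", "year", "area"),
    dplyr::select(ponds, "pond_id", "max_area_ever"),
    by = "pond_id"
  )
  out$condition <- pmin(pmax(out$area / out$max_area_ever, 0), 1)
  attr(out, "condition_stat") <- stat
  dplyr::select(out, "pond_id", "year", "condition")
}

#' Ponds available for breeding in a given year
#'
#' A pond is available to a species in a year when its breeding-window
#' condition strictly exceeds the threshold (default 30%) and it did not dry
#' before the sampling date. The threshold is strict: a condition of exactly
#' 0.30 is excluded.
#'
#' @param conditions tibble from [pond_condition()].
#' @param hydro tibble with `pond_id`, `year`, `dry_before_sampling` (logical).
#' @param threshold availability cutoff on condition.
#' @return tibble `pond_id`, `year`, `available` (logical; ponds with missing
#'   condition are unavailable).
#' @export
available_ponds <- function(conditions, hydro, threshold = 0.30) {
  out <- dplyr::left_join(
    conditions,
    dplyr::select(hydro, "pond_id", "year", "dry_before_sampling"),
    by = c("pond_id", "year")
  )
  out$available <- !is.na(out$condition) & out$condition > threshold &
    !dplyr::coalesce(out$dry_before_sampling, FALSE)
  dplyr::select(out, "pond_id", "year", "available")
}

#' Cumulative habitable set of a species
#'
#' The set of potentially habitable ponds is estimated as the cumulative list
#' of ponds in which the species was ever recorded; for most species the
#' accumulation curve saturates after a few years of monitoring.
#'
#' @param survey collapsed survey tibble (one row per pond-year-species).
#' @param species_id species of interest.
#' @return list with `ponds` (character vector, the final habitable set) and
#'   `curve` (tibble `year`, `n_cumulative`), which is nondecreasing.
#' @export
habitable_set <- function(survey, species_id) {
  sp <- dplyr::filter(survey, .data$species_id == !!species_id, .data$present)
  years <- sort(unique(survey$year))
  if (nrow(sp) == 0) {
    warning("species '", species_id, "' never present; habitable set is empty")
    return(list(ponds = character(0),
                curve = tibble::tibble(year = years, n_cumulative = 0L)))
  }
  seen <- character(0)
  curve <- tibble::tibble(year = years, n_cumulative = NA_integer_)
  for (k in seq_along(years)) {
    seen <- union(seen, sp$pond_id[sp$year == years[k]])
    curve$n_cumulative[k] <- length(seen)
  }
  list(ponds = seen, curve = curve)
}

#' Constrained occupancy: occupied over available-and-habitable ponds
#'
#' The fraction of ponds estimated to be uniquely available to a species that
#' it actually occupies. The denominator is the intersection of the year's
#' available ponds with the species' habitable set. Values above 1 are
#' meaningful (occupancy maintained by mass effects beyond estimated
#' availability) and are flagged rather than clipped; an empty denominator
#' yields `NA`.
#'
#' @param occupied character vector of occupied pond ids for the year.
#' @param available character vector of available pond ids for the year.
#' @param habitable character vector, the species' habitable set.
#' @return tibble with `n_occupied`, `n_available_habitable`,
#'   `constrained_occupancy`, `exceeds_availability`.
#' @export
constrained_occupancy <- function(occupied, available, habitable) {
  denom <- intersect(available, habitable)
  value <- if (length(denom) == 0) NA_real_ else length(occupied) / length(denom)
  tibble::tibble(
    n_occupied = length(occupied),
    n_available_habitable = length(denom),
    constrained_occupancy = value,
    exceeds_availability = !is.na(value) && value > 1
  )
}

#' Expected number of suitable ponds from category counts
#'
#' Weights the number of ponds in each suitability category by the frequency
#' with which the focal species occupied that category when it was abundant,
#' sums, and rounds to the nearest integer (half away from zero). The default
#' categories are open-canopy ponds that dried the previous fall, open-canopy
#' ponds that did not, and closed-canopy ponds.
#'
#' @param counts named integer vector of pond counts per category.
#' @param freqs named numeric vector of occupancy frequencies in `[0, 1]`;
#'   names must match `counts`. Defaults to [suitability_frequencies()].
#' @return integer expected number of suitable ponds.
#' @export
weighted_suitability <- function(counts, freqs = suitability_frequencies()) {
  if (!setequal(names(counts), names(freqs))) {
    stop("category names of `counts` and `freqs` differ")
  }
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  total <- sum(counts[names(freqs)] * freqs)
  as.integer(sign(total) * floor(abs(total) + 0.5))
}
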