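#' Interspecific d-a coordinates per species
#'
#' For each species: mean local density (mean density in occupied ponds each
#' year, then averaged across years -- a mean of yearly means, not a pooled
#' mean), the mean number of ponds occupied per year, and, when an
#' availability table is supplied, the mean constrained occupancy.
#'
#' @param survey collapsed survey tibble (one row per pond-year-species).
#' @param availability optional tibble `pond_id`, `year`, `available` from
#'   [available_ponds()]; habitable sets are computed from the survey itself.
#' @return tibble `species_id`, `mean_density`, `mean_n_occupied`,
#'   `mean_constrained_occupancy` (NA without availability), `n_years`.
#' @export
interspecific_points <- function(survey, availability = NULL) {
  species <- sort(unique(survey$species_id))
  purrr::map_dfr(species, function(spp) {
    sp <- dplyr::filter(survey, .data$species_id == spp)
    yearly <- dplyr::summarise(
      dplyr::group_by(sp, .data$year),
      n_occupied = sum(.data$present),
      mean_density = ifelse(sum(.data$present) > 0,
        mean(.data$density[.data$present]), NA_real_),
      .groups = "drop"
    )
    if (all(yearly$n_occupied == 0)) {
      warning("species '", spp, "' absent in all years; omitted")
      return(tibble::tibble())
    }
    co <- NA_real_
    if (!is.null(availability)) {
      hab <- habitable_set(survey, spp)$ponds
      co_years <- vapply(yearly$year, function(yr) {
        occ <- sp$pond_id[sp$year == yr & sp$present]
        av <- availability$pond_id[availability$year == yr & availability$available]
        constrained_occupancy(occ, av, hab)$constrained_occupancy
      }, 0)
      co <- mean(co_years, na.rm = TRUE)
    }
    tibble::tibble(
      species_id = spp,
      mean_density = mean(yearly$mean_density, na.rm = TRUE),
      mean_n_occupied = mean(yearly$n_occupied),
      mean_constrained_occupancy = co,
      n_years = nrow(yearly)
    )
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates availability estimation, per-species summaries, the
#' interspecific d-a model suite, regime-shift detection on a focal species'
#' occupancy and log mean density, and Hanski connectivity with
#' occupied-versus-unoccupied comparisons. All stages are deterministic given
#' `seed`.
#'
#' @param survey collapsed survey tibble.
#' @param ponds pond attribute tibble (`pond_id`, `x`, `y`, `region`,
#'   `canopy`, `max_area_ever`).
#' @param hydro hydrology tibble (`pond_id`, `year`, `area`,
#'   `dry_before_sampling`).
#' @param focal_species species for the regime-shift and intraspecific
#'   analyses (default: the most widespread).
#' @param condition_threshold availability cutoff on pond condition.
#' @param stars_l,stars_alpha regime-shift parameters.
#' @param seed passed to bootstrap components.
#' @return list of class `pond_report` with elements `availability`,
#'   `interspecific` (points + suite ranking), `regimes` (occupancy and
#'   density `stars_result`s), `connectivity`, and `params`.
#' @export
run_pipeline <- function(survey, ponds, hydro, focal_species = NULL,
                         condition_threshold = 0.30,
                         stars_l = 4, stars_alpha = 0.05, seed = 1L) {
  if (!all(c("pond_id", "year", "species_id", "density", "present") %in% names(survey))) {
    stop("survey must be a collapsed survey table")
  }
  conditions <- pond_condition(hydro, ponds)
  avail <- available_ponds(conditions, hydro, threshold = condition_threshold)
  points <- interspecific_points(survey, avail)
  suite <- if (nrow(points) >= 6) {
    da_model_suite(points$mean_density, points$mean_n_occupied, seed = seed)
  } else NULL

  if (is.null(focal_species)) {
    focal_species <- points$species_id[which.max(points$mean_n_occupied)]
  }
  sp <- dplyr::filter(survey, .data$species_id == focal_species)
  yearly <- dplyr::summarise(
    dplyr::group_by(sp, .data$year),
    n_occupied = sum(.data$present),
    mean_density = ifelse(sum(.data$present) > 0,
      mean(.data$density[.data$present]), NA_real_),
    .groups = "drop"
  )
  yearly <- dplyr::arrange(yearly, .data$year)
  occ_stars <- stars(yearly$n_occupied, years = yearly$year, l = stars_l, alpha = stars_alpha)
  dens_ok <- is.finite(yearly$mean_density) & yearly$mean_density > 0
  dens_stars <- if (all(dens_ok)) {
    stars(log(yearly$mean_density), years = yearly$year, l = stars_l, alpha = 0.10)
  } else NULL

  pops <- dplyr::left_join(
    dplyr::select(sp, "pond_id", "year", "density"),
    dplyr::select(hydro, "pond_id", "year", "area"),
    by = c("pond_id", "year")
  )
  pops$n <- pops$density * pmax(pops$area, 0)
  conn <- hanski_index(ponds, dplyr::select(pops, "pond_id", "year", "n"))
  comparison <- compare_occupied(conn, dplyr::select(sp, "pond_id", "year", "present"))

  structure(
    list(
      availability = avail,
      interspecific = list(points = points, ranking = if (!is.null(suite)) suite$ranking),
      focal_species = focal_species,
      yearly = yearly,
      regimes = list(occupancy = occ_stars, density = dens_stars),
      connectivity = list(index = conn, comparison = comparison),
      params = list(condition_threshold = condition_threshold,
                    stars_l = stars_l, stars_alpha = stars_alpha, seed = seed)
    ),
    class = "pond_report"
  )
}

#' @export
print.pond_report <- function(x, ...) {
  cat("pond metacommunity analysis report\n")
  cat(sprintf("  species analysed: %d; focal species: %s\n",
              nrow(x$interspecific$points), x$focal_species))
  cat(sprintf("  occupancy regime shifts: %d; density regime shifts: %d\n",
              nrow(x$regimes$occupancy$shifts),
              if (!is.null(x$regimes$density)) nrow(x$regimes$density$shifts) else NA_integer_))
  invisible(x)
}

#' Write a machine-readable report bundle
#'
#' Serialises the tabular contents of a `pond_report` to a JSON file
#' (schema_version 1). Identical inputs and seed give byte-identical output.
#'
#' @param report a `pond_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pond_report"))
  payload <- list(
    schema_version = 1L,
    focal_species = report$focal_species,
    params = report$params,
    interspecific_points = report$interspecific$points,
    model_ranking = report$interspecific$ranking,
    yearly = report$yearly,
    occupancy_shifts = report$regimes$occupancy$shifts,
    density_shifts = if (!is.null(report$regimes$density)) report$regimes$density$shifts,
    connectivity_comparison = report$connectivity$comparison
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
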