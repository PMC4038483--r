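#' Read a long-format larval survey table
#'
#' The universal input of the pipeline: one row per pond, year, season and
#' species with a larval density in individuals per m^2. Presence is defined
#' operationally as density greater than zero.
#'
#' @param path CSV file with columns `pond_id`, `year`, `season`, `species_id`,
#'   `density` (UTF-8, header row).
#' @return validated tibble with an added logical `present` column.
#' @export
read_survey <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_survey(tbl)
}

#' @rdname read_survey
#' @param survey a survey tibble as returned by [read_survey()].
#' @export
write_survey <- function(survey, path) {
  survey <- validate_survey(survey)
  readr::write_csv(dplyr::select(survey, -"present"), path)
  invisible(path)
}

#' @rdname read_survey
#' @param tbl data frame to validate.
#' @export
validate_survey <- function(tbl) {
  required <- c("pond_id", "year", "season", "species_id", "density")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("survey table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(tbl$density)) stop("`density` must be numeric")
  bad <- which(!is.finite(tbl$density) | tbl$density < 0)
  if (length(bad) > 0) {
    stop("negative or non-finite density at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  tbl$year <- as.integer(tbl$year)
  dup <- duplicated(tbl[, c("pond_id", "year", "season", "species_id")])
  if (any(dup)) {
    stop("duplicate (pond, year, season, species) rows at: ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  }
  tbl$present <- tbl$density > 0
  tibble::as_tibble(tbl)
}

#' Collapse May and July samples to one record per pond-year-species
#'
#' When a species is sampled in both seasons the annual density is the maximum
#' of the seasonal estimates, and the species is present if it was present in
#' any season. Idempotent: collapsing a collapsed table is a no-op.
#'
#' @param survey survey tibble (see [read_survey()]).
#' @return tibble with one row per pond-year-species; the `season` column is
#'   dropped.
#' @export
season_collapse <- function(survey) {
  survey <- validate_survey(survey)
  out <- dplyr::summarise(
    dplyr::group_by(survey, .data$pond_id, .data$year, .data$species_id),
    density = max(.data$density),
    present = any(.data$present),
    .groups = "drop"
  )
  out
}

#' Cohort adjustment for species that overwinter as larvae
#'
#' Species whose larvae overwinter (bullfrog, green frog) are sampled either
#' just after hatching or as second-year animals, biasing density relative to
#' the mid-larval-period standard of the other species. Densities are rescaled
#' to the survivorship expected at the midpoint between the year-1 and year-2
#' age classes: hatchling-season records are multiplied by
#' `sqrt(survivorship)` and second-year records divided by it, and second-year
#' records are re-dated to the hatching year so presences line up with species
#' that emerge the summer eggs are laid.
#'
#' @param survey survey tibble.
#' @param species_id species to adjust.
#' @param survivorship year-1 to year-2 cohort survivorship in (0, 1]; the
#'   field estimate for the two overwintering ranids is 0.002 (0.20%).
#' @param hatchling_season,yearling_season season labels identifying the
#'   post-hatching and second-year samples.
#' @return adjusted survey tibble. Zero densities (and hence absences) are
#'   preserved. Unknown species: returned unchanged with a warning.
#' @export
cohort_adjust <- function(survey, species_id, survivorship = 0.002,
                          hatchling_season = "july", yearling_season = "may") {
  survey <- validate_survey(survey)
  if (survivorship <= 0 || survivorship > 1) stop("`survivorship` must be in (0, 1]")
  if (!species_id %in% survey$species_id) {
    warning("species '", species_id, "' not present in survey; returning unchanged")
    return(survey)
  }
  mid <- sqrt(survivorship)
  sel <- survey$species_id == species_id
  hatch <- sel & survey$season == hatchling_season
  yearl <- sel & survey$season == yearling_season
  survey$density[hatch] <- survey$density[hatch] * mid
  survey$density[yearl] <- survey$density[yearl] / mid
  survey$year[yearl] <- survey$year[yearl] - 1L
  survey$present <- survey$density > 0
  survey
}

#' Read a phylogeny for contrast analyses
#'
#' Thin wrapper around [ape::read.tree()] that checks the tips against the
#' analysed species and optionally substitutes unit branch lengths when the
#' input is a cladogram (no lengths), the default treatment for composite
#' trees assembled from published topologies.
#'
#' @param path newick file.
#' @param species optional character vector; every species must be a tip.
#' @param unit_lengths replace missing branch lengths with 1.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_phylo <- function(path, species = NULL, unit_lengths = TRUE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (is.null(tree$edge.length) && unit_lengths) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (!is.null(species)) {
    miss <- setdiff(species, tree$tip.label)
    if (length(miss) > 0) {
      stop("species missing from tree: ", paste(miss, collapse = ", "))
    }
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length <= 0)) {
    stop("tree has non-positive branch lengths; consider unit-length substitution")
  }
  tree
}

#' Read and write ESRI ASCII grids (friction rasters)
#'
#' Minimal reader for the ESRI ASCII grid format used for landscape friction
#' surfaces: a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `nodata_value`) followed by `nrows` rows of values, northmost
#' row first.
#'
#' @param path ASCII grid file.
#' @return object of class `friction_raster`: list with `values` (numeric
#'   matrix, row 1 = northmost), `cellsize`, `xll`, `yll`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("ASCII grid too short at ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header at line ", i)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header missing: ", paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid has ", length(vals), " values; expected ", hdr$ncols * hdr$nrows)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  structure(
    list(values = m, cellsize = hdr$cellsize, xll = hdr$xllcorner,
         yll = hdr$yllcorner, nodata = hdr$nodata_value),
    class = "friction_raster"
  )
}

#' @rdname read_ascii_grid
#' @param raster a `friction_raster`.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "friction_raster"))
  m <- raster$values
  m[is.na(m)] <- raster$nodata
  hdr <- c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", raster$xll), paste("yllcorner", raster$yll),
    paste("cellsize", raster$cellsize), paste("nodata_value", raster$nodata)
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct a friction raster from class values
#'
#' Default friction values follow the standard wetland/forest/open/slope
#' scheme (1, 3, 10, 100).
#'
#' @param values numeric matrix of per-cell friction (> 0), row 1 northmost.
#' @param cellsize cell edge length in metres.
#' @param xll,yll coordinates of the lower-left corner.
#' @param nodata sentinel written for missing cells.
#' @export
friction_raster <- function(values, cellsize, xll = 0, yll = 0, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  if (any(values <= 0, na.rm = TRUE)) stop("friction values must be positive")
  structure(
    list(values = values, cellsize = cellsize, xll = xll, yll = yll, nodata = nodata),
    class = "friction_raster"
  )
}

#' @export
print.friction_raster <- function(x, ...) {
  cat(sprintf(
    "friction_raster: %d x %d cells, cellsize %g m, %d nodata cells\n",
    nrow(x$values), ncol(x$values), x$cellsize, sum(is.na(x$values))
  ))
  invisible(x)
}
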