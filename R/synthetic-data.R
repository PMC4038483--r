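#' Climate scenario for the synthetic metacommunity
#'
#' Defaults emulate the drought regime observed on the study landscape: the
#' proportion of ponds drying the previous fall is ~0.36 outside drought
#' years and ~0.80 during the multi-year drought, and mean hydroperiod drops
#' from ~0.92 to ~0.59.
#'
#' @param years simulated calendar years.
#' @param drought_years subset of `years` under drought forcing.
#' @param p_dry_fall_base,p_dry_fall_drought probability a pond dried the
#'   previous fall.
#' @param hydroperiod_base,hydroperiod_drought mean fraction of the season a
#'   pond holds water.
#' @param p_dry_spring_base,p_dry_spring_drought probability a pond is also
#'   dry in early spring (refilling later).
#' @return list of class `climate_scenario`.
#' @export
climate_scenario <- function(years = 1996:2010, drought_years = 1999:2007,
                             p_dry_fall_base = 0.36, p_dry_fall_drought = 0.80,
                             hydroperiod_base = 0.92, hydroperiod_drought = 0.59,
                             p_dry_spring_base = 0.02, p_dry_spring_drought = 0.08) {
  probs <- c(p_dry_fall_base, p_dry_fall_drought, p_dry_spring_base, p_dry_spring_drought)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(drought_years %in% years)) stop("drought_years must be a subset of years")
  structure(
    list(
      years = years, drought_years = drought_years,
      p_dry_fall_base = p_dry_fall_base, p_dry_fall_drought = p_dry_fall_drought,
      hydroperiod_base = hydroperiod_base, hydroperiod_drought = hydroperiod_drought,
      p_dry_spring_base = p_dry_spring_base, p_dry_spring_drought = p_dry_spring_drought
    ),
    class = "climate_scenario"
  )
}

#' Demographic parameters for a simulated species
#'
#' The density update is phenomenological (Ricker growth toward a
#' predator-dependent carrying capacity with lognormal demographic noise),
#' not a life-table model. Carrying capacities by pond category default to
#' the observed mean densities: 6.2/m^2 in open ponds that dried the previous
#' fall, 3.0 in open ponds that did not, 0.9 in closed-canopy ponds (sink
#' habitat: extinction risk at that density is high, so closed ponds persist
#' only through mass effects). The extinction probability declines
#' logistically with log density through two anchors: P = 0.40 at 1.5/m^2
#' (observed) and P = 0.05 at 10/m^2 (a documented default).
#'
#' @param species_id label used in the survey output.
#' @param r intrinsic growth rate.
#' @param K_open_dried,K_open_wet,K_closed carrying capacities (individuals/m^2).
#' @param alpha dispersal kernel decay (1/m); the default mean dispersal
#'   distance is 125 m.
#' @param c_col colonisation coefficient scaling kernel-weighted source
#'   population size into a yearly colonisation probability.
#' @param ext_anchor_low,ext_anchor_high `(density, probability)` anchors of
#'   the extinction curve.
#' @param dispersal_threshold larval density (individuals/m^2) above which a
#'   pond exports colonists at full strength; below it the pond contributes
#'   only `subthreshold_dispersal` of its population to the colonisation
#'   kernel. This implements density-gated dispersal: small choruses attract
#'   few breeders and export few dispersers, so occupancy expansions are
#'   triggered only after local densities cross a threshold.
#' @param subthreshold_dispersal fraction of a below-threshold population
#'   contributing to colonisation pressure.
#' @param background_colonisation yearly probability floor that an empty pond
#'   is colonised from outside the modelled landscape (long-distance or
#'   off-reserve immigration); keeps total regional extinction from being an
#'   absorbing state of the scenario generator.
#' @param rescue_scale kernel-weighted immigration (same units as the
#'   colonisation kernel sum) that suppresses extinction by `exp(-S/scale)`:
#'   the rescue effect. Populations embedded in a strong source network
#'   rarely wink out; isolated ones face their intrinsic risk.
#' @param colonist_density density founded by a successful colonisation.
#' @param noise_sd lognormal demographic noise on growth (log scale).
#' @return list of class `species_params`.
#' @export
species_params <- function(species_id = "chorus_frog", r = 1.8,
                           K_open_dried = 6.2, K_open_wet = 2.3, K_closed = 0.9,
                           alpha = 1 / 125, c_col = 3.5e-4,
                           ext_anchor_low = c(1.5, 0.40),
                           ext_anchor_high = c(2.2, 0.01),
                           dispersal_threshold = 4.2, subthreshold_dispersal = 0.15,
                           background_colonisation = 0.010, rescue_scale = 2500,
                           colonist_density = 1.5, noise_sd = 0.25) {
  stopifnot(r > 0, alpha > 0, c_col >= 0, K_open_dried >= 0, K_open_wet >= 0, K_closed >= 0)
  if (!(K_closed < K_open_dried)) stop("closed-canopy K must be below open-dried K")
  b <- (stats::qlogis(ext_anchor_high[2]) - stats::qlogis(ext_anchor_low[2])) /
    (log(ext_anchor_high[1]) - log(ext_anchor_low[1]))
  a <- stats::qlogis(ext_anchor_low[2]) - b * log(ext_anchor_low[1])
  structure(
    list(
      species_id = species_id, r = r,
      K_open_dried = K_open_dried, K_open_wet = K_open_wet, K_closed = K_closed,
      alpha = alpha, c_col = c_col,
      ext_intercept = a, ext_slope = b,
      dispersal_threshold = dispersal_threshold,
      subthreshold_dispersal = subthreshold_dispersal,
      background_colonisation = background_colonisation,
      rescue_scale = rescue_scale,
      colonist_density = colonist_density, noise_sd = noise_sd
    ),
    class = "species_params"
  )
}

#' Extinction probability as a function of larval density
#'
#' @param params a [species_params()] object.
#' @param density individuals/m^2.
#' @export
extinction_probability <- function(params, density) {
  ifelse(density <= 0, 1,
    stats::plogis(params$ext_intercept + params$ext_slope * log(density))
  )
}

#' Predator-biomass model
#'
#' Spring predator biomass relative to ponds that held water: ponds that
#' dried the previous fall retain 25.5% of predator biomass, ponds also dry
#' in early spring 14%. Closed-canopy pond predators are unaffected by
#' drying. The carrying capacity of an open pond rises as predator biomass
#' falls, calibrated so that the multipliers reproduce the open-pond
#' carrying capacities of [species_params()].
#'
#' The measured multipliers describe drought-class drying, where ponds stand
#' dry for months across seasons. An ordinary (non-drought) fall dry-down is
#' brief and leaves part of the predator community in place, so its biomass
#' reduction is attenuated: the dried-pond multiplier is raised to the power
#' `base_drying_severity` (< 1) outside drought years.
#'
#' @param wet,dried_fall,dried_fall_spring biomass multipliers in (0, 1].
#' @param base_drying_severity exponent attenuating the drying effect in
#'   non-drought years (1 = ordinary drying is as severe as drought drying).
#' @return list of class `predator_model`.
#' @export
predator_model <- function(wet = 1.0, dried_fall = 0.255, dried_fall_spring = 0.14,
                           base_drying_severity = 0.25) {
  m <- c(wet, dried_fall, dried_fall_spring)
  if (any(m <= 0 | m > 1)) stop("multipliers must lie in (0, 1]")
  if (base_drying_severity <= 0 || base_drying_severity > 1) {
    stop("base_drying_severity must lie in (0, 1]")
  }
  structure(
    list(wet = wet, dried_fall = dried_fall, dried_fall_spring = dried_fall_spring,
         base_drying_severity = base_drying_severity),
    class = "predator_model"
  )
}

# carrying capacity for one pond-year given canopy and drying history;
# open-pond K interpolates in predator biomass through the two calibration
# points (wet -> K_open_wet, dried_fall -> K_open_dried)
k_effective <- function(params, predator, canopy, dried_prev_fall, dry_spring,
                        drought = TRUE, quality = 1) {
  if (canopy == "closed") return(params$K_closed)
  sev <- if (drought) 1 else predator$base_drying_severity
  pb <- if (!dried_prev_fall) predator$wet
        else if (dry_spring) predator$dried_fall_spring^sev
        else predator$dried_fall^sev
  ratio <- params$K_open_dried / params$K_open_wet
  kp <- (ratio - 1) / (predator$wet - ratio * predator$dried_fall)
  if (kp <= 0) return(params$K_open_wet * quality)
  k_base <- params$K_open_wet * (1 + kp * predator$wet)
  quality * k_base / (1 + kp * pb)
}

#' Generate a two-region pond landscape
#'
#' Ponds are laid out along two loosely linear wetland arrays (emulating the
#' east/west pond clusters of the study reserve) so that within-region
#' nearest-neighbour distances are on the order of 80-120 m while the regions
#' sit roughly 1.2 km apart.
#'
#' @param n_ponds total ponds (>= 2).
#' @param region_split fraction of ponds in each region (two values summing
#'   to 1).
#' @param canopy_fraction_open fraction of ponds with open canopy.
#' @param prime_fraction fraction of ponds that are prime breeding habitat
#'   (deeper basins with richer resources); the rest are marginal. Quality
#'   scales the carrying capacity of open ponds (`quality` column: prime
#'   1.25, marginal 0.75), so in the base climate only prime ponds sustain
#'   populations for long and the species is confined to a small refuge set.
#' @param spacing_west,spacing_east uniform ranges (m) of along-array spacing.
#' @param region_gap west-to-east offset in metres.
#' @param seed RNG seed; identical seeds give identical landscapes.
#' @return tibble `pond_id`, `x`, `y`, `region`, `canopy`, `max_area_ever`.
#' @export
generate_landscape <- function(n_ponds = 37, region_split = c(west = 0.5, east = 0.5),
                               canopy_fraction_open = 0.6, prime_fraction = 0.25,
                               spacing_west = c(55, 105), spacing_east = c(85, 160),
                               region_gap = 1250, seed = 1L) {
  if (n_ponds < 2) stop("need at least two ponds")
  if (abs(sum(region_split) - 1) > 1e-8) stop("region_split must sum to 1")
  if (region_gap <= 0) stop("degenerate landscape extent")
  set.seed(seed)
  n_west <- round(n_ponds * region_split[[1]])
  n_east <- n_ponds - n_west
  lay_array <- function(n, spacing, x0) {
    if (n == 0) return(NULL)
    step <- stats::runif(n, spacing[1], spacing[2])
    tibble::tibble(
      x = x0 + stats::rnorm(n, 0, 25),
      y = cumsum(step) + stats::rnorm(n, 0, 15)
    )
  }
  west <- lay_array(n_west, spacing_west, 0)
  east <- lay_array(n_east, spacing_east, region_gap)
  out <- dplyr::bind_rows(
    if (!is.null(west)) dplyr::mutate(west, region = names(region_split)[1] %||% "west"),
    if (!is.null(east)) dplyr::mutate(east, region = names(region_split)[2] %||% "east")
  )
  out$pond_id <- sprintf("P%02d", seq_len(nrow(out)))
  out$canopy <- ifelse(stats::runif(nrow(out)) < canopy_fraction_open, "open", "closed")
  out$quality <- ifelse(stats::runif(nrow(out)) < prime_fraction, 1.15, 0.9)
  out$max_area_ever <- exp(stats::rnorm(nrow(out), log(600), 0.7))
  dplyr::select(out, "pond_id", "x", "y", "region", "canopy", "quality", "max_area_ever")
}

#' Simulate pond hydrology under a climate scenario
#'
#' Whether a pond dried the previous fall is a Bernoulli draw at the
#' scenario's drying probability. With `persistence = 0` (the default) draws
#' are independent across ponds and years; with `persistence > 0` each pond
#' carries a latent depth propensity so that shallow ponds tend to be the
#' ones that dry year after year, while the marginal (per pond-year) drying
#' probability is preserved exactly. Persistent propensities produce the
#' spatially coherent, climate-forced habitat change (a Moran effect) that
#' the drought scenario assumes.
#'
#' @param landscape from [generate_landscape()].
#' @param scenario a [climate_scenario()].
#' @param persistence in `[0, 1)`: cross-year correlation of the latent
#'   drying propensity (0 = independent draws).
#' @param seed RNG seed.
#' @return tibble `pond_id`, `year`, `drought`, `dried_prev_fall`,
#'   `dry_before_sampling`, `hydroperiod`, `area` (breeding-window maximum
#'   area, m^2), `propensity` (per-pond latent, higher = dries more readily).
#' @export
simulate_hydrology <- function(landscape, scenario, persistence = 0, seed = 1L) {
  stopifnot(inherits(scenario, "climate_scenario"))
  if (persistence < 0 || persistence >= 1) stop("persistence must be in [0, 1)")
  set.seed(seed)
  n <- nrow(landscape)
  z_pond <- stats::rnorm(n)                       # latent shallowness, higher = drier
  grid <- tidyr::expand_grid(pond_id = landscape$pond_id, year = scenario$years)
  grid <- dplyr::left_join(grid, dplyr::select(landscape, "pond_id", "max_area_ever"),
                           by = "pond_id")
  grid$drought <- grid$year %in% scenario$drought_years
  p_fall <- ifelse(grid$drought, scenario$p_dry_fall_drought, scenario$p_dry_fall_base)
  p_spring <- ifelse(grid$drought, scenario$p_dry_spring_drought, scenario$p_dry_spring_base)
  z_it <- persistence * z_pond[match(grid$pond_id, landscape$pond_id)] +
    sqrt(1 - persistence^2) * stats::rnorm(nrow(grid))
  # z_it is standard normal marginally, so pnorm(z_it) < p is Bernoulli(p)
  grid$dried_prev_fall <- stats::pnorm(z_it) < p_fall
  grid$dry_before_sampling <- grid$dried_prev_fall & (stats::runif(nrow(grid)) < p_spring)
  h_mean <- ifelse(grid$drought, scenario$hydroperiod_drought, scenario$hydroperiod_base)
  grid$hydroperiod <- pmin(pmax(stats::rnorm(nrow(grid), h_mean, 0.06), 0.05), 1)
  cond <- pmin(pmax(stats::rnorm(nrow(grid), ifelse(grid$drought, 0.75, 0.85), 0.12), 0), 1)
  grid$area <- grid$max_area_ever * cond
  grid$propensity <- z_pond[match(grid$pond_id, landscape$pond_id)]
  dplyr::select(grid, "pond_id", "year", "drought", "dried_prev_fall",
                "dry_before_sampling", "hydroperiod", "area", "propensity")
}

#' Simulate a metacommunity with density-dependent colonisation and extinction
#'
#' Annual update per pond and species: (i) Ricker growth toward the
#' predator-dependent carrying capacity with truncated lognormal noise;
#' (ii) stochastic extinction with probability declining in log density;
#' (iii) colonisation of empty ponds with probability
#' `1 - exp(-c * sum_j N_j exp(-alpha d_ij))`, where `N_j` are larval
#' population sizes (density times wet area). Every colonisation, extinction
#' and carrying-capacity value is recorded in a truth log so parameter
#' recovery and replay tests have full ground truth.
#'
#' @param landscape,hydro from the generators above.
#' @param params a [species_params()] (or list of them for several species).
#' @param predator a [predator_model()].
#' @param init tibble `pond_id`, `density` of initially occupied ponds.
#' @param seed RNG seed.
#' @return list with `survey` (tibble `pond_id`, `year`, `season`,
#'   `species_id`, `density`, `present`) and `truth` (tibble of events:
#'   `year`, `pond_id`, `species_id`, `event`, `density`, `K`).
#' @export
simulate_metacommunity <- function(landscape, hydro, params, predator = predator_model(),
                                   init, seed = 1L) {
  if (inherits(params, "species_params")) params <- list(params)
  set.seed(seed)
  years <- sort(unique(hydro$year))
  ponds <- landscape$pond_id
  d <- as.matrix(stats::dist(cbind(landscape$x, landscape$y)))
  dimnames(d) <- list(ponds, ponds)
  hyd <- dplyr::arrange(hydro, .data$pond_id, .data$year)
  hkey <- paste(hyd$pond_id, hyd$year)
  hrow <- function(p, yr) match(paste(p, yr), hkey)

  surveys <- list(); truths <- list()
  for (sp in params) {
    N <- stats::setNames(rep(0, length(ponds)), ponds)
    N[init$pond_id] <- init$density
    kern <- exp(-sp$alpha * d); diag(kern) <- 0
    log_rows <- list(); out_rows <- list()
    for (yr in years) {
      rows <- hrow(ponds, yr)
      K <- vapply(seq_along(ponds), function(i) {
        k_effective(sp, predator,
          canopy = landscape$canopy[i],
          dried_prev_fall = hyd$dried_prev_fall[rows[i]],
          dry_spring = hyd$dry_before_sampling[rows[i]],
          drought = isTRUE(hyd$drought[rows[i]]),
          quality = if ("quality" %in% names(landscape)) landscape$quality[i] else 1
        )
      }, 0)
      # compensatory (Beverton-Holt) growth toward K with truncated lognormal
      # noise; compensatory rather than overcompensatory so a dense population
      # relaxes to a lowered K instead of crashing past it
      occ <- N > 0
      z <- pmin(pmax(stats::rnorm(length(ponds)), -2.5), 2.5)
      lam <- exp(sp$r)
      grown <- ifelse(occ,
        N * lam / (1 + (lam - 1) * N / K) * exp(sp$noise_sd * z - sp$noise_sd^2 / 2), 0)
      if (any(!is.finite(grown))) {
        stop("non-finite density update in year ", yr, " at pond ",
             ponds[which(!is.finite(grown))[1]])
      }
      N <- grown
      # extinction: density-dependent and rescue-moderated (kernel-weighted
      # immigration pressure suppresses local extinction), plus certain
      # cohort failure when the pond is dry in early spring
      area <- pmax(hyd$area[rows], 0)
      gate <- ifelse(N >= sp$dispersal_threshold, 1, sp$subthreshold_dispersal)
      S_rescue <- as.numeric(kern %*% (N * area * gate))
      pext <- extinction_probability(sp, N) * exp(-S_rescue / sp$rescue_scale)
      pext[hyd$dry_before_sampling[rows]] <- 1
      dies <- occ & (stats::runif(length(ponds)) < pext)
      if (any(dies)) {
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          year = yr, pond_id = ponds[dies], species_id = sp$species_id,
          event = "extinction", density = N[dies], K = K[dies]
        )
        N[dies] <- 0
      }
      # colonisation of empty ponds from kernel-weighted sources; ponds
      # below the dispersal threshold export only a trickle of colonists
      gate <- ifelse(N >= sp$dispersal_threshold, 1, sp$subthreshold_dispersal)
      S <- as.numeric(kern %*% (N * area * gate))
      empty <- N == 0 & !hyd$dry_before_sampling[rows]
      pcol <- 1 - (1 - sp$background_colonisation) * exp(-sp$c_col * S)
      newly <- empty & (stats::runif(length(ponds)) < pcol)
      if (any(newly)) {
        N[newly] <- sp$colonist_density
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          year = yr, pond_id = ponds[newly], species_id = sp$species_id,
          event = "colonization", density = sp$colonist_density, K = K[newly]
        )
      }
      out_rows[[length(out_rows) + 1L]] <- tibble::tibble(
        pond_id = ponds, year = yr, season = "may", species_id = sp$species_id,
        density = N, present = N > 0, K = K
      )
    }
    surveys[[sp$species_id]] <- dplyr::bind_rows(out_rows)
    truths[[sp$species_id]] <- dplyr::bind_rows(log_rows)
  }
  survey <- dplyr::bind_rows(surveys)
  list(
    survey = dplyr::select(survey, -"K"),
    truth = dplyr::bind_rows(truths),
    K_table = dplyr::select(survey, "pond_id", "year", "species_id", "K")
  )
}

#' Canned 15-year chorus-frog drought scenario
#'
#' A 37-pond, two-region landscape surveyed 1996-2010 with a 1999-2007
#' drought. At the default parameters the drought suppresses pond predators,
#' local densities rise toward the dried-pond carrying capacity, and the
#' kernel-weighted colonisation pressure then drives an occupancy expansion
#' that lags the density increase; when the drought breaks, densities fall
#' and occupancy collapses. Both transitions are detectable by [stars()] on
#' the simulated series. With `drought = FALSE` the landscape stays in the
#' base climate and no regime shift is expected.
#'
#' @param seed RNG seed controlling every stochastic component.
#' @param drought include the drought period?
#' @param n_init number of initially occupied (western) ponds.
#' @return list with `landscape`, `hydro`, `survey`, `truth`, `yearly`
#'   (tibble `year`, `n_occupied`, `mean_density`, `ln_mean_density`).
#' @export
scenario_chorus_frog <- function(seed = 1L, drought = TRUE, n_init = 5, burn_in = 30) {
  years <- (1996 - burn_in):2010
  scen <- climate_scenario(years = years,
                           drought_years = if (drought) 1999:2007 else integer(0))
  land <- generate_landscape(canopy_fraction_open = 0.65, seed = seed)
  hydro <- simulate_hydrology(land, scen, persistence = 0.9, seed = seed + 1L)
  sp <- species_params()
  # pre-drought refuges: open ponds of intermediate hydroperiod -- wet in
  # ordinary years (so they hold predators and a modest carrying capacity)
  # but among the first to dry under drought forcing
  prop <- dplyr::distinct(hydro, .data$pond_id, .data$propensity)
  cand <- dplyr::left_join(prop, land, by = "pond_id")
  cand <- dplyr::filter(cand, .data$canopy == "open",
                        .data$propensity > -0.4, .data$propensity < 1.2)
  cand <- dplyr::arrange(cand, .data$region, dplyr::desc(.data$quality),
                         dplyr::desc(.data$propensity))
  set.seed(seed + 2L)
  n_west <- min(ceiling(n_init * 0.6), sum(cand$region == "west"))
  init_ids <- c(
    utils::head(cand$pond_id[cand$region == "west"], n_west),
    utils::head(cand$pond_id[cand$region == "east"], n_init - n_west)
  )
  init <- tibble::tibble(pond_id = init_ids, density = 1.5)
  sim <- simulate_metacommunity(land, hydro, sp, init = init, seed = seed + 3L)
  sim$survey <- dplyr::filter(sim$survey, .data$year >= 1996)
  sim$truth <- dplyr::filter(sim$truth, .data$year >= 1996)
  sim$K_table <- dplyr::filter(sim$K_table, .data$year >= 1996)
  hydro <- dplyr::filter(hydro, .data$year >= 1996)
  yearly <- dplyr::summarise(
    dplyr::group_by(sim$survey, .data$year),
    n_occupied = sum(.data$present),
    mean_density = ifelse(sum(.data$present) > 0,
      mean(.data$density[.data$present]), NA_real_),
    .groups = "drop"
  )
  yearly$ln_mean_density <- log(yearly$mean_density)
  list(landscape = land, hydro = hydro, survey = sim$survey, truth = sim$truth,
       K_table = sim$K_table, yearly = yearly, scenario = scen)
}
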