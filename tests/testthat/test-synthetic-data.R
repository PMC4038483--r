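test_that("landscape generation is deterministic with the documented geometry", {
  l1 <- generate_landscape(seed = 4)
  l2 <- generate_landscape(seed = 4)
  expect_identical(l1, l2)
  expect_equal(nrow(l1), 37)

  d <- as.matrix(dist(cbind(l1$x, l1$y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(mean(nn), 200)              # within-region nearest neighbours
  west <- l1$region == "west"
  cross <- d[west, !west]
  expect_gt(min(cross), 800)            # regions well separated

  one <- generate_landscape(n_ponds = 10, region_split = c(west = 1, east = 0), seed = 1)
  expect_true(all(one$region == "west"))
  expect_error(generate_landscape(n_ponds = 1), "two ponds")
  expect_error(generate_landscape(region_gap = 0), "degenerate")
})

test_that("hydrology respects drying probabilities and drought ordering", {
  land <- generate_landscape(seed = 2)
  scen <- climate_scenario(years = 1996:2010, drought_years = 1999:2007)
  h <- simulate_hydrology(land, scen, seed = 9)
  expect_true(all(h$hydroperiod >= 0 & h$hydroperiod <= 1))
  expect_true(all(h$area >= 0))
  # drought years are drier on average, by construction
  expect_lt(mean(h$hydroperiod[h$drought]), mean(h$hydroperiod[!h$drought]))

  # p_dry = 0: no pond ever dries
  none <- simulate_hydrology(land, climate_scenario(
    drought_years = integer(0), p_dry_fall_base = 0, p_dry_fall_drought = 0
  ), seed = 9)
  expect_false(any(none$dried_prev_fall))

  # empirical drying fraction within 3 binomial SEs at p = 0.8
  scen8 <- climate_scenario(years = 1:14, drought_years = 1:14,
                            p_dry_fall_drought = 0.8)
  h8 <- simulate_hydrology(land, scen8, seed = 10)
  n <- nrow(h8)                          # 37 ponds x 14 years = 518 pond-years
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(mean(h8$dried_prev_fall) - 0.8), 3 * se)

  expect_error(climate_scenario(p_dry_fall_base = 1.4), "0, 1")
  expect_error(simulate_hydrology(land, scen, persistence = 1), "persistence")
})

test_that("two-pond colonisation matches the closed-form kernel probability", {
  land <- tibble::tibble(pond_id = c("A", "B"), x = c(0, 150), y = 0,
                         region = "west", canopy = "open", quality = 1,
                         max_area_ever = c(100, 100))
  hyd <- tidyr::expand_grid(pond_id = c("A", "B"), year = 1:400)
  hyd$drought <- FALSE; hyd$dried_prev_fall <- FALSE
  hyd$dry_before_sampling <- FALSE; hyd$hydroperiod <- 0.9
  hyd$area <- 100
  # hold the source above the dispersal gate and switch off noise/extinction
  sp <- species_params(c_col = 2e-4, noise_sd = 1e-9, r = 1e-9,
                       dispersal_threshold = 0, subthreshold_dispersal = 1,
                       background_colonisation = 0,
                       ext_anchor_low = c(1e-6, 1e-12), ext_anchor_high = c(1, 1e-12),
                       rescue_scale = Inf)
  init <- tibble::tibble(pond_id = "A", density = 10)
  sim <- simulate_metacommunity(land, hyd, sp, init = init, seed = 3)
  # expected yearly colonisation probability of B
  S <- 10 * 100 * exp(-150 / 125)
  p_expected <- 1 - exp(-2e-4 * S)
  col_years <- sim$truth$year[sim$truth$event == "colonization" & sim$truth$pond_id == "B"]
  # B empties never (no extinction), so only the first colonisation counts;
  # estimate p from the geometric waiting time over many replicates
  waits <- vapply(1:60, function(k) {
    s <- simulate_metacommunity(land, hyd, sp, init = init, seed = 100 + k)
    w <- s$truth$year[s$truth$event == "colonization" & s$truth$pond_id == "B"]
    if (length(w) == 0) 400 else min(w)
  }, 0)
  p_hat <- 1 / mean(waits)
  expect_lt(abs(p_hat - p_expected), 0.35 * p_expected + 0.005)
})

test_that("c = 0 and no background yields no colonisations ever", {
  land <- generate_landscape(n_ponds = 8, seed = 5)
  scen <- climate_scenario(years = 1:10, drought_years = integer(0))
  hyd <- simulate_hydrology(land, scen, seed = 5)
  sp <- species_params(c_col = 0, background_colonisation = 0)
  init <- tibble::tibble(pond_id = land$pond_id[1:3], density = 3)
  sim <- simulate_metacommunity(land, hyd, sp, init = init, seed = 6)
  expect_false(any(sim$truth$event == "colonization"))
  # occupancy can only shrink
  occ <- dplyr::summarise(dplyr::group_by(sim$survey, .data$year),
                          n = sum(.data$present))
  expect_true(all(diff(occ$n) <= 0))
})

test_that("an isolated population with extinction off persists unchanged in occupancy", {
  land <- tibble::tibble(pond_id = "A", x = 0, y = 0, region = "west",
                         canopy = "open", quality = 1, max_area_ever = 100)
  hyd <- tibble::tibble(pond_id = "A", year = 1:20, drought = FALSE,
                        dried_prev_fall = FALSE, dry_before_sampling = FALSE,
                        hydroperiod = 0.9, area = 90)
  sp <- species_params(ext_anchor_low = c(1e-6, 1e-12), ext_anchor_high = c(1, 1e-12),
                       background_colonisation = 0)
  sim <- simulate_metacommunity(land, hyd, sp,
                                init = tibble::tibble(pond_id = "A", density = 2),
                                seed = 7)
  expect_true(all(sim$survey$present))
})

test_that("with dispersal off and extinction on, extinction is absorbing", {
  land <- generate_landscape(n_ponds = 6, seed = 8)
  scen <- climate_scenario(years = 1:60, drought_years = integer(0))
  hyd <- simulate_hydrology(land, scen, seed = 8)
  sp <- species_params(c_col = 0, background_colonisation = 0)
  sim <- simulate_metacommunity(land, hyd, sp,
    init = tibble::tibble(pond_id = land$pond_id[1:4], density = 2), seed = 9)
  occ <- dplyr::summarise(dplyr::group_by(sim$survey, .data$year),
                          n = sum(.data$present))
  expect_equal(occ$n[60], 0)
})

test_that("the truth log replays exactly into the occupancy matrix", {
  b <- scenario_chorus_frog(seed = 3, burn_in = 0)
  occ <- dplyr::select(b$survey, "pond_id", "year", "present")
  # replay: start from the initial year's presences, apply logged events
  years <- sort(unique(occ$year))
  state <- stats::setNames(occ$present[occ$year == years[1]],
                           occ$pond_id[occ$year == years[1]])
  for (yr in years[-1]) {
    ev <- b$truth[b$truth$year == yr, ]
    state[ev$pond_id[ev$event == "extinction"]] <- FALSE
    state[ev$pond_id[ev$event == "colonization"]] <- TRUE
    now <- stats::setNames(occ$present[occ$year == yr], occ$pond_id[occ$year == yr])
    expect_equal(state[names(now)], now)
  }
})

test_that("densities stay non-negative and bounded by K times the overshoot cap", {
  b <- scenario_chorus_frog(seed = 6)
  expect_true(all(b$survey$density >= 0))
  j <- dplyr::left_join(b$survey, b$K_table,
                        by = c("pond_id", "year", "species_id"))
  # Beverton-Holt is compensatory: the only overshoot comes from one year of
  # truncated lognormal noise on top of lambda growth
  sp <- species_params()
  cap <- exp(sp$r) * exp(2.5 * sp$noise_sd)
  expect_true(all(j$density <= pmax(j$K, sp$colonist_density) * cap + 1e-9))
})

test_that("the canned scenario is reproducible and drought-responsive", {
  a <- scenario_chorus_frog(seed = 2)
  b <- scenario_chorus_frog(seed = 2)
  expect_identical(a$survey, b$survey)
  # drought runs reach higher occupancy than paired no-drought runs (ensemble)
  diffs <- vapply(1:8, function(s) {
    on <- scenario_chorus_frog(seed = s * 31)$yearly
    off <- scenario_chorus_frog(seed = s * 31, drought = FALSE)$yearly
    max(on$n_occupied) - max(off$n_occupied)
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("extinction risk is anchored near 0.40 below 1.5 per m2", {
  sp <- species_params()
  expect_equal(extinction_probability(sp, 1.5), 0.40, tolerance = 1e-9)
  expect_equal(extinction_probability(sp, 0), 1)
  # aggregate risk for sub-threshold pond-years in simulation output
  probs <- c()
  for (s in 1:6) {
    b <- scenario_chorus_frog(seed = s * 7)
    sv <- b$survey
    nxt <- dplyr::mutate(sv, year = .data$year - 1)
    joined <- dplyr::inner_join(
      dplyr::filter(sv, .data$present, .data$density < 1.5),
      dplyr::select(nxt, "pond_id", "year", next_present = "present"),
      by = c("pond_id", "year")
    )
    probs <- c(probs, !joined$next_present)
  }
  expect_equal(mean(probs), 0.40, tolerance = 0.15)
})
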