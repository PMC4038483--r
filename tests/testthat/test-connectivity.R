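test_that("Hanski index matches closed forms and a double-loop oracle", {
  one <- tibble::tibble(pond_id = "A", x = 0, y = 0)
  expect_equal(hanski_index(one, tibble::tibble(pond_id = "A", n = 50))$hanski_index, 0)

  two <- tibble::tibble(pond_id = c("A", "B"), x = c(0, 125), y = 0)
  pops <- tibble::tibble(pond_id = c("A", "B"), n = c(0, 100))
  h <- hanski_index(two, pops, alpha = 1 / 125)
  expect_equal(h$hanski_index[h$pond_id == "A"], 100 * exp(-1), tolerance = 1e-9)

  set.seed(3)
  p5 <- tibble::tibble(pond_id = paste0("p", 1:5),
                       x = runif(5, 0, 500), y = runif(5, 0, 500))
  n5 <- tibble::tibble(pond_id = p5$pond_id, n = runif(5, 0, 100))
  got <- hanski_index(p5, n5, alpha = 0.008)
  oracle <- vapply(1:5, function(i) {
    s <- 0
    for (j in 1:5) if (j != i) {
      d <- sqrt((p5$x[i] - p5$x[j])^2 + (p5$y[i] - p5$y[j])^2)
      s <- s + n5$n[j] * exp(-0.008 * d)
    }
    s
  }, 0)
  expect_equal(got$hanski_index, oracle, tolerance = 1e-9)

  # invariant to adding an unoccupied pond
  p6 <- dplyr::bind_rows(p5, tibble::tibble(pond_id = "p6", x = 10, y = 10))
  n6 <- dplyr::bind_rows(n5, tibble::tibble(pond_id = "p6", n = 0))
  got6 <- hanski_index(p6, n6, alpha = 0.008)
  expect_equal(got6$hanski_index[1:5], got$hanski_index, tolerance = 1e-9)

  expect_error(hanski_index(two, tibble::tibble(pond_id = "A", n = -1)), "non-negative")
})

test_that("effective resistance obeys Ohm, series and parallel laws", {
  # 1 x 2 grid: a single edge of conductance 2/(f_a+f_b)
  ra <- friction_raster(matrix(c(2, 4), 1, 2), cellsize = 1)
  cells <- tibble::tibble(pond_id = c("a", "b"), row = 1, col = c(1, 2))
  R <- effective_resistance(ra, cells)
  expect_equal(R["a", "b"], (2 + 4) / 2)
  # series: 1 x 3 line adds resistances
  rs <- friction_raster(matrix(c(2, 4, 6), 1, 3), cellsize = 1)
  cs <- tibble::tibble(pond_id = c("a", "c"), row = 1, col = c(1, 3))
  Rs <- effective_resistance(rs, cs)
  expect_equal(Rs["a", "c"], (2 + 4) / 2 + (4 + 6) / 2)
  # parallel: a 2 x 2 loop between opposite corners halves the series value
  rp <- friction_raster(matrix(1, 2, 2), cellsize = 1)
  cp <- tibble::tibble(pond_id = c("a", "d"), row = c(1, 2), col = c(1, 2))
  Rp <- effective_resistance(rp, cp)
  expect_equal(Rp["a", "d"], 1)    # two parallel 2-ohm routes
})

test_that("grid resistances equal the Laplacian pseudoinverse oracle", {
  n <- 3
  ra <- uniform_raster(n)
  cells <- tibble::tibble(pond_id = c("a", "b", "c"),
                          row = c(1, 3, 2), col = c(1, 3, 2))
  R <- effective_resistance(ra, cells)
  Ro <- resistance_oracle(grid_laplacian(n))
  id <- function(r, c) (c - 1) * n + r
  expect_equal(R["a", "b"], Ro[id(1, 1), id(3, 3)], tolerance = 1e-8)
  expect_equal(R["a", "c"], Ro[id(1, 1), id(2, 2)], tolerance = 1e-8)
  # symmetry, zero diagonal, triangle inequality
  expect_equal(R, t(R))
  expect_true(all(diag(R) == 0))
  expect_lte(R["a", "b"], R["a", "c"] + R["c", "b"] + 1e-9)
})

test_that("adding a parallel path never increases resistance (Rayleigh)", {
  line <- friction_raster(matrix(1, 1, 3), cellsize = 1)
  cells <- tibble::tibble(pond_id = c("a", "b"), row = 1, col = c(1, 3))
  R1 <- effective_resistance(line, cells)["a", "b"]
  loop <- friction_raster(matrix(1, 2, 3), cellsize = 1)
  R2 <- effective_resistance(loop, cells)["a", "b"]
  expect_lte(R2, R1 + 1e-12)
})

test_that("disconnected ponds get infinite resistance and nodata ponds error", {
  m <- matrix(1, 1, 5); m[1, 3] <- NA
  ra <- friction_raster(matrix(1, 1, 5), 1); ra$values[1, 3] <- NA
  cells <- tibble::tibble(pond_id = c("a", "b"), row = 1, col = c(1, 5))
  R <- effective_resistance(ra, cells)
  expect_equal(R["a", "b"], Inf)
  bad <- tibble::tibble(pond_id = "x", row = 1, col = 3)
  expect_error(effective_resistance(ra, bad), "nodata")
})

test_that("occupied-vs-unoccupied comparison matches the pooled-t closed form", {
  conn <- tibble::tibble(pond_id = rep(c("A", "B", "C", "D"), 2),
                         year = rep(1:2, each = 4),
                         hanski_index = c(5, 6, 1, 2, 5.5, 6.5, 1.5, 2.2))
  occ <- tibble::tibble(pond_id = rep(c("A", "B", "C", "D"), 2),
                        year = rep(1:2, each = 4),
                        present = rep(c(TRUE, TRUE, FALSE, FALSE), 2))
  res <- compare_occupied(conn, occ)
  g1 <- c(5, 6, 5.5, 6.5); g0 <- c(1, 2, 1.5, 2.2)
  sp2 <- (3 * var(g1) + 3 * var(g0)) / 6
  t_hand <- (mean(g1) - mean(g0)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 6)
  expect_equal(res$ratio, mean(g1) / mean(g0))

  # identical groups: t = 0, p = 1
  occ_same <- dplyr::mutate(occ, present = rep(c(TRUE, FALSE), 4))
  conn_same <- dplyr::mutate(conn, hanski_index = 3)
  res0 <- compare_occupied(conn_same, occ_same)
  expect_true(is.na(res0$t) || abs(res0$t) < 1e-12)
})

test_that("connected rare species show up as a positive connectivity effect", {
  set.seed(17)
  hits <- 0
  for (rep in 1:20) {
    land <- generate_landscape(n_ponds = 20, seed = rep)
    pops <- tibble::tibble(pond_id = land$pond_id, n = runif(20, 50, 150))
    h <- hanski_index(land, pops)
    # occupy the most-connected third of ponds
    occ <- tibble::tibble(pond_id = h$pond_id, year = 1,
                          present = rank(-h$hanski_index) <= 7)
    hy <- dplyr::mutate(h, year = 1)
    res <- compare_occupied(hy, occ)
    if (res$t > 0 && res$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)   # >= 90% of replicates significant and positive
})

test_that("regional resistance summaries are permutation invariant", {
  set.seed(23)
  ra <- uniform_raster(6)
  cells <- tibble::tibble(pond_id = paste0("p", 1:4),
                          row = c(1, 2, 5, 6), col = c(1, 2, 5, 6))
  R <- effective_resistance(ra, cells)
  regions <- c(p1 = "w", p2 = "w", p3 = "e", p4 = "e")
  s1 <- region_resistance_summary(R, regions)
  perm <- c(3, 1, 4, 2)
  s2 <- region_resistance_summary(R[perm, perm], regions)
  expect_equal(
    dplyr::arrange(s1, .data$region)$mean_resistance,
    dplyr::arrange(s2, .data$region)$mean_resistance
  )
  # one-region landscape: global equals the region mean
  sall <- region_resistance_summary(R, c(p1 = "a", p2 = "a", p3 = "a", p4 = "a"))
  expect_equal(sall$mean_resistance[1], sall$mean_resistance[2])
})

test_that("two clusters joined by a bottleneck raise the global mean", {
  # 2 x 7 grid with a single-cell corridor in the middle column
  m <- matrix(1, 2, 7)
  m[2, 4] <- NA          # bottleneck: only the top cell connects the halves
  ra <- friction_raster(matrix(1, 2, 7), 1); ra$values[2, 4] <- NA
  cells <- tibble::tibble(pond_id = paste0("p", 1:4),
                          row = c(1, 2, 1, 2), col = c(1, 1, 7, 7))
  R <- effective_resistance(ra, cells)
  regions <- c(p1 = "w", p2 = "w", p3 = "e", p4 = "e")
  s <- region_resistance_summary(R, regions)
  glob <- s$mean_resistance[s$region == "global"]
  within <- s$mean_resistance[s$region != "global"]
  expect_true(all(glob > within))
})
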