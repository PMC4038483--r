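# small in-code fixtures shared across test files

tiny_survey <- function() {
  tibble::tibble(
    pond_id = c("A", "A", "A", "B", "B", "C"),
    year = c(2000L, 2000L, 2001L, 2000L, 2001L, 2001L),
    season = c("may", "july", "may", "may", "may", "july"),
    species_id = c("frog", "frog", "frog", "frog", "frog", "frog"),
    density = c(2, 5, 1, 0, 3, 0)
  )
}

write_tiny_survey <- function(path = tempfile(fileext = ".csv")) {
  readr::write_csv(tiny_survey(), path)
  path
}

tiny_ponds <- function() {
  tibble::tibble(
    pond_id = c("A", "B", "C"),
    x = c(0, 100, 250), y = c(0, 0, 0),
    region = c("west", "west", "east"),
    canopy = c("open", "open", "closed"),
    max_area_ever = c(100, 200, 50)
  )
}

# uniform friction raster helper
uniform_raster <- function(n = 3, f = 1, cellsize = 1) {
  friction_raster(matrix(f, n, n), cellsize = cellsize)
}

# dense-matrix effective resistance oracle via Laplacian pseudoinverse
resistance_oracle <- function(L) {
  Li <- MASS::ginv(as.matrix(L))
  n <- nrow(Li)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    R[i, j] <- Li[i, i] + Li[j, j] - 2 * Li[i, j]
  }
  R
}

# grid graph Laplacian for a uniform-friction n x n raster (4-neighbour),
# edge conductance 2/(f+f)/cellsize
grid_laplacian <- function(n, f = 1, cellsize = 1) {
  id <- function(r, c) (c - 1) * n + r
  N <- n * n
  L <- matrix(0, N, N)
  g <- (2 / (2 * f)) / cellsize
  for (r in seq_len(n)) for (c in seq_len(n)) {
    if (r < n) { a <- id(r, c); b <- id(r + 1, c); L[a, b] <- L[b, a] <- L[a, b] - g }
    if (c < n) { a <- id(r, c); b <- id(r, c + 1); L[a, b] <- L[b, a] <- L[a, b] - g }
  }
  diag(L) <- -rowSums(L)
  L
}
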