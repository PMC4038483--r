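#' Published chorus frog time series (1996-2010)
#'
#' Fifteen-year series for the western chorus frog (*Pseudacris triseriata*)
#' on a 37-pond reserve landscape: the number of occupied ponds each year and
#' the natural log of mean larval density (individuals per m^2) in occupied
#' ponds. The species transitioned from rare and narrowly distributed to
#' common and widely distributed during a multi-year drought, and back again
#' when the drought broke, making the pair of series the canonical worked
#' example for [stars()] and [cross_correlation()].
#'
#' @return tibble with columns `year`, `occupancy` (ponds occupied) and
#'   `ln_density` (ln mean larval density in occupied ponds).
#' @export
chorus_frog_series <- function() {
  tibble::tibble(
    year = 1996:2010,
    occupancy = c(5, 6, 3, 3, 6, 21, 20, 15, 17, 17, 19, 20, 21, 21, 8),
    ln_density = c(
      0.262, 0.034, 0.693, 0.949, 1.966, 1.030, 2.055, 1.351,
      0.095, 1.133, 1.165, 1.672, 1.655, 1.115, 0.523
    )
  )
}

#' Published model-selection table for the constrained d-a relationship
#'
#' Candidate-model summaries (residual sum of squares, parameter count K and
#' sample size) for the constrained interspecific distribution-abundance
#' relationship across 13 amphibian species. K follows the convention that the
#' error variance counts as a parameter (mean-only model: K = 2). Feeding this
#' table to [aicc_rank()] reproduces the published AICc ranking, Akaike
#' weights and evidence ratios.
#'
#' @return tibble with columns `model`, `K`, `n`, `rss`.
#' @export
da_constrained_model_table <- function() {
  tibble::tibble(
    model = c(
      "saturating", "seg_horizontal_horizontal", "linear",
      "seg_sloping_horizontal", "mean", "seg_sloping_sloping"
    ),
    K = c(3, 4, 3, 5, 2, 6),
    n = 13L,
    rss = c(0.16, 0.13, 0.32, 0.15, 0.58, 0.16)
  )
}

#' Published chorus frog pond-suitability occupancy frequencies
#'
#' Frequencies of chorus frog occupancy by pond category during the years the
#' regional population was large and the species was not dispersal limited:
#' open-canopy ponds that dried the previous fall, open-canopy ponds that did
#' not dry, and closed-canopy ponds. Used as weights by
#' [weighted_suitability()] to estimate the expected number of suitable ponds
#' when the species is rare.
#'
#' @return named numeric vector of occupancy frequencies.
#' @export
suitability_frequencies <- function() {
  c(open_dried = 0.93, open_not_dried = 0.40, closed = 0.32)
}
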