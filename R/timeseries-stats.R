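#' Lagged cross-correlation between two yearly series
#'
#' Pearson correlations on overlapping pairs at each lag. The sign convention
#' is fixed: a positive lag means the first series leads (its value in year
#' `t` is paired with the second series' value in year `t + lag`), so
#' `cross_correlation(a, b, k)` at lag `k` equals `cross_correlation(b, a, -k)`
#' at lag `-k`. No detrending is applied. Two-sided p-values come from the t
#' transform of r with n - 2 df.
#'
#' @param a,b numeric vectors on aligned year indices.
#' @param max_lag largest lead/lag (years) to evaluate.
#' @param min_overlap smallest number of overlapping pairs to report a lag.
#' @return tibble `lag`, `r`, `n`, `p`. Lags with insufficient overlap are
#'   omitted.
#' @export
cross_correlation <- function(a, b, max_lag = 3, min_overlap = 3) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  purrr::map_dfr(seq(-max_lag, max_lag), function(k) {
    if (k >= 0) {
      aa <- a[seq_len(n - k)]
      bb <- b[seq_len(n - k) + k]
    } else {
      aa <- a[seq_len(n + k) - k]
      bb <- b[seq_len(n + k)]
    }
    m <- length(aa)
    if (m < min_overlap) return(tibble::tibble())
    if (stats::sd(aa) == 0 || stats::sd(bb) == 0) {
      return(tibble::tibble(lag = k, r = NA_real_, n = m, p = NA_real_))
    }
    r <- stats::cor(aa, bb)
    tstat <- r * sqrt((m - 2) / (1 - r^2))
    tibble::tibble(lag = k, r = r, n = m,
                   p = 2 * stats::pt(abs(tstat), m - 2, lower.tail = FALSE))
  })
}

#' Availability-tracking diagnostics
#'
#' How closely a species' occupancy tracks the availability of suitable
#' ponds: the lag-0 Pearson correlation between the two counts, and the mean
#' yearly ratio of occupied to available ponds. Years with zero available
#' ponds are skipped with a warning. Species that colonise most suitable
#' habitat as it appears show high correlations and ratios near 1; dispersal-
#' limited species do not.
#'
#' @param occupied,available integer vectors of yearly counts, aligned.
#' @return tibble `r`, `p`, `mean_ratio`, `n_years`.
#' @export
tracking_metrics <- function(occupied, available) {
  stopifnot(length(occupied) == length(available))
  keep <- available > 0
  if (any(!keep)) warning(sum(!keep), " year(s) with zero available ponds skipped")
  occ <- occupied[keep]; av <- available[keep]
  if (stats::sd(occ) == 0 || stats::sd(av) == 0) {
    r <- if (all(occ == av)) 1 else NA_real_
    p <- NA_real_
  } else {
    r <- stats::cor(occ, av)
    tstat <- r * sqrt((length(occ) - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), length(occ) - 2, lower.tail = FALSE)
  }
  tibble::tibble(r = r, p = p, mean_ratio = mean(occ / av), n_years = length(occ))
}

#' Intraspecific d-a relationship across years
#'
#' Runs the candidate model suite on one species' yearly (mean density in
#' occupied ponds, ponds occupied) pairs, optionally within a region and
#' optionally after excluding Cook's-distance outliers under the linear fit.
#'
#' @param summaries tibble with columns `year`, `mean_density`, `n_occupied`
#'   and optionally `region`.
#' @param region optional region filter.
#' @param exclude_outliers drop points with Cook's distance above `4/n` before
#'   fitting.
#' @param min_years minimum number of yearly points required.
#' @param models,... passed to [da_model_suite()].
#' @return list as from [da_model_suite()], with an `excluded` element giving
#'   dropped years.
#' @export
intraspecific_da <- function(summaries, region = NULL, exclude_outliers = FALSE,
                             min_years = 6,
                             models = c("saturating", "seg_horizontal_horizontal",
                                        "linear", "mean"), ...) {
  if (!is.null(region)) {
    summaries <- dplyr::filter(summaries, .data$region == !!region)
  }
  summaries <- dplyr::filter(summaries, is.finite(.data$mean_density))
  if (nrow(summaries) < min_years) {
    stop("need at least ", min_years, " years; got ", nrow(summaries))
  }
  excluded <- tibble::tibble(year = integer(0), cooks_d = numeric(0))
  if (exclude_outliers) {
    cd <- cooks_outliers(summaries$mean_density, summaries$n_occupied)
    if (any(cd$flagged)) {
      excluded <- tibble::tibble(
        year = summaries$year[cd$flagged],
        cooks_d = cd$cooks_d[cd$flagged]
      )
      summaries <- summaries[!cd$flagged, ]
    }
  }
  out <- da_model_suite(summaries$mean_density, summaries$n_occupied, models = models, ...)
  out$excluded <- excluded
  out
}
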