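#' Candidate models for distribution-abundance (d-a) curves
#'
#' Fits one of the candidate model families used for interspecific and
#' intraspecific d-a relationships: a mean-only model, ordinary linear
#' regression, the saturating curve `y = a (1 - b^x)`, and four segmented
#' (piecewise) families with a breakpoint. Parameter counts `K` include the
#' error variance, so the mean-only model has `K = 2`, linear and saturating
#' `K = 3`, horizontal/horizontal `K = 4`, sloping/horizontal and
#' horizontal/sloping `K = 5`, and sloping/sloping `K = 6`. Many software
#' packages count parameters without the variance; this convention matters
#' when comparing AICc across sources.
#'
#' @param x,y numeric vectors (abundance axis, occupancy axis).
#' @param family one of `"mean"`, `"linear"`, `"saturating"`,
#'   `"seg_horizontal_horizontal"`, `"seg_sloping_horizontal"`,
#'   `"seg_horizontal_sloping"`, `"seg_sloping_sloping"`.
#' @param ... passed to the family-specific fitter ([fit_saturating()] or
#'   [fit_segmented()]).
#' @return object of class `da_fit`: list with `family`, `params`, `K`, `n`,
#'   `rss`, `r2`, `fitted`, and for segmented families a `breakpoint` element.
#' @export
fit_da <- function(x, y, family = c(
                     "mean", "linear", "saturating",
                     "seg_horizontal_horizontal", "seg_sloping_horizontal",
                     "seg_horizontal_sloping", "seg_sloping_sloping"
                   ), ...) {
  family <- match.arg(family)
  stopifnot(length(x) == length(y))
  switch(family,
    mean = {
      mu <- mean(y)
      new_da_fit("mean", list(mean = mu), K = 2, x = x, y = y, fitted = rep(mu, length(y)))
    },
    linear = {
      fit <- stats::lm(y ~ x)
      new_da_fit("linear",
        list(intercept = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2])),
        K = 3, x = x, y = y, fitted = unname(stats::fitted(fit))
      )
    },
    saturating = fit_saturating(x, y, ...),
    fit_segmented(x, y, family = family, ...)
  )
}

new_da_fit <- function(family, params, K, x, y, fitted, breakpoint = NULL, extra = list()) {
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  structure(
    c(list(
      family = family, params = params, K = K, n = length(y),
      rss = rss, r2 = if (tss > 0) 1 - rss / tss else NA_real_,
      x = x, y = y, fitted = fitted, breakpoint = breakpoint
    ), extra),
    class = "da_fit"
  )
}

#' @export
print.da_fit <- function(x, ...) {
  cat(sprintf("d-a model [%s]: n = %d, K = %d, RSS = %.4g, R^2 = %.3f\n",
              x$family, x$n, x$K, x$rss, x$r2))
  cat("params:", paste(names(x$params), signif(unlist(x$params), 4), sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$breakpoint)) {
    cat(sprintf("breakpoint x* = %.4g", x$breakpoint$x_star))
    if (!is.null(x$breakpoint$ci)) {
      cat(sprintf(" (bootstrap CI %.4g-%.4g)", x$breakpoint$ci[1], x$breakpoint$ci[2]))
    }
    if (!is.null(x$breakpoint$f_test)) {
      cat(sprintf("; F vs %s: F = %.3g, p = %.3g",
                  x$breakpoint$f_test$nested, x$breakpoint$f_test$F, x$breakpoint$f_test$p))
    }
    cat("\n")
  }
  invisible(x)
}

#' @rdname fit_da
#' @export
tidy.da_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unlist(x$params, use.names = FALSE))
}

#' @rdname fit_da
#' @param object a `da_fit`.
#' @export
glance.da_fit <- function(x, ...) {
  tibble::tibble(family = x$family, n = x$n, K = x$K, rss = x$rss, r2 = x$r2)
}

#' Saturating d-a curve y = a (1 - b^x)
#'
#' Nonlinear least squares fit of the saturating relationship expected for
#' occupancy against local abundance. Initialisation `a0 = max(y)`,
#' `b0 = 0.5`; bounds `a > 0`, `0 < b < 1`.
#'
#' @inheritParams fit_da
#' @return a `da_fit`; `degenerate` is set when `y` is constant and `b` is
#'   unidentifiable.
#' @export
fit_saturating <- function(x, y, ...) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("saturating fit needs n >= 4")
  if (any(x < 0)) stop("abundances must be non-negative")
  if (stats::sd(y) == 0) {
    fit <- new_da_fit("saturating", list(a = mean(y), b = NA_real_),
      K = 3, x = x, y = y, fitted = rep(mean(y), length(y))
    )
    fit$degenerate <- TRUE
    warning("constant response: saturating parameter b is unidentifiable")
    return(fit)
  }
  a0 <- max(y)
  fit <- try(stats::nls(y ~ a * (1 - b^x),
    start = list(a = a0, b = 0.5),
    lower = c(a = 1e-8, b = 1e-6), upper = c(a = 2 * max(abs(y)) + 1e-6, b = 1 - 1e-6),
    algorithm = "port",
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("saturating fit failed to converge: ", attr(fit, "condition")$message)
  }
  cf <- stats::coef(fit)
  new_da_fit("saturating", list(a = unname(cf["a"]), b = unname(cf["b"])),
    K = 3, x = x, y = y, fitted = unname(stats::fitted(fit))
  )
}

#' Segmented (piecewise) regression with breakpoint search
#'
#' Grid search over candidate breakpoints placed at midpoints between
#' consecutive distinct sorted `x` values. For each candidate the two segments
#' are fitted by least squares (a horizontal segment is its mean, a sloping
#' segment an ordinary regression) and the breakpoint minimising total RSS is
#' selected, which also maximises R^2; ties break toward the smaller
#' breakpoint. Significance against the nested single-segment model
#' (mean-only for horizontal/horizontal, linear otherwise) is assessed by an
#' F-test with degrees of freedom corrected for the added parameters, and a
#' breakpoint confidence interval is obtained by case-resampling bootstrap.
#'
#' @inheritParams fit_da
#' @param family segmented family (see [fit_da()]).
#' @param min_segment minimum points per segment.
#' @param boot number of bootstrap resamples for the breakpoint CI (0 skips).
#' @param conf CI coverage.
#' @param seed seed for the bootstrap.
#' @return a `da_fit` with a `breakpoint` element (`x_star`, `ci`, `f_test`).
#' @export
fit_segmented <- function(x, y, family = c(
                            "seg_horizontal_horizontal", "seg_sloping_horizontal",
                            "seg_horizontal_sloping", "seg_sloping_sloping"
                          ),
                          min_segment = 3, boot = 999, conf = 0.95, seed = 1L) {
  family <- match.arg(family)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2 * min_segment) stop("need at least ", 2 * min_segment, " points")
  left_kind <- if (family %in% c("seg_horizontal_horizontal", "seg_horizontal_sloping")) "h" else "s"
  right_kind <- if (family %in% c("seg_horizontal_horizontal", "seg_sloping_horizontal")) "h" else "s"

  core <- function(x, y) {
    xs <- sort(unique(x))
    if (length(xs) < 2) return(NULL)
    cands <- (xs[-1] + xs[-length(xs)]) / 2
    best <- NULL
    for (bp in cands) {
      li <- x <= bp; ri <- !li
      if (sum(li) < min_segment || sum(ri) < min_segment) next
      seg <- function(idx, kind) {
        if (kind == "h") {
          mu <- mean(y[idx])
          list(fitted = rep(mu, sum(idx)), par = c(level = mu))
        } else {
          f <- stats::lm(y[idx] ~ x[idx])
          list(fitted = unname(stats::fitted(f)),
               par = c(intercept = unname(stats::coef(f)[1]), slope = unname(stats::coef(f)[2])))
        }
      }
      L <- seg(li, left_kind); R <- seg(ri, right_kind)
      rss <- sum((y[li] - L$fitted)^2) + sum((y[ri] - R$fitted)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(bp = bp, rss = rss, left = L$par, right = R$par, li = li)
      }
    }
    best
  }

  best <- core(x, y)
  if (is.null(best)) stop("too few distinct x values for a breakpoint search")

  K <- switch(family,
    seg_horizontal_horizontal = 4, seg_sloping_horizontal = 5,
    seg_horizontal_sloping = 5, seg_sloping_sloping = 6
  )
  fitted <- numeric(n)
  predict_seg <- function(par, xx, kind) {
    if (kind == "h") rep(unname(par["level"]), length(xx))
    else unname(par["intercept"]) + unname(par["slope"]) * xx
  }
  fitted[best$li] <- predict_seg(best$left, x[best$li], left_kind)
  fitted[!best$li] <- predict_seg(best$right, x[!best$li], right_kind)

  # nested single-segment comparison (F-test, df corrected for added params)
  nested_family <- if (family == "seg_horizontal_horizontal") "mean" else "linear"
  nested <- fit_da(x, y, nested_family)
  p1 <- K - 1          # regression params incl. breakpoint, excl. variance
  p0 <- nested$K - 1
  df2 <- n - p1
  f_stat <- ((nested$rss - best$rss) / (p1 - p0)) / (best$rss / df2)
  f_p <- stats::pf(f_stat, p1 - p0, df2, lower.tail = FALSE)

  ci <- NULL
  if (boot > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    bps <- vapply(seq_len(boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      b <- core(x[idx], y[idx])
      if (is.null(b)) NA_real_ else b$bp
    }, 0)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    bps <- bps[!is.na(bps)]
    if (length(bps) > 0) {
      ci <- unname(stats::quantile(bps, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
    }
  }

  new_da_fit(family,
    params = c(as.list(stats::setNames(best$left, paste0("left_", names(best$left)))),
               as.list(stats::setNames(best$right, paste0("right_", names(best$right)))),
               list(x_star = best$bp)),
    K = K, x = x, y = y, fitted = fitted,
    breakpoint = list(
      x_star = best$bp, ci = ci,
      f_test = list(nested = nested_family, F = f_stat, p = f_p)
    )
  )
}

#' Fit the full d-a candidate model suite
#'
#' @inheritParams fit_da
#' @param models character vector of families (default: all six used for the
#'   constrained interspecific analysis).
#' @param ... passed to the individual fitters.
#' @return list with `fits` (named list of `da_fit`) and `ranking` (the
#'   [aicc_rank()] table).
#' @export
da_model_suite <- function(x, y, models = c(
                             "saturating", "seg_horizontal_horizontal", "linear",
                             "seg_sloping_horizontal", "mean", "seg_sloping_sloping"
                           ), ...) {
  fits <- purrr::map(stats::setNames(models, models), function(m) fit_da(x, y, m, ...))
  tbl <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$family, K = f$K, n = f$n, rss = f$rss)
  })
  list(fits = fits, ranking = aicc_rank(tbl))
}

#' Small-sample AIC ranking with Akaike weights and evidence ratios
#'
#' For least-squares models, `AIC = n log(RSS/n) + 2K` and
#' `AICc = AIC + 2K(K+1)/(n - K - 1)`, with `K` counting the error variance.
#' The table reports `delta` (AICc difference from the best model),
#' `exp(-delta/2)`, Akaike weights (normalised model likelihoods) and the
#' evidence ratio of the best model against each model. Models with
#' `n <= K + 1` have undefined AICc and are flagged.
#'
#' @param models either a tibble with columns `model`, `K`, `n`, `rss`, or a
#'   list of `da_fit` objects fitted to the same data.
#' @return tibble ordered by AICc with columns `model`, `K`, `n`, `rss`,
#'   `aic`, `aicc`, `delta`, `exp_half_delta`, `weight`, `evidence_ratio`,
#'   `best`.
#' @export
aicc_rank <- function(models) {
  if (inherits(models, "data.frame")) {
    tbl <- tibble::as_tibble(models)
  } else {
    tbl <- purrr::map_dfr(models, function(f) {
      tibble::tibble(model = f$family, K = f$K, n = f$n, rss = f$rss)
    })
  }
  stopifnot(all(c("model", "K", "n", "rss") %in% names(tbl)))
  if (length(unique(tbl$n)) > 1) stop("all models must be fitted to the same data (equal n)")
  tbl$aic <- tbl$n * log(tbl$rss / tbl$n) + 2 * tbl$K
  tbl$aicc <- ifelse(tbl$n > tbl$K + 1,
    tbl$aic + 2 * tbl$K * (tbl$K + 1) / (tbl$n - tbl$K - 1), NA_real_
  )
  if (anyNA(tbl$aicc)) warning("AICc undefined for model(s) with n <= K + 1")
  best_aicc <- min(tbl$aicc, na.rm = TRUE)
  tbl$delta <- tbl$aicc - best_aicc
  tbl$exp_half_delta <- exp(-tbl$delta / 2)
  tbl$weight <- tbl$exp_half_delta / sum(tbl$exp_half_delta, na.rm = TRUE)
  tbl$evidence_ratio <- max(tbl$weight, na.rm = TRUE) / tbl$weight
  tbl$best <- !is.na(tbl$delta) & tbl$delta == 0
  dplyr::arrange(tbl, .data$aicc)
}

#' Phylogenetically independent contrasts with regression through the origin
#'
#' Computes Felsenstein's standardised contrasts for two traits on a rooted
#' bifurcating tree and regresses the contrasts of `trait_y` on those of
#' `trait_x` through the origin. Ancestral values are branch-length-weighted
#' averages of daughter values; after each internal node the parent branch is
#' extended by `v1 v2 / (v1 + v2)`; each contrast is standardised by the
#' square root of the summed (extended) daughter branch lengths.
#'
#' @param tree a `phylo` object (rooted, bifurcating; unit branch lengths are
#'   substituted when absent).
#' @param trait_x,trait_y named numeric vectors; names must match tip labels.
#' @return list with `contrasts` (tibble `node`, `contrast_x`, `contrast_y`)
#'   and `regression` (tibble `slope`, `se`, `t`, `p`, `df`). The slope is
#'   `NA` with a flag when all x-contrasts are zero.
#' @export
pic_regression <- function(tree, trait_x, trait_y) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  if (any(tree$edge.length <= 0)) {
    stop("tree has non-positive branch lengths; substitute unit lengths first")
  }
  tips <- tree$tip.label
  if (!all(tips %in% names(trait_x)) || !all(tips %in% names(trait_y))) {
    stop("traits must be named for every tip of the tree")
  }
  cx <- pic_contrasts(tree, trait_x[tips])
  cy <- pic_contrasts(tree, trait_y[tips])
  contrasts <- tibble::tibble(node = cx$node, contrast_x = cx$contrast, contrast_y = cy$contrast)
  sxx <- sum(contrasts$contrast_x^2)
  if (sxx == 0) {
    warning("all x-contrasts are zero; slope undefined")
    reg <- tibble::tibble(slope = NA_real_, se = NA_real_, t = NA_real_,
                          p = NA_real_, df = nrow(contrasts) - 1)
  } else {
    slope <- sum(contrasts$contrast_x * contrasts$contrast_y) / sxx
    res <- contrasts$contrast_y - slope * contrasts$contrast_x
    df <- nrow(contrasts) - 1
    se <- sqrt(sum(res^2) / df / sxx)
    tval <- slope / se
    reg <- tibble::tibble(slope = slope, se = se, t = tval,
                          p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE), df = df)
  }
  list(contrasts = contrasts, regression = reg)
}

# Post-order Felsenstein pruning; returns one standardised contrast per
# internal node of a bifurcating tree.
pic_contrasts <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (nnode != ntip - 1) stop("tree must be fully bifurcating (n - 1 internal nodes)")
  edge <- tree$edge
  elen <- tree$edge.length
  val <- c(unname(states), rep(NA_real_, nnode))
  vlen <- numeric(ntip + nnode)
  # edge length from each node to its parent, with pruning extensions
  up <- rep(NA_real_, ntip + nnode)
  up[edge[, 2]] <- elen
  contrast <- rep(NA_real_, ntip + nnode)
  children <- split(edge[, 2], edge[, 1])
  post <- rev(unique(edge[, 1][order(edge[, 1])]))  # internal nodes, highest first
  # reorder: process nodes whose children are all resolved (post-order)
  pending <- as.integer(names(children))
  done <- rep(FALSE, ntip + nnode); done[seq_len(ntip)] <- TRUE
  while (length(pending) > 0) {
    for (nd in pending) {
      kids <- children[[as.character(nd)]]
      if (all(done[kids])) {
        if (length(kids) != 2) stop("tree must be fully bifurcating")
        v1 <- up[kids[1]] + vlen[kids[1]]
        v2 <- up[kids[2]] + vlen[kids[2]]
        contrast[nd] <- (val[kids[1]] - val[kids[2]]) / sqrt(v1 + v2)
        val[nd] <- (val[kids[1]] / v1 + val[kids[2]] / v2) / (1 / v1 + 1 / v2)
        vlen[nd] <- v1 * v2 / (v1 + v2)
        done[nd] <- TRUE
      }
    }
    pending <- pending[!done[pending]]
  }
  nodes <- sort(unique(edge[, 1]))
  tibble::tibble(node = nodes, contrast = contrast[nodes])
}

#' Cook's distance outlier screen for linear d-a fits
#'
#' Flags observations whose Cook's distance exceeds `4/n` under an ordinary
#' linear regression of `y` on `x`.
#'
#' @inheritParams fit_da
#' @param cutoff influence cutoff; defaults to `4 / length(x)`.
#' @return tibble `index`, `cooks_d`, `flagged`.
#' @export
cooks_outliers <- function(x, y, cutoff = NULL) {
  fit <- stats::lm(y ~ x)
  d <- unname(stats::cooks.distance(fit))
  if (is.null(cutoff)) cutoff <- 4 / length(x)
  tibble::tibble(index = seq_along(x), cooks_d = d, flagged = is.finite(d) & d > cutoff)
}
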