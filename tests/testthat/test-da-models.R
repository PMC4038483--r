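test_that("saturating fit recovers exact parameters on noiseless data", {
  x <- 1:6
  y <- 2 * (1 - 0.5^x)
  f <- fit_saturating(x, y)
  expect_equal(f$params$a, 2, tolerance = 1e-5)
  expect_equal(f$params$b, 0.5, tolerance = 1e-5)
  expect_lt(f$rss, 1e-9)
  # prediction monotone nondecreasing and bounded by a
  expect_true(all(diff(f$fitted[order(x)]) >= -1e-12))
  expect_true(all(f$fitted <= f$params$a + 1e-9))
})

test_that("saturating fit flags constant response and recovers noisy truth", {
  expect_warning(f <- fit_saturating(1:6, rep(2, 6)), "unidentifiable")
  expect_true(isTRUE(f$degenerate))

  set.seed(5)
  x <- seq(0.2, 6, length.out = 13)
  y <- 1 * (1 - 0.3^x) + rnorm(13, 0, 0.05)
  f <- fit_saturating(x, y)
  # parameter recovery within a generous 3-sigma band for sigma = 0.05
  expect_equal(f$params$a, 1, tolerance = 0.15)
  expect_equal(f$params$b, 0.3, tolerance = 0.45)
})

test_that("segmented fit finds an exact clean step and beats nothing on lines", {
  x <- c(1:4, 6:9)
  y <- c(rep(0, 4), rep(1, 4))
  f <- fit_segmented(x, y, "seg_horizontal_horizontal", boot = 0)
  expect_gt(f$breakpoint$x_star, 4)
  expect_lt(f$breakpoint$x_star, 6)
  expect_lt(f$rss, 1e-12)
  expect_lt(f$breakpoint$f_test$p, 0.01)

  set.seed(9)
  xl <- seq(1, 10, length.out = 14)
  yl <- 2 + 0.5 * xl + rnorm(14, 0, 0.3)
  fl <- fit_segmented(xl, yl, "seg_sloping_sloping", boot = 0)
  expect_gt(fl$breakpoint$f_test$p, 0.05)   # no support for a breakpoint
})

test_that("grid search equals a brute-force minimum-RSS oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:20, 1)
    x <- sort(runif(n, 0, 10))
    y <- ifelse(x < 4, 1, 3) + rnorm(n, 0, 0.4)
    f <- fit_segmented(x, y, "seg_horizontal_horizontal", boot = 0)
    # oracle: try every midpoint split directly
    xs <- sort(unique(x))
    cands <- (xs[-1] + xs[-length(xs)]) / 2
    rss <- vapply(cands, function(bp) {
      li <- x <= bp
      if (sum(li) < 3 || sum(!li) < 3) return(Inf)
      sum((y[li] - mean(y[li]))^2) + sum((y[!li] - mean(y[!li]))^2)
    }, 0)
    expect_equal(f$rss, min(rss), tolerance = 1e-10)
    expect_equal(f$breakpoint$x_star, cands[which.min(rss)])
  }
})

test_that("segmented RSS never exceeds the nested single-segment RSS", {
  set.seed(41)
  for (rep in 1:10) {
    x <- sort(runif(14, 0, 8))
    y <- rnorm(14)
    seg <- fit_segmented(x, y, "seg_horizontal_horizontal", boot = 0)
    expect_lte(seg$rss, fit_da(x, y, "mean")$rss + 1e-12)
    seg2 <- fit_segmented(x, y, "seg_sloping_sloping", boot = 0)
    expect_lte(seg2$rss, fit_da(x, y, "linear")$rss + 1e-12)
  }
})

test_that("AICc ranking reproduces the published constrained d-a table", {
  r <- aicc_rank(da_constrained_model_table())
  expect_equal(r$model[1], "saturating")
  # the small-sample correction for K = 3, n = 13 is 2K(K+1)/(n-K-1) = 8/3
  sat <- r[r$model == "saturating", ]
  expect_equal(sat$aicc - sat$aic, 2 * 3 * 4 / 9)
  expect_equal(sum(r$weight), 1, tolerance = 1e-9)
  expect_lt(abs(r$weight[1] - 0.692), 0.02)
  hh <- r[r$model == "seg_horizontal_horizontal", ]
  expect_lt(abs(hh$weight - 0.292), 0.02)
  expect_lt(abs(hh$evidence_ratio - 2.37), 0.35)
  expect_true(all(r$evidence_ratio >= 1))
  expect_equal(r$evidence_ratio[1], 1)
})

test_that("AICc ranking handles degenerate cases", {
  one <- tibble::tibble(model = "m", K = 2, n = 10, rss = 1)
  r1 <- aicc_rank(one)
  expect_equal(r1$delta, 0)
  expect_equal(r1$weight, 1)
  two <- tibble::tibble(model = c("a", "b"), K = 3, n = 10, rss = 0.5)
  r2 <- aicc_rank(two)
  expect_equal(r2$weight, c(0.5, 0.5))
  tiny <- tibble::tibble(model = c("a", "b"), K = c(2, 9), n = 10, rss = c(1, 0.5))
  expect_warning(r3 <- aicc_rank(tiny), "undefined")
  expect_true(any(is.na(r3$aicc)))
})

test_that("independent contrasts match the closed form and the ape oracle", {
  # two taxa, unit branch lengths: contrast = (x1 - x2)/sqrt(2)
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  px <- pic_regression(tr2, c(A = 3, B = 1), c(A = 5, B = 1))
  expect_equal(abs(px$contrasts$contrast_x), 2 / sqrt(2))
  expect_equal(px$regression$slope, 4 / 2)   # through-origin slope of y on x

  set.seed(7)
  for (n in 4:8) {
    tr <- ape::rtree(n)
    tx <- stats::setNames(rnorm(n, 10), tr$tip.label)
    ty <- stats::setNames(2 * tx + rnorm(n), tr$tip.label)
    ours <- pic_regression(tr, tx, ty)
    ox <- ape::pic(tx[tr$tip.label], tr)
    oy <- ape::pic(ty[tr$tip.label], tr)
    # contrasts agree up to node ordering and sign
    expect_equal(sort(abs(ours$contrasts$contrast_x)), sort(abs(unname(ox))),
                 tolerance = 1e-9)
    oracle_slope <- sum(ox * oy) / sum(ox^2)
    expect_equal(ours$regression$slope, oracle_slope, tolerance = 1e-9)
  }
})

test_that("identical traits give zero contrasts and a flagged slope", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  same <- stats::setNames(rep(4, 4), tr$tip.label)
  other <- stats::setNames(1:4, tr$tip.label)
  expect_warning(res <- pic_regression(tr, same, other), "zero")
  expect_true(is.na(res$regression$slope))
})

test_that("Cook's distance screen flags a gross outlier and nothing on a line", {
  x <- 1:14
  y <- 2 * x
  y[7] <- 60                       # gross outlier off the line
  cd <- cooks_outliers(x, y)
  expect_true(cd$flagged[7])
  expect_equal(cd$cooks_d > 4 / 14, cd$flagged)
  clean <- cooks_outliers(x, 2 * x + rnorm(14, 0, 1e-6))
  expect_false(any(clean$flagged))
})

test_that("breakpoint bootstrap CI covers a true threshold", {
  set.seed(13)
  x <- seq(0.3, 5, length.out = 13)
  y <- ifelse(x < 1.6, 0.6, 0.22) + rnorm(13, 0, 0.05)
  f <- fit_segmented(x, y, "seg_horizontal_horizontal", boot = 199, seed = 2)
  expect_true(f$breakpoint$ci[1] <= 1.6 && 1.6 <= f$breakpoint$ci[2])
})
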