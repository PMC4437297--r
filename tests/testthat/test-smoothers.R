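test_that("loess reproduces polynomials of the local degree exactly", {
  x <- seq(0, 10, length.out = 25)
  lin <- data.frame(x = x, y = 2 * x + 1)
  for (span in c(0.4, 0.8, 1)) {
    fit <- loess_fit(lin, span = span)
    expect_equal(fit$y, 2 * sort(x) + 1, tolerance = 1e-10)
  }
  quad <- data.frame(x = x, y = x^2 - 3 * x + 2)
  fit2 <- loess_fit(quad, span = 0.7, degree = 2)
  xs <- sort(x)
  expect_equal(fit2$y, xs^2 - 3 * xs + 2, tolerance = 1e-8)
})

test_that("loess equals the brute-force weighted normal equations", {
  set.seed(4)
  n <- 40
  x <- sort(runif(n))
  y <- sin(3 * x) + rnorm(n, sd = 0.2)
  for (span in c(0.5, 0.8)) {
    fit <- loess_fit(data.frame(x, y), span = span)
    r <- ceiling(span * n)
    for (i in c(1, 7, 20, 40)) {
      x0 <- sort(x)[i]
      d <- abs(x - x0)
      h <- sort(d)[r]
      u <- d / h
      w <- ifelse(u < 1, (1 - u^3)^3, 0)
      expect_equal(fit$y[i], oracle_wls_at(x, y, w, x0, 1),
                   tolerance = 1e-10)
    }
  }
  # 3 points, full-window case: the end windows hold two positive-weight
  # points (the tricube vanishes at the window edge), the middle window
  # degenerates to the point itself and falls back to its own value
  x3 <- c(0, 1, 2); y3 <- c(0, 1, 0)
  expect_warning(f3 <- loess_fit(data.frame(x = x3, y = y3), span = 1),
                 "singular")
  for (i in c(1, 3)) {
    d <- abs(x3 - x3[i]); h <- sort(d)[3]
    w <- ifelse(d / h < 1, (1 - (d / h)^3)^3, 0)
    expect_equal(f3$y[i], oracle_wls_at(x3, y3, w, x3[i], 1),
                 tolerance = 1e-12)
  }
  expect_equal(f3$y[2], 1)
})

test_that("loess handles degenerate windows and tiny spans", {
  dup <- data.frame(x = c(1, 1, 1, 1, 2), y = c(1, 2, 3, 4, 9))
  expect_warning(fit <- loess_fit(dup, span = 0.6), "degenerate")
  expect_true(all(is.finite(fit$y)))
  set.seed(9)
  d <- data.frame(x = sort(runif(12)), y = runif(12))
  fit2 <- loess_fit(d, span = 0.2)
  expect_true(all(is.finite(fit2$y)))
  expect_error(loess_fit(d, span = 0), "span")
  expect_error(loess_fit(d[1:2, ], span = 0.5), "too few")
})

test_that("nw_fit limits: flat kernel averages, delta kernel interpolates", {
  set.seed(11)
  d <- data.frame(x = sort(runif(30)), y = rnorm(30))
  wide <- nw_fit(d, bandwidth = 1e6)
  expect_equal(wide$y, rep(mean(d$y), 30), tolerance = 1e-6)
  narrow <- nw_fit(d, bandwidth = 1e-5)
  expect_equal(narrow$y, d$y[order(d$x)], tolerance = 1e-6)
  # convex-combination bound
  mid <- nw_fit(d, bandwidth = 0.1)
  expect_true(all(mid$y <= max(d$y) + 1e-12 & mid$y >= min(d$y) - 1e-12))
})

test_that("LOOCV bandwidth lands inside the grid and beats the endpoints", {
  set.seed(12)
  n <- 200
  x <- sort(runif(n))
  y <- sin(2 * pi * x) + rnorm(n, sd = 0.1)
  fit <- nw_fit(data.frame(x, y), bandwidth = "auto")
  cv <- fit$cv
  best <- which.min(cv$loo_mse)
  expect_gt(best, 1)
  expect_lt(best, nrow(cv))
  expect_lt(cv$loo_mse[best], cv$loo_mse[1])
  expect_lt(cv$loo_mse[best], cv$loo_mse[nrow(cv)])
  expect_equal(fit$h, cv$h[best])
})

test_that("nw_fit cross-checks against ksmooth's normal kernel", {
  set.seed(13)
  x <- sort(runif(80))
  y <- cos(4 * x) + rnorm(80, sd = 0.05)
  h <- 0.05
  ours <- nw_fit(data.frame(x, y), bandwidth = h, eval_x = x)
  # ksmooth scales its "bandwidth" so the quartiles sit at +/- 0.25 bw
  ks <- stats::ksmooth(x, y, kernel = "normal",
                       bandwidth = h / 0.3706506, x.points = x)
  expect_equal(ours$y, ks$y, tolerance = 1e-4)
})

test_that("departure_point finds a planted changepoint and ignores lines", {
  x <- seq(0.01, 1, by = 0.01)
  lin <- new_curve <- list(x = x, y = 0.3 * x, method = "loess", h = 0.8)
  class(lin) <- "curve_estimate"
  expect_true(is.na(departure_point(lin)))
  bent <- list(x = x, y = 0.3 * x + ifelse(x > 0.5, (x - 0.5)^2 * 3, 0),
               method = "loess", h = 0.8)
  class(bent) <- "curve_estimate"
  dp <- departure_point(bent)
  expect_false(is.na(dp))
  expect_lt(abs(dp - 0.5), 0.1)
  # fixed reference slope variant
  dp2 <- departure_point(bent, slope_ref = 0.3)
  expect_false(is.na(dp2))
})
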