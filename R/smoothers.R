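# Nonparametric trend extraction for (f, fe) scatter: locally weighted
# regression (LOESS) and the Nadaraya-Watson kernel smoother.

new_curve_estimate <- function(x, y, method, h, extra = list()) {
  structure(c(list(x = x, y = y, method = method, h = h), extra),
            class = "curve_estimate")
}

#' @export
print.curve_estimate <- function(x, ...) {
  cat(sprintf("curve_estimate (%s, h = %s): %d evaluation points\n",
              x$method, format(x$h, digits = 4), length(x$x)))
  invisible(x)
}

#' @export
plot.curve_estimate <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l", xlab = "x", ylab = "fitted", ...)
  if (!is.null(x$data))
    graphics::points(x$data$x, x$data$y, pch = 16, cex = 0.4,
                     col = "grey50")
  invisible(x)
}

#' Locally weighted regression (LOESS)
#'
#' At each evaluation point `x0` the window half-width `h_i` is the
#' distance to the `r`-th nearest observation, `r = ceiling(span * n)`.
#' Observations are weighted by the tricube kernel
#' `W(u) = (1 - |u|^3)^3` for `|u| < 1` (0 outside) of the scaled
#' distance `u = (x_k - x0) / h_i`, and a weighted least-squares local
#' polynomial of the given degree is evaluated at `x0`. No robustness
#' iterations are applied.
#'
#' Degenerate windows (at least `r` duplicated abscissae, so `h_i = 0`)
#' fall back to the weighted mean of the exact ties, with a warning; so
#' do windows whose weighted design matrix is singular.
#'
#' @param points data.frame with columns `x` and `y` (or a two-column
#'   matrix).
#' @param span fraction of the data in each local window, `0 < span <= 1`.
#' @param degree local polynomial degree (default 1, local linear).
#' @param eval_x abscissae at which to evaluate (defaults to the data
#'   abscissae, sorted).
#' @return a `curve_estimate` (fields `x`, `y`, `method`, `h`).
#' @examples
#' d <- data.frame(x = 0:10, y = 2 * (0:10) + 1)
#' loess_fit(d, span = 0.8)$y   # exact on a line
#' @export
loess_fit <- function(points, span = 0.8, degree = 1, eval_x = NULL) {
  d <- as.data.frame(points)
  x <- as.numeric(d[[1]]); y <- as.numeric(d[[2]])
  n <- length(x)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (n < degree + 2) stop("too few points for a local fit")
  if (is.null(eval_x)) eval_x <- sort(x)
  r <- ceiling(span * n)
  fit_at <- function(x0) {
    dist <- abs(x - x0)
    h <- sort(dist)[r]
    if (h == 0) {
      warning("degenerate window (duplicated abscissae); using mean of ties")
      return(mean(y[dist == 0]))
    }
    u <- dist / h
    w <- ifelse(u < 1, (1 - u^3)^3, 0)
    keep <- w > 0
    X <- outer(x[keep] - x0, 0:degree, `^`)
    fit <- tryCatch(lm.wfit(X, y[keep], w[keep]), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      warning("singular local fit; falling back to weighted mean")
      return(sum(w * y) / sum(w))
    }
    unname(fit$coefficients[1])
  }
  yhat <- vapply(eval_x, fit_at, numeric(1))
  new_curve_estimate(eval_x, yhat, "loess", span,
                     list(degree = degree, data = data.frame(x = x, y = y)))
}

#' Nadaraya-Watson kernel regression
#'
#' `yhat(x) = sum_i K_h(x - x_i) y_i / sum_i K_h(x - x_i)` with a
#' Gaussian kernel `K_h(u) = exp(-u^2 / (2 h^2))`. With
#' `bandwidth = "auto"` the bandwidth minimises the leave-one-out squared
#' prediction error over 30 log-spaced values between 0.01 and 1 times
#' the abscissa range. If every kernel weight underflows at some
#' evaluation point the kernel is widened there (doubling `h` until a
#' weight is positive), with a warning.
#'
#' @param points data.frame with columns `x` and `y`.
#' @param bandwidth positive bandwidth, or `"auto"` for leave-one-out
#'   cross-validation.
#' @param eval_x abscissae at which to evaluate (defaults to the data
#'   abscissae, sorted).
#' @return a `curve_estimate`; `$h` is the bandwidth used, `$cv` the LOO
#'   error per candidate when selected automatically.
#' @export
nw_fit <- function(points, bandwidth = "auto", eval_x = NULL) {
  d <- as.data.frame(points)
  x <- as.numeric(d[[1]]); y <- as.numeric(d[[2]])
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (is.null(eval_x)) eval_x <- sort(x)
  cv <- NULL
  if (identical(bandwidth, "auto")) {
    rng <- diff(range(x))
    grid <- exp(seq(log(0.01), log(1), length.out = 30)) * rng
    cv <- vapply(grid, function(h) {
      K <- exp(-outer(x, x, `-`)^2 / (2 * h^2))
      diag(K) <- 0
      den <- rowSums(K)
      pred <- ifelse(den > 0, (K %*% y) / den, NA_real_)
      mean((y - pred)^2, na.rm = TRUE)
    }, numeric(1))
    bandwidth <- grid[which.min(cv)]
    cv <- data.frame(h = grid, loo_mse = cv)
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  h <- bandwidth
  yhat <- vapply(eval_x, function(x0) {
    hh <- h
    w <- exp(-(x0 - x)^2 / (2 * hh^2))
    while (sum(w) == 0) {
      hh <- 2 * hh
      w <- exp(-(x0 - x)^2 / (2 * hh^2))
      warning("kernel weights underflowed; widening the kernel")
    }
    sum(w * y) / sum(w)
  }, numeric(1))
  new_curve_estimate(eval_x, yhat, "nw", h,
                     list(cv = cv, data = data.frame(x = x, y = y)))
}

#' Departure point from linear growth
#'
#' Operationalises the visual "departure from linearity" of an (f, fe)
#' trend: a reference line through the origin is fitted to the low-f part
#' of the curve (abscissae below `cutoff`), and the departure point is
#' the smallest abscissa at which the curve exceeds the line by more than
#' `margin_mult` times the residual standard deviation of the low-f fit.
#'
#' @param curve a `curve_estimate`.
#' @param slope_ref optional fixed reference slope (skips the low-f fit).
#' @param cutoff largest abscissa used for the reference fit
#'   (default 0.3).
#' @param margin_mult multiplier of the low-f residual sd (default 3).
#' @return the departure abscissa, or `NA` if the curve never exceeds
#'   the reference line by the margin. The slope and margin used are
#'   attached as attributes.
#' @export
departure_point <- function(curve, slope_ref = NULL, cutoff = 0.3,
                            margin_mult = 3) {
  x <- curve$x; y <- curve$y
  low <- x <= cutoff
  if (sum(low) < 3) stop("too few curve points below the cutoff")
  if (is.null(slope_ref)) {
    fit <- lm(y[low] ~ x[low] - 1)
    slope_ref <- unname(coef(fit)[1])
    resid_sd <- sd(fit$residuals)
  } else {
    resid_sd <- sd(y[low] - slope_ref * x[low])
  }
  # floor keeps an exactly-linear curve (zero residuals) from tripping on
  # rounding noise
  margin <- max(margin_mult * resid_sd, 1e-10 * max(abs(y), 1))
  exceeds <- y > slope_ref * x + margin
  out <- if (any(exceeds)) x[which(exceeds)[1]] else NA_real_
  attr(out, "slope") <- slope_ref
  attr(out, "margin") <- margin
  out
}
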