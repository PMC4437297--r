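# Discrete power-law tail fitting (maximum likelihood, KS-chosen xmin).

# Hurwitz zeta sum_{k>=0} (a + k)^(-s) for s > 1, via Euler-Maclaurin.
hurwitz_zeta <- function(s, a) {
  K <- 64
  k <- 0:(K - 1)
  head_sum <- sum((a + k)^(-s))
  b <- a + K
  head_sum + b^(1 - s) / (s - 1) + 0.5 * b^(-s) +
    s / 12 * b^(-s - 1) - s * (s + 1) * (s + 2) / 720 * b^(-s - 3)
}

plaw_loglik <- function(alpha, x, xmin) {
  -length(x) * log(hurwitz_zeta(alpha, xmin)) - alpha * sum(log(x))
}

plaw_mle <- function(x, xmin) {
  opt <- optimize(plaw_loglik, c(1.0001, 8), x = x, xmin = xmin,
                  maximum = TRUE)
  opt$maximum
}

# KS distance between the empirical CDF of the tail sample and the
# discrete power-law CDF with the given exponent; both step functions
# jump at the same support points, so comparing there suffices.
plaw_ks <- function(x, alpha, xmin) {
  ux <- sort(unique(x))
  n <- length(x)
  z <- hurwitz_zeta(alpha, xmin)
  # P(X <= x) = 1 - zeta(alpha, x + 1) / zeta(alpha, xmin)
  th <- 1 - vapply(ux, function(v) hurwitz_zeta(alpha, v + 1),
                   numeric(1)) / z
  emp <- cumsum(tabulate(match(x, ux))) / n
  max(abs(emp - th))
}

#' Fit a discrete power-law tail to avalanche sizes
#'
#' Maximum-likelihood fit of `P(S = s) ~ s^(-alpha)` for `s >= xmin` on
#' positive integer sizes. By default `xmin` is chosen by minimising the
#' Kolmogorov-Smirnov distance between the tail sample and the fitted
#' distribution over candidate cutoffs (the standard tail-selection
#' recipe); a fixed `xmin` can be supplied instead. The KS statistic of
#' the selected fit is returned as a goodness diagnostic -- large values
#' flag a poor power-law fit (e.g. geometric data).
#'
#' @param sizes positive integer avalanche sizes.
#' @param xmin_strategy `"ks"` (default) or `"fixed"`.
#' @param xmin lower cutoff when `xmin_strategy = "fixed"`, and the
#'   smallest candidate otherwise.
#' @param min_tail minimum number of observations required at or above the
#'   cutoff (default 100).
#' @return list with `alpha`, `xmin`, `ks`, `n_tail`, `se`, `ci`
#'   (95 percent, from the observed Fisher information).
#' @examples
#' s <- rplaw_discrete(2000, alpha = 1.5, xmin = 1, seed = 1)
#' fit_tail(s, xmin_strategy = "fixed", xmin = 1)$alpha
#' @export
fit_tail <- function(sizes, xmin_strategy = c("ks", "fixed"), xmin = 1L,
                     min_tail = 100L) {
  xmin_strategy <- match.arg(xmin_strategy)
  sizes <- floor(as.numeric(sizes))
  sizes <- sizes[sizes >= 1]
  if (length(unique(sizes)) < 2)
    stop("degenerate tail: need at least two distinct sizes")
  if (xmin_strategy == "fixed") {
    cands <- as.numeric(xmin)
  } else {
    cands <- sort(unique(sizes))
    cands <- cands[cands >= xmin]
    # keep candidates leaving enough tail mass
    cands <- cands[vapply(cands, function(c) sum(sizes >= c),
                          numeric(1)) >= min_tail]
    if (length(cands) == 0)
      stop(sprintf("insufficient tail data: fewer than %d values above every candidate xmin",
                   min_tail))
    if (length(cands) > 40)  # thin the candidate list for speed
      cands <- cands[unique(round(seq(1, length(cands), length.out = 40)))]
  }
  best <- NULL
  for (c in cands) {
    tail_x <- sizes[sizes >= c]
    if (length(tail_x) < min_tail)
      stop(sprintf("insufficient tail data: %d values >= xmin = %d (need %d)",
                   length(tail_x), c, min_tail))
    if (length(unique(tail_x)) < 2) next
    alpha <- plaw_mle(tail_x, c)
    ks <- plaw_ks(tail_x, alpha, c)
    if (is.null(best) || ks < best$ks)
      best <- list(alpha = alpha, xmin = c, ks = ks,
                   n_tail = length(tail_x))
  }
  if (is.null(best)) stop("degenerate tail: no candidate cutoff usable")
  # observed information via central second difference of the log-likelihood
  tail_x <- sizes[sizes >= best$xmin]
  h <- 1e-4
  d2 <- (plaw_loglik(best$alpha + h, tail_x, best$xmin) -
         2 * plaw_loglik(best$alpha, tail_x, best$xmin) +
         plaw_loglik(best$alpha - h, tail_x, best$xmin)) / h^2
  best$se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  best$ci <- best$alpha + c(-1, 1) * 1.96 * best$se
  best
}

#' Envelope fit of avalanche-size distributions across f0 slices
#'
#' Away from the exact critical point each avalanche-size distribution
#' carries a cutoff, so the size distribution at any single `f0` decays
#' faster than the critical power law; the *envelope* of the
#' distributions across a family of `f0` values traces the critical
#' scaling itself. Sizes are binned in powers of two, each slice is
#' converted to a density (counts per unit size), the envelope takes the
#' per-bin maximum across slices, and the exponent is the least-squares
#' slope of log density against log size over the leading bins, stopping
#' before the envelope first turns up again (the supercritical bump at
#' the cutoff scale is not part of the scaling range).
#'
#' @param sizes_by_f0 list of positive integer size vectors, one per f0
#'   slice (e.g. the `sizes` field of an [avalanche_profile()] run with
#'   `keep_sizes = TRUE`).
#' @param min_slice slices with fewer sizes are ignored (default 50).
#' @return list with `exponent` (positive, as in `P(S) ~ S^-exponent`),
#'   `se`, `n_bins`, and the envelope table (`size`, `density`).
#' @export
fit_tail_envelope <- function(sizes_by_f0, min_slice = 50L) {
  sizes_by_f0 <- Filter(function(s) length(s) >= min_slice, sizes_by_f0)
  if (length(sizes_by_f0) < 2)
    stop("need at least 2 usable f0 slices")
  top <- max(unlist(sizes_by_f0))
  breaks <- c(0, 2^(0:ceiling(log2(top + 1))))  # (0,1], (1,2], (2,4], ...
  env <- rep(0, length(breaks) - 1)
  for (s in sizes_by_f0) {
    h <- hist(s, breaks = breaks, plot = FALSE)$counts
    env <- pmax(env, h / length(s) / diff(breaks))
  }
  mid <- c(1, sqrt(breaks[-c(1, 2)] * breaks[-c(1, length(breaks))]))
  # scaling range: leading strictly-positive, non-increasing part
  last <- length(env)
  for (i in seq_along(env)) {
    if (env[i] == 0 || (i > 1 && env[i] > env[i - 1])) { last <- i - 1; break }
  }
  if (last < 4) stop("envelope too short for a slope fit")
  fit <- lm(log(env[1:last]) ~ log(mid[1:last]))
  sm <- suppressWarnings(summary(fit))
  list(exponent = -unname(coef(fit)[2]),
       se = sm$coefficients[2, 2],
       n_bins = last,
       envelope = data.frame(size = mid[1:last], density = env[1:last]))
}

#' Draw from a discrete power law
#'
#' Inversion sampling: exact on a tabulated range of the support, with a
#' continuous-tail approximation for the far tail (a negligible share of
#' the mass for the exponents of interest). Used as the generator half of
#' generator-vs-estimator round-trip tests.
#'
#' @param n number of draws.
#' @param alpha exponent (> 1).
#' @param xmin smallest attainable value.
#' @param seed optional seed.
#' @param table_max largest exactly-tabulated value.
#' @return numeric vector of integer-valued draws `>= xmin` (doubles, since
#'   heavy tails overflow 32-bit integers).
#' @export
rplaw_discrete <- function(n, alpha, xmin = 1L, seed = NULL,
                           table_max = 100000L) {
  if (!is.null(seed)) set.seed(seed)
  z <- hurwitz_zeta(alpha, xmin)
  supp <- xmin:table_max
  cdf <- cumsum(supp^(-alpha) / z)
  u <- runif(n)
  x <- numeric(n)
  inside <- u < cdf[length(cdf)]
  x[inside] <- supp[findInterval(u[inside], cdf) + 1L]
  if (any(!inside)) {
    # conditional far tail: P(X > t) ~ continuous Pareto matched at t
    t0 <- table_max
    v <- (1 - u[!inside]) / (1 - cdf[length(cdf)])
    x[!inside] <- floor((t0 + 0.5) * v^(-1 / (alpha - 1)))
  }
  x
}
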