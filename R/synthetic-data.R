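# Synthetic poll fixtures: multinomial counts per unit drawn around a
# latent (f, fe) curve, emulating the shape of category-count survey
# tables without any external data.

#' Latent (f -> fe) curve families
#'
#' `latent_linear(slope)` gives `fe = slope * f`; `latent_piecewise`
#' grows linearly up to `changepoint` and superlinearly (quadratically in
#' the excess) beyond it; `latent_from_sweep` interpolates a model
#' sweep's (f, fe) curve. All families are clamped to `0 <= fe <= f`.
#'
#' @param slope low-f slope (must keep `fe <= f`, i.e. `slope <= 1`).
#' @param changepoint abscissa where the superlinear term switches on.
#' @param gain curvature of the superlinear excess.
#' @return a function `f -> fe` usable as the `g` of [gen_polls()].
#' @export
latent_linear <- function(slope = 0.33) {
  if (slope < 0 || slope > 1) stop("slope must be in [0, 1]")
  function(f) pmin(slope * f, f)
}

#' @rdname latent_linear
#' @export
latent_piecewise <- function(slope = 0.33, changepoint = 0.5, gain = 2) {
  function(f) {
    fe <- slope * f + gain * pmax(f - changepoint, 0)^2
    pmax(pmin(fe, f), 0)
  }
}

#' @rdname latent_linear
#' @param sweep an `opinion_sweep`.
#' @export
latent_from_sweep <- function(sweep) {
  mc <- model_curve(sweep)
  mc <- mc[order(mc$f), ]
  function(f) {
    fe <- approx(mc$f, mc$fe, xout = f, rule = 2, ties = mean)$y
    pmax(pmin(fe, f), 0)
  }
}

#' Generate synthetic poll tables
#'
#' Per unit: a latent moderate-or-extreme fraction `f ~ Uniform(0.05,
#' 0.95)` is drawn, the latent extremist fraction is `fe = g(f)`, and the
#' negative side mirrors the positive one through the same curve applied
#' to `1 - f`. The four category counts are multinomial draws with the
#' implied probabilities; `overdispersion > 1` inflates the count
#' variance by (approximately) that factor through a Dirichlet draw of
#' the per-unit probabilities.
#'
#' @param n_units number of survey units.
#' @param respondents respondents per unit (scalar or length-2 range to
#'   sample uniformly).
#' @param g latent curve, e.g. [latent_linear()]; must satisfy
#'   `g(f) <= f`.
#' @param seed optional seed.
#' @param overdispersion variance inflation factor (default 1, pure
#'   multinomial noise).
#' @return a [poll_table()] with `n_units` rows.
#' @export
gen_polls <- function(n_units, respondents, g = latent_linear(),
                      seed = NULL, overdispersion = 1) {
  if (any(respondents <= 0)) stop("respondents must be positive")
  if (!is.null(seed)) set.seed(seed)
  m <- if (length(respondents) == 2)
    sample(respondents[1]:respondents[2], n_units, replace = TRUE)
  else rep_len(as.integer(respondents), n_units)
  f <- runif(n_units, 0.05, 0.95)
  fe <- pmin(g(f), f)
  fe_neg <- pmin(g(1 - f), 1 - f)
  probs <- cbind(fe, f - fe, (1 - f) - fe_neg, fe_neg)
  counts <- matrix(0L, n_units, 4)
  for (i in seq_len(n_units)) {
    p <- probs[i, ]
    if (overdispersion > 1) {
      conc <- (m[i] - overdispersion) / (overdispersion - 1)
      a <- rgamma(4, shape = pmax(p, 1e-12) * conc)
      p <- a / sum(a)
    }
    counts[i, ] <- rmultinom(1, m[i], p)
  }
  poll_table(sprintf("unit%04d", seq_len(n_units)),
             counts[, 1], counts[, 2], counts[, 3], counts[, 4],
             n_total = m)
}

#' Generate poll tables from a model sweep
#'
#' Units sample latent (f, fe) pairs from the sweep's model curve (with
#' multinomial respondent noise), closing the loop between the simulator
#' and the empirical pipeline: [fit_mean_degree()] should recover the
#' sweep's mean degree from the generated table.
#'
#' @param sweep an `opinion_sweep`.
#' @param n_units,respondents,seed as in [gen_polls()].
#' @return a [poll_table()].
#' @export
gen_from_model <- function(sweep, n_units, respondents, seed = NULL) {
  gen_polls(n_units, respondents, g = latent_from_sweep(sweep),
            seed = seed)
}
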