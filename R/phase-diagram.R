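# Phase diagram in the (f_e, <k>) plane and classification of societies.

#' Build the extreme-opinion phase diagram
#'
#' For each mean degree, an f0 sweep and an avalanche profile locate the
#' two critical points; these are mapped from f0 into the observable
#' extremist fraction `f_e` through the sweep's own f0-to-mean-fe
#' relation, giving the percolation line (`fe_c1`, Phase I / Phase II
#' boundary) and the extreme-consensus line (`fe_c2`, Phase II / III
#' boundary), each carrying the transition-order label.
#'
#' @param k_grid increasing vector of mean degrees.
#' @param n network size used for every sweep (a reported parameter of
#'   the diagram).
#' @param f0_grid sweep grid covering both critical points at all
#'   degrees.
#' @param n_realizations realizations per cell.
#' @param base_seed integer seed.
#' @param params a [model_params()].
#' @param aval_realizations realizations for the avalanche profiles
#'   (defaults to `n_realizations`).
#' @return object of class `phase_diagram`: data.frame `lines` with
#'   columns `k`, `fe_c1`, `fe_c2`, `order`, plus metadata.
#' @export
build_phase_diagram <- function(k_grid, n, f0_grid, n_realizations = 10,
                                base_seed = 1, params = model_params(),
                                aval_realizations = n_realizations) {
  rows <- vector("list", length(k_grid))
  for (ki in seq_along(k_grid)) {
    seed <- base_seed + 10000L * ki
    sw <- run_sweep(n, k_grid[ki], f0_grid, n_realizations, seed, params)
    av <- avalanche_profile(n, k_grid[ki], f0_grid, aval_realizations,
                            seed + 5000L, params)
    cp <- find_critical_points(sw, av)
    s <- sw$summary
    fe_of_f0 <- function(f0) approx(s$f0, s$fe, xout = f0, rule = 2)$y
    rows[[ki]] <- data.frame(k = k_grid[ki],
                             f0_c1 = cp$f0_c1, f0_c2 = cp$f0_c2,
                             fe_c1 = fe_of_f0(cp$f0_c1),
                             fe_c2 = fe_of_f0(cp$f0_c2),
                             order = as.character(cp$order))
  }
  lines <- do.call(rbind, rows)
  if (any(lines$fe_c2 < lines$fe_c1))
    warning("fe_c2 below fe_c1 at some degree; increase realizations")
  structure(list(lines = lines,
                 meta = list(n = n, f0_grid = f0_grid,
                             n_realizations = n_realizations,
                             base_seed = base_seed, params = params)),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase_diagram: %d degrees, n = %d\n", nrow(x$lines),
              x$meta$n))
  print(x$lines)
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  l <- x$lines
  graphics::matplot(cbind(l$fe_c1, l$fe_c2), l$k, type = "b", pch = 16,
                    lty = 1, col = c("blue", "black"),
                    xlab = expression(f[e]), ylab = "<k>", ...)
  graphics::legend("topright", legend = c("I / II line", "II / III line"),
                   col = c("blue", "black"), lty = 1, bty = "n")
  invisible(x)
}

#' Classify a society in the phase diagram
#'
#' Compares an observed extremist fraction against the two transition
#' lines interpolated at the society's effective mean degree. Phase I:
#' no giant e-cluster (below the percolation line); Phase II: incipient
#' giant e-cluster with growing cascades (between the lines); Phase III:
#' extremist consensus (above the upper line).
#'
#' @param fe observed extremist fraction.
#' @param k_mean effective mean degree; must lie within the diagram's
#'   degree grid.
#' @param diagram a `phase_diagram`.
#' @return `"I"`, `"II"`, or `"III"`.
#' @export
classify_society <- function(fe, k_mean, diagram) {
  l <- diagram$lines
  if (k_mean < min(l$k) || k_mean > max(l$k))
    stop("k_mean outside the diagram's degree grid")
  c1 <- approx(l$k, l$fe_c1, xout = k_mean)$y
  c2 <- approx(l$k, l$fe_c2, xout = k_mean)$y
  if (fe < c1) "I" else if (fe < c2) "II" else "III"
}

#' Fit an effective mean degree to empirical (f, fe) points
#'
#' For each candidate degree the model's (f, fe) curve is generated by an
#' f0 sweep (at the default stubbornness and threshold unless overridden),
#' the model fe is interpolated at each empirical f, and the candidate
#' minimising the sum of squared vertical residuals is returned. Grid
#' search only -- no smoothness assumptions about the objective.
#'
#' @param points data.frame with columns `f` and `fe` (one row per survey
#'   unit or rating item).
#' @param k_candidates candidate mean degrees (sorted).
#' @param n,f0_grid,n_realizations,base_seed,params simulation budget for
#'   the per-candidate model curves.
#' @return list with `k` (argmin candidate), `sse` (per candidate), and
#'   the model curves.
#' @export
fit_mean_degree <- function(points, k_candidates, n = 2000,
                            f0_grid = seq(0.02, 0.98, by = 0.04),
                            n_realizations = 4, base_seed = 1,
                            params = model_params()) {
  points <- as.data.frame(points)
  if (nrow(points) < 10) stop("need at least 10 (f, fe) points")
  k_candidates <- sort(k_candidates)
  sse <- numeric(length(k_candidates))
  curves <- vector("list", length(k_candidates))
  for (ci in seq_along(k_candidates)) {
    sw <- run_sweep(n, k_candidates[ci], f0_grid, n_realizations,
                    base_seed + 100L * ci, params)
    mc <- model_curve(sw)
    mc <- mc[order(mc$f), ]
    pred <- approx(mc$f, mc$fe, xout = points$f, ties = mean)$y
    drop <- is.na(pred)
    if (any(drop))
      warning(sprintf("%d point(s) outside the model curve support dropped",
                      sum(drop)))
    sse[ci] <- sum((points$fe[drop == FALSE] - pred[!drop])^2)
    curves[[ci]] <- mc
  }
  names(sse) <- format(k_candidates)
  list(k = k_candidates[which.min(sse)], sse = sse, curves = curves)
}
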