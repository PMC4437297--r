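#' Sweep the initial positive fraction f0 over network realizations
#'
#' For each value of `f0` and each realization, a fresh Erdos-Renyi
#' network is generated, opinions are initialised, the dynamics is relaxed
#' and the final-state observables recorded. The cell at grid index `i`
#' (1-based) and realization `r` uses seed
#' `base_seed + (r - 1) * |grid| + (i - 1)`, so any single cell can be
#' reproduced independently. Non-convergent relaxations (period-2 cycles
#' at `a = 0`) contribute their cycle-averaged state and are flagged.
#'
#' @param n network size.
#' @param k_mean target mean degree.
#' @param f0_grid strictly increasing vector of initial positive fractions.
#' @param n_realizations networks per grid point.
#' @param base_seed integer seed anchoring the per-cell seeds.
#' @param params a [model_params()].
#' @return an object of class `opinion_sweep`: list with `raw` (tidy
#'   data.frame: `f0`, `realization`, `f`, `fe`, `g1`, `g2`, `converged`),
#'   `summary` (per-f0 means and standard errors), and `config`.
#' @examples
#' sw <- run_sweep(300, 4, c(0.2, 0.5, 0.8), n_realizations = 2,
#'                 base_seed = 1)
#' sw$summary
#' @export
run_sweep <- function(n, k_mean, f0_grid, n_realizations = 1,
                      base_seed = 1, params = model_params()) {
  if (anyDuplicated(f0_grid) || is.unsorted(f0_grid, strictly = TRUE))
    stop("f0_grid must be strictly increasing (no duplicates)")
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  ng <- length(f0_grid)
  rows <- vector("list", ng * n_realizations)
  idx <- 0L
  for (r in seq_len(n_realizations)) {
    for (i in seq_len(ng)) {
      seed <- base_seed + (r - 1L) * ng + (i - 1L)
      set.seed(seed)
      net <- generate_er(n, k_mean)
      st <- init_opinions(net, f0_grid[i])
      st <- relax(st, params)
      fr <- fractions(st, params$q_e)
      ec <- e_clusters(st, params$q_e)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        f0 = f0_grid[i], realization = r, seed = seed,
        f = fr$f_pos, fe = fr$fe_pos, g1 = ec$g1, g2 = ec$g2,
        converged = st$converged)
    }
  }
  raw <- do.call(rbind, rows)
  agg <- function(v) {
    m <- tapply(raw[[v]], raw$f0, mean)
    s <- tapply(raw[[v]], raw$f0, function(x)
      if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_)
    list(mean = as.numeric(m), se = as.numeric(s))
  }
  vars <- c("f", "fe", "g1", "g2")
  summ <- data.frame(f0 = f0_grid)
  for (v in vars) {
    a <- agg(v)
    summ[[v]] <- a$mean
    summ[[paste0(v, "_se")]] <- a$se
  }
  structure(list(raw = raw, summary = summ,
                 config = list(n = n, k_mean = k_mean, f0_grid = f0_grid,
                               n_realizations = n_realizations,
                               base_seed = base_seed, params = params)),
            class = "opinion_sweep")
}

#' @export
print.opinion_sweep <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "opinion_sweep: n = %d, <k> = %g, a = %g, q_e = %g, %d f0 points x %d realizations\n",
    cf$n, cf$k_mean, cf$params$a, cf$params$q_e, length(cf$f0_grid),
    cf$n_realizations))
  print(head(x$summary))
  invisible(x)
}

#' @export
plot.opinion_sweep <- function(x, ...) {
  s <- x$summary
  graphics::matplot(s$f0, cbind(s$f, s$fe, s$g1, s$g2), type = "l",
                    lty = 1, col = c("black", "red", "blue", "darkgreen"),
                    xlab = expression(f[0]), ylab = "value", ...)
  graphics::legend("topleft", legend = c("f", "fe", "g1", "g2"), lty = 1,
                   col = c("black", "red", "blue", "darkgreen"), bty = "n")
  invisible(x)
}

#' Parametric (f, fe) curve of a sweep
#'
#' The per-f0 means of the final moderate-or-extreme fraction `f` and the
#' extremist fraction `fe`, ordered by `f0`; the shape of this curve is
#' what survey data can be compared against.
#'
#' @param sweep an `opinion_sweep`.
#' @return data.frame with columns `f0`, `f`, `fe`.
#' @export
model_curve <- function(sweep) {
  s <- sweep$summary
  data.frame(f0 = s$f0, f = s$f, fe = s$fe)
}
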