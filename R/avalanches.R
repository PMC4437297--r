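#' Perturb a single vulnerable node and measure the avalanche
#'
#' Starting from a relaxed state, one vulnerable node (opinion
#' `0 < q < q_e`) is forced to the extreme opinion `q = 1` and the system
#' is re-relaxed. The avalanche size `S` counts the other previously
#' vulnerable nodes that end up extreme (`q > q_e`); the trigger itself is
#' excluded since it was set extreme by fiat. The input state is not
#' modified.
#'
#' @param stable a relaxed `opinion_state`.
#' @param trigger node id with `0 < q < q_e` in `stable`.
#' @param params a [model_params()].
#' @return list with `trigger`, `size_s`, `succeeded` (`S >= 1`).
#' @export
perturb_one <- function(stable, trigger, params = model_params()) {
  q <- stable$q
  if (trigger < 1 || trigger > length(q)) stop("unknown node id")
  if (!(q[trigger] > 0 && q[trigger] < params$q_e))
    stop("trigger is not vulnerable (needs 0 < q < q_e)")
  net <- stable$network
  s <- cpp_avalanche_scan(net$xadj, net$adjncy, q,
                          as.integer(trigger - 1L), params$a,
                          mix_coef(params), params$q_e, params$tol,
                          params$max_steps, zero_rule_code(params))
  list(trigger = trigger, size_s = as.integer(s), succeeded = s >= 1L)
}

#' Avalanche scan over all vulnerable nodes
#'
#' Every vulnerable node (`0 < q < q_e`) is perturbed one at a time
#' against the same base state (no compounding), and the avalanche sizes
#' are aggregated. `mean_s` averages over triggers that succeeded
#' (`S >= 1`); `s_star` is the largest size observed.
#'
#' @param stable a relaxed `opinion_state`.
#' @param params a [model_params()].
#' @param max_triggers optional cap: when the state holds more vulnerable
#'   nodes than this, a uniform subsample of triggers is scanned instead
#'   of all of them (deterministic given the current RNG state). The
#'   default scans every vulnerable node.
#' @return object of class `avalanche_summary`: list with `sizes` (one
#'   entry per vulnerable trigger), `mean_s` (`NA` if no success),
#'   `s_star` (0 if no triggers), `n_triggers`, `n_succeeded`.
#' @export
avalanche_scan <- function(stable, params = model_params(),
                           max_triggers = Inf) {
  q <- stable$q
  triggers <- which(q > 0 & q < params$q_e)
  if (length(triggers) > max_triggers)
    triggers <- sort(sample(triggers, max_triggers))
  net <- stable$network
  if (length(triggers) == 0) {
    sizes <- integer(0)
  } else {
    sizes <- as.integer(cpp_avalanche_scan(
      net$xadj, net$adjncy, q, as.integer(triggers - 1L), params$a,
      mix_coef(params), params$q_e, params$tol, params$max_steps,
      zero_rule_code(params)))
  }
  ok <- sizes >= 1L
  structure(list(sizes = sizes, triggers = triggers,
                 mean_s = if (any(ok)) mean(sizes[ok]) else NA_real_,
                 s_star = if (length(sizes)) max(sizes) else 0L,
                 n_triggers = length(triggers), n_succeeded = sum(ok)),
            class = "avalanche_summary")
}

#' @export
print.avalanche_summary <- function(x, ...) {
  cat(sprintf(
    "avalanche_summary: %d triggers, %d succeeded, <S> = %s, S* = %d\n",
    x$n_triggers, x$n_succeeded,
    if (is.na(x$mean_s)) "NA" else sprintf("%.2f", x$mean_s), x$s_star))
  invisible(x)
}

#' Avalanche statistics along an f0 grid
#'
#' For each `f0` and realization: fresh Erdos-Renyi network, initial
#' opinions, relaxation, then a full [avalanche_scan()]. Seeding follows
#' the same per-cell contract as [run_sweep()], so the underlying states
#' match a sweep run with the same arguments.
#'
#' @inheritParams run_sweep
#' @param keep_sizes pool and return all avalanche sizes per f0.
#' @param max_triggers per-state trigger cap, see [avalanche_scan()].
#' @return list with `summary` (data.frame: `f0`, `s_star` = mean over
#'   realizations of the per-realization largest size, `s_star_max`,
#'   `mean_s`) and, if `keep_sizes`, `sizes` (named list per f0 of pooled
#'   positive avalanche sizes).
#' @export
avalanche_profile <- function(n, k_mean, f0_grid, n_realizations = 1,
                              base_seed = 1, params = model_params(),
                              keep_sizes = FALSE, max_triggers = Inf) {
  ng <- length(f0_grid)
  s_star <- matrix(NA_real_, ng, n_realizations)
  mean_s <- matrix(NA_real_, ng, n_realizations)
  pooled <- if (keep_sizes) vector("list", ng) else NULL
  for (r in seq_len(n_realizations)) {
    for (i in seq_len(ng)) {
      seed <- base_seed + (r - 1L) * ng + (i - 1L)
      set.seed(seed)
      net <- generate_er(n, k_mean)
      st <- relax(init_opinions(net, f0_grid[i]), params)
      av <- avalanche_scan(st, params, max_triggers = max_triggers)
      s_star[i, r] <- av$s_star
      mean_s[i, r] <- av$mean_s
      if (keep_sizes)
        pooled[[i]] <- c(pooled[[i]], av$sizes[av$sizes >= 1L])
    }
  }
  summ <- data.frame(
    f0 = f0_grid,
    s_star = rowMeans(s_star),
    s_star_max = apply(s_star, 1, max),
    mean_s = rowMeans(mean_s, na.rm = TRUE))
  out <- list(summary = summ,
              config = list(n = n, k_mean = k_mean, f0_grid = f0_grid,
                            n_realizations = n_realizations,
                            base_seed = base_seed, params = params))
  if (keep_sizes) {
    names(pooled) <- format(f0_grid)
    out$sizes <- pooled
  }
  structure(out, class = "avalanche_profile")
}

#' @export
print.avalanche_profile <- function(x, ...) {
  cat(sprintf("avalanche_profile: n = %d, <k> = %g, %d f0 points\n",
              x$config$n, x$config$k_mean, nrow(x$summary)))
  print(head(x$summary))
  invisible(x)
}
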