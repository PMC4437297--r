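#' Model parameters
#'
#' @param a stubbornness in `[0, 1]`. It widens the range of neighbour
#'   opinions a node ignores and weights the node's own opinion when it
#'   compromises. `a = 0` reduces the dynamics to synchronous neighbour
#'   averaging (consensus); at `a = 1` a node only ever adopts a
#'   more-extreme same-sign neighbourhood mean.
#' @param q_e extremism threshold in `(0, 1)`: opinions with `|q| > q_e`
#'   count as extreme. Four-category surveys motivate the default 0.5.
#' @param tol convergence tolerance on the maximum per-node opinion change
#'   in one synchronous sweep.
#' @param max_steps cap on synchronous sweeps during relaxation.
#' @param compromise_weight which side the stubbornness weights in the
#'   rule-(iii) compromise. `"self"` (default) gives
#'   `(1 - a) qbar + a q`: the node's own opinion carries weight `a`, and
#'   `a = 0` reduces the whole dynamics to synchronous neighbour averaging
#'   (the consensus limit). `"neighbors"` gives `a qbar + (1 - a) q`, the
#'   convention implied by the model's worked single-node example
#'   (q = 0.5, a = 0.8 moving to -0.3); at `a = 1` it adopts opposing
#'   neighbourhood means outright, which is what produces the abrupt
#'   extreme-consensus transitions and macroscopic opinion cascades at
#'   high mean degree. The inflexibility range of rule (ii) is
#'   `[(1 - a)|q|, |q|]` under both conventions. See the methods vignette
#'   for why both conventions are kept.
#' @param zero_opinion_rule convention for the measure-zero case `q = 0`
#'   (sign undefined, so the adopt/hold rules cannot fire): `"mix"` applies
#'   the compromise formula (dropping the `q` term); `"adopt"` takes the
#'   neighbourhood mean.
#' @return an object of class `model_params`.
#' @export
model_params <- function(a = 1, q_e = 0.5, tol = 1e-9, max_steps = 10000L,
                         compromise_weight = c("self", "neighbors"),
                         zero_opinion_rule = c("mix", "adopt")) {
  compromise_weight <- match.arg(compromise_weight)
  zero_opinion_rule <- match.arg(zero_opinion_rule)
  if (a < 0 || a > 1) stop("a must be in [0, 1]")
  if (q_e <= 0 || q_e >= 1) stop("q_e must be in (0, 1)")
  if (tol <= 0) stop("tol must be positive")
  if (max_steps < 1) stop("max_steps must be >= 1")
  structure(list(a = a, q_e = q_e, tol = tol,
                 max_steps = as.integer(max_steps),
                 compromise_weight = compromise_weight,
                 zero_opinion_rule = zero_opinion_rule),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: a = %g, q_e = %g, tol = %g, max_steps = %d\n  compromise weight on %s, q = 0 rule: %s\n",
    x$a, x$q_e, x$tol, x$max_steps, x$compromise_weight,
    x$zero_opinion_rule))
  invisible(x)
}

zero_rule_code <- function(params) {
  match(params$zero_opinion_rule, c("mix", "adopt")) - 1L
}

# weight of the node's own opinion in the rule-(iii) compromise
mix_coef <- function(params) {
  if (params$compromise_weight == "self") params$a else 1 - params$a
}

#' Read or write an opinion state as CSV
#'
#' Two columns: `node_id` (1-based) and `q`. Reading requires the network
#' the opinions live on.
#'
#' @param state an `opinion_state`.
#' @param path CSV file path.
#' @param net an [opinion_network()] with matching node count.
#' @export
write_state_csv <- function(state, path) {
  write.csv(data.frame(node_id = seq_along(state$q), q = state$q), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_csv
#' @export
read_state_csv <- function(path, net) {
  d <- read.csv(path)
  q <- numeric(nrow(d))
  q[d$node_id] <- d$q
  opinion_state(q, net)
}

#' Mean opinion of a node's neighbours
#'
#' @param state an `opinion_state`.
#' @param node node id (1-based).
#' @return the arithmetic mean of the neighbours' opinions, or `NA` for a
#'   degree-0 node (no social input).
#' @export
neighbor_mean <- function(state, node) {
  net <- state$network
  if (length(node) != 1 || is.na(node) || node < 1 || node > net$n)
    stop("unknown node id")
  lo <- net$xadj[node] + 1L
  hi <- net$xadj[node + 1L]
  if (hi < lo) return(NA_real_)
  mean(state$q[net$adjncy[lo:hi] + 1L])
}

#' Apply the opinion update rules to one node
#'
#' For a node with opinion `q > 0` facing neighbourhood mean `qbar`:
#' rule (i) adopts `qbar` when `qbar > q` (a more extreme same-sign mean
#' pulls the node outward); rule (ii) keeps `q` when
#' `(1 - a) q <= qbar <= q` (the stubbornness-widened inflexibility range);
#' rule (iii) compromises to `(1 - a) qbar + a q` when `qbar < (1 - a) q`
#' (the mean is opposite in sign or much more moderate). The rules are
#' mirror-symmetric for `q < 0`. An undefined `qbar` (`NA`, degree-0 node)
#' leaves `q` unchanged. Exactly one branch fires for any input; boundary
#' ties belong to rule (ii).
#'
#' Vectorised over `q` and `qbar`.
#'
#' @param q current opinion(s) in `[-1, 1]`.
#' @param qbar neighbourhood mean(s) in `[-1, 1]`, or `NA`.
#' @param params a [model_params()].
#' @return updated opinion(s), guaranteed to stay in `[-1, 1]` (every
#'   branch is a convex combination of values in the interval).
#' @examples
#' p <- model_params(a = 0.8)
#' update_node(0.5, 0.8, p)   # rule (i): adopt
#' update_node(0.5, 0.2, p)   # rule (ii): hold
#' update_node(0.5, -0.5, p)  # rule (iii): compromise to 0.3
#' @export
update_node <- function(q, qbar, params = model_params()) {
  if (any(q < -1 | q > 1, na.rm = TRUE) ||
      any(qbar < -1 | qbar > 1, na.rm = TRUE))
    stop("opinions must lie in [-1, 1]")
  m <- max(length(q), length(qbar))
  q <- rep_len(q, m); qbar <- rep_len(qbar, m)
  a <- params$a
  mx <- mix_coef(params)
  out <- numeric(m)
  und <- is.na(qbar)
  pos <- !und & q > 0
  neg <- !und & q < 0
  zer <- !und & q == 0
  out[und] <- q[und]
  i1 <- pos & qbar > q
  i2 <- pos & qbar <= q & qbar >= (1 - a) * q
  i3 <- pos & qbar < (1 - a) * q
  out[i1] <- qbar[i1]
  out[i2] <- q[i2]
  out[i3] <- (1 - mx) * qbar[i3] + mx * q[i3]
  j1 <- neg & qbar < q
  j2 <- neg & qbar >= q & qbar <= (1 - a) * q
  j3 <- neg & qbar > (1 - a) * q
  out[j1] <- qbar[j1]
  out[j2] <- q[j2]
  out[j3] <- (1 - mx) * qbar[j3] + mx * q[j3]
  out[zer] <- if (params$zero_opinion_rule == "mix")
    (1 - mx) * qbar[zer] else qbar[zer]
  out
}

#' One synchronous sweep of the dynamics
#'
#' All neighbourhood means are computed from the input state, then every
#' node is updated; the input state is not modified.
#'
#' @param state an `opinion_state`.
#' @param params a [model_params()].
#' @return a new `opinion_state` with the step counter incremented.
#' @export
step_opinions <- function(state, params = model_params()) {
  net <- state$network
  qn <- cpp_step(net$xadj, net$adjncy, state$q, params$a,
                 mix_coef(params), zero_rule_code(params))
  out <- state
  out$q <- qn
  out$step <- state$step + 1L
  out
}

#' Relax to a stable state
#'
#' Iterates synchronous sweeps until the maximum per-node change falls
#' below `tol`, a period-2 cycle is detected (the state repeats with period
#' 2 within `tol` -- synchronous averaging at `a = 0` can oscillate), or
#' `max_steps` sweeps have run. On a cycle the time average over the two
#' phases is returned and `cycle_detected` is set; non-convergence is
#' reported through the flags, never as an error.
#'
#' @param state an `opinion_state`.
#' @param params a [model_params()].
#' @return the relaxed `opinion_state`.
#' @examples
#' net <- net_complete(3)
#' st <- opinion_state(c(0.9, 0.8, 0.1), net)
#' relax(st, model_params(a = 1))$q        # all pulled up to 0.9
#' relax(st, model_params(a = 0))$q        # consensus at the mean 0.6
#' @export
relax <- function(state, params = model_params()) {
  net <- state$network
  res <- cpp_relax(net$xadj, net$adjncy, state$q, params$a,
                   mix_coef(params), params$tol, params$max_steps,
                   zero_rule_code(params))
  out <- state
  out$q <- res$q
  out$step <- state$step + res$steps
  out$converged <- res$converged
  out$cycle_detected <- res$cycle
  out
}
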