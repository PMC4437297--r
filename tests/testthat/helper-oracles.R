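# Independent straight-line oracles, deliberately naive: plain loops and
# no shared code with the package internals.

# Single-node rule application written as a literal transcription; `mix`
# is the weight of the node's own opinion in the compromise (defaults to
# the stubbornness itself, i.e. the "self" convention).
oracle_rule <- function(q, qbar, a, mix = a) {
  if (is.na(qbar)) return(q)
  if (q > 0) {
    if (qbar > q) return(qbar)
    if (qbar >= (1 - a) * q && qbar <= q) return(q)
    return((1 - mix) * qbar + mix * q)
  }
  if (q < 0) {
    if (qbar < q) return(qbar)
    if (qbar <= (1 - a) * q && qbar >= q) return(q)
    return((1 - mix) * qbar + mix * q)
  }
  (1 - mix) * qbar
}

# Adjacency list from an edge matrix.
oracle_adjlist <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

oracle_step <- function(q, adj, a, mix = a) {
  out <- q
  for (i in seq_along(q)) {
    nb <- adj[[i]]
    qbar <- if (length(nb) == 0) NA_real_ else mean(q[nb])
    out[i] <- oracle_rule(q[i], qbar, a, mix)
  }
  out
}

oracle_relax <- function(q, edges, n, a, tol = 1e-9, max_steps = 10000,
                         mix = a) {
  adj <- oracle_adjlist(edges, n)
  prev2 <- q
  prev <- q
  for (t in seq_len(max_steps)) {
    cur <- oracle_step(prev, adj, a, mix)
    if (max(abs(cur - prev)) < tol) return(cur)
    if (t >= 2 && max(abs(cur - prev2)) < tol) return((cur + prev) / 2)
    prev2 <- prev
    prev <- cur
  }
  cur
}

# Union-find connected components of the extremist-induced subgraph;
# returns decreasing component sizes.
oracle_ecluster_sizes <- function(q, edges, q_e) {
  ext <- which(q > q_e)
  if (length(ext) == 0) return(integer(0))
  parent <- seq_len(length(q))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    if (q[i] > q_e && q[j] > q_e) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(ext, find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# Brute-force weighted local-polynomial value via the normal equations.
oracle_wls_at <- function(x, y, w, x0, degree) {
  keep <- w > 0
  X <- outer(x[keep] - x0, 0:degree, `^`)
  W <- diag(w[keep], nrow = sum(keep))
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y[keep])
  beta[1, 1]
}

# Tiny deterministic random graph for property tests.
random_edges <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}
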