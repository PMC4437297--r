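#' Opinion-fraction statistics of a state
#'
#' Membership is strict: a node counts as positive when `q > 0` and as an
#' extreme positive when `q > q_e` (mirrored for the negative side); with
#' continuous opinions the boundaries are measure-zero. Denominators are
#' the total node count.
#'
#' @param state an `opinion_state` (or a bare numeric vector of opinions).
#' @param q_e extremism threshold.
#' @return list with `f_pos`, `f_neg`, `fe_pos`, `fe_neg`, `n_total`.
#' @examples
#' fractions(c(0.9, 0.6, 0.3, -0.2), q_e = 0.5)
#' @export
fractions <- function(state, q_e = 0.5) {
  q <- if (inherits(state, "opinion_state")) state$q else as.numeric(state)
  n <- length(q)
  list(f_pos = sum(q > 0) / n, f_neg = sum(q < 0) / n,
       fe_pos = sum(q > q_e) / n, fe_neg = sum(q < -q_e) / n,
       n_total = n)
}

#' e-cluster statistics
#'
#' An e-cluster is a connected component of the subgraph induced by the
#' extremists of one polarity (`q > q_e`). The largest (`g1`) and second
#' largest (`g2`) e-cluster sizes are normalised by the size of the
#' largest connected component of the full network; `g2 = 0` when there
#' are fewer than two clusters.
#'
#' @param state an `opinion_state`.
#' @param q_e extremism threshold.
#' @param polarity `"positive"` (the phase analysis tracks positive
#'   e-clusters) or `"negative"`.
#' @return list with `g1`, `g2`, `n_clusters`, and the raw integer
#'   `sizes` of all e-clusters (unnormalised, decreasing).
#' @examples
#' net <- net_path(4)
#' st <- opinion_state(c(0.9, 0.6, 0.3, 0.8), net)
#' e_clusters(st, q_e = 0.5)   # clusters {1,2} and {4}: g1 = 0.5, g2 = 0.25
#' @export
e_clusters <- function(state, q_e = 0.5,
                       polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  net <- state$network
  q <- if (polarity == "positive") state$q else -state$q
  ext <- which(q > q_e)
  norm <- net$lcc_size
  if (length(ext) == 0)
    return(list(g1 = 0, g2 = 0, n_clusters = 0L, sizes = integer(0)))
  inext <- logical(net$n)
  inext[ext] <- TRUE
  e <- net$edges
  keep <- inext[e[, 1]] & inext[e[, 2]]
  map <- integer(net$n)
  map[ext] <- seq_along(ext)
  sub <- cbind(map[e[keep, 1]], map[e[keep, 2]])
  g <- igraph::make_empty_graph(length(ext), directed = FALSE)
  if (nrow(sub) > 0) g <- igraph::add_edges(g, t(sub))
  sizes <- sort(igraph::components(g)$csize, decreasing = TRUE)
  list(g1 = sizes[1] / norm,
       g2 = if (length(sizes) > 1) sizes[2] / norm else 0,
       n_clusters = length(sizes),
       sizes = as.integer(sizes))
}
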