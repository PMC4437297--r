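#' Build an opinion network from an edge list
#'
#' Networks are simple undirected graphs (no self-loops, no multi-edges) on
#' nodes `1..n`. Internally a compressed adjacency structure is kept for the
#' compiled dynamics, and the size of the largest connected component is
#' cached because e-cluster sizes are normalised by it.
#'
#' @param edges two-column integer matrix of undirected edges (1-based node
#'   ids); zero-row matrix allowed.
#' @param n number of nodes.
#' @param k_target the target mean degree, if the graph came from a random
#'   ensemble (stored for bookkeeping; `NA` otherwise).
#' @return an object of class `opinion_network` with fields `n`, `edges`,
#'   `k_mean` (realised mean degree \eqn{2|E|/n}), `k_target`, `deg`, and
#'   `lcc_size` (largest-component size).
#' @export
opinion_network <- function(edges, n, k_target = NA_real_) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("multi-edges are not allowed")
  }
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  deg <- tabulate(src, nbins = n)
  o <- order(src)
  net <- structure(list(
    n = as.integer(n),
    edges = edges,
    k_mean = 2 * nrow(edges) / n,
    k_target = k_target,
    deg = deg,
    xadj = c(0L, cumsum(deg)),
    adjncy = dst[o] - 1L
  ), class = "opinion_network")
  comp <- net_components(net)
  net$lcc_size <- if (length(comp$csize)) max(comp$csize) else 0L
  net
}

net_components <- function(net) {
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  g <- igraph::add_vertices(g, net$n - igraph::vcount(g))
  igraph::components(g)
}

#' @export
print.opinion_network <- function(x, ...) {
  cat(sprintf(
    "opinion_network: %d nodes, %d edges, <k> = %.3f (largest component %d)\n",
    x$n, nrow(x$edges), x$k_mean, x$lcc_size))
  invisible(x)
}

#' Generate an Erdos-Renyi random network
#'
#' G(n, p) with `p = k_mean / (n - 1)`, so the expected mean degree is
#' `k_mean`. The realised mean degree is stored on the returned network.
#'
#' @param n number of nodes.
#' @param k_mean target mean degree, `0 < k_mean < n` (values `>= n - 1`
#'   give the complete graph).
#' @param seed optional integer seed; when supplied the generation is
#'   reproducible.
#' @return an [opinion_network()].
#' @examples
#' net <- generate_er(200, 4, seed = 1)
#' net$k_mean
#' @export
generate_er <- function(n, k_mean, seed = NULL) {
  if (k_mean <= 0 || k_mean >= n) stop("need 0 < k_mean < n")
  if (!is.null(seed)) set.seed(seed)
  p <- min(1, k_mean / (n - 1))
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  opinion_network(igraph::as_edgelist(g, names = FALSE), n,
                  k_target = k_mean)
}

#' Largest connected component
#'
#' @param net an [opinion_network()].
#' @return integer vector of node ids of the maximal connected set; ties
#'   between equal-size components are broken towards the component
#'   containing the smallest node id.
#' @export
largest_component <- function(net) {
  if (net$n == 0) return(integer(0))
  comp <- net_components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    first_node <- vapply(best, function(b) min(which(comp$membership == b)),
                         integer(1))
    best <- best[which.min(first_node)]
  }
  which(comp$membership == best)
}

#' Restrict a network to its largest component
#'
#' Nodes are re-indexed `1..m`; useful when the dynamics should run on a
#' single connected society.
#'
#' @param net an [opinion_network()].
#' @return an [opinion_network()] on the largest component.
#' @export
keep_largest_component <- function(net) {
  keep <- largest_component(net)
  map <- integer(net$n)
  map[keep] <- seq_along(keep)
  e <- net$edges
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  opinion_network(cbind(map[e[, 1]], map[e[, 2]]), length(keep),
                  k_target = net$k_target)
}

#' Assign initial opinions
#'
#' Exactly `round(f0 * n)` distinct nodes, chosen uniformly, receive
#' opinions drawn from Uniform(0, 1); the remaining nodes from
#' Uniform(-1, 0). Fixing the count (rather than sampling each node with
#' probability `f0`) removes initial-condition binomial variance. The
#' expected initial extremist fraction at threshold `q_e` is
#' `(1 - q_e) * f0`.
#'
#' @param net an [opinion_network()].
#' @param f0 initial fraction of positive-opinion nodes, in `[0, 1]`.
#' @param seed optional integer seed.
#' @return an object of class `opinion_state`: list with `q` (opinions),
#'   `network`, `step`, `converged`, `cycle_detected`.
#' @export
init_opinions <- function(net, f0, seed = NULL) {
  if (f0 < 0 || f0 > 1) stop("f0 must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- net$n
  npos <- round(f0 * n)
  q <- -runif(n)
  if (npos > 0) {
    pos <- sample.int(n, npos)
    q[pos] <- runif(npos)
  }
  opinion_state(q, net)
}

#' @rdname opinion_network
#' @param q numeric vector of opinions in `[-1, 1]`, one per node.
#' @param net an [opinion_network()].
#' @export
opinion_state <- function(q, net) {
  if (length(q) != net$n) stop("length(q) must equal the node count")
  if (any(q < -1 | q > 1)) stop("opinions must lie in [-1, 1]")
  structure(list(q = as.numeric(q), network = net, step = 0L,
                 converged = FALSE, cycle_detected = FALSE),
            class = "opinion_state")
}

#' @export
print.opinion_state <- function(x, ...) {
  cat(sprintf(
    "opinion_state: %d nodes, step %d, converged = %s, cycle = %s\n",
    length(x$q), x$step, x$converged, x$cycle_detected))
  cat(sprintf("  mean q = %.4f, positive fraction = %.4f\n",
              mean(x$q), mean(x$q > 0)))
  invisible(x)
}

# --- deterministic fixture graphs ------------------------------------------

#' Fixture graphs for tests and examples
#'
#' @param n number of nodes.
#' @return an [opinion_network()].
#' @export
net_path <- function(n) {
  opinion_network(cbind(seq_len(n - 1), seq_len(n - 1) + 1L), n)
}

#' @rdname net_path
#' @export
net_star <- function(n) {
  opinion_network(cbind(1L, seq.int(2L, n)), n)
}

#' @rdname net_path
#' @export
net_complete <- function(n) {
  opinion_network(t(utils::combn(n, 2)), n)
}

#' @rdname net_path
#' @param isolate add one degree-0 node after the two triangles.
#' @export
net_two_triangles <- function(isolate = TRUE) {
  e <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))
  opinion_network(e, if (isolate) 7L else 6L)
}

# --- edge-list text IO ------------------------------------------------------

#' Read or write a network as a whitespace-separated edge list
#'
#' Two integer columns, 1-based node ids, one edge per line. The node count
#' is taken as the maximum id unless given.
#'
#' @param net an [opinion_network()].
#' @param path file path.
#' @param n node count override for graphs with trailing isolated nodes.
#' @export
write_edgelist <- function(net, path) {
  write.table(net$edges, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, n = NULL) {
  e <- as.matrix(read.table(path, colClasses = "integer"))
  if (is.null(n)) n <- max(e)
  opinion_network(e, n)
}
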