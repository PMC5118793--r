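#' Coerce to a network tessellation
#'
#' The CA lattice is an undirected, unweighted simple graph. Accepts an
#' igraph object, a two-column edge matrix/data frame (0-based node ids, as
#' in the on-disk edge-list format) or an adjacency matrix. Self-loops and
#' duplicate edges are dropped; directed input is symmetrized.
#'
#' @param x Graph-like input.
#' @param n_nodes Optional node count when an edge list omits isolated
#'   trailing nodes.
#' @return An undirected simple `igraph` graph.
#' @export
as_tessellation <- function(x, n_nodes = NULL) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    return(igraph::simplify(g))
  }
  if (is.matrix(x) && nrow(x) == ncol(x) && nrow(x) > 2) {
    return(igraph::simplify(igraph::graph_from_adjacency_matrix(
      x > 0, mode = "undirected")))
  }
  edges <- as.matrix(x)
  stopifnot(ncol(edges) == 2)
  storage.mode(edges) <- "integer"
  n <- max(if (is.null(n_nodes)) 0L else n_nodes, max(edges) + 1L)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::simplify(igraph::add_edges(g, t(edges) + 1L))
}

# CSR adjacency (0-based) for the C++ kernel.
tessellation_csr <- function(net) {
  adj <- igraph::as_adj_list(net, mode = "all")
  lens <- lengths(adj)
  list(
    ptr = c(0L, cumsum(lens)),
    idx = if (sum(lens)) unlist(lapply(adj, as.integer), use.names = FALSE) - 1L
          else integer(0)
  )
}

#' Neighbourhood density
#'
#' Fraction of a node's neighbours that are alive,
#' `rho_i = (1/k_i) * sum_j A_ij s_j`. An isolated node (degree 0) takes
#' density 0, the continuous limit of "no alive neighbours".
#'
#' @param net A tessellation (anything [as_tessellation()] accepts).
#' @param states Binary state vector, one entry per node.
#' @param nodes Nodes to evaluate (1-based indices); default all.
#' @return Numeric densities in `[0, 1]`.
#' @examples
#' g <- igraph::make_ring(4)
#' neighborhood_density(g, c(1, 0, 1, 0))
#' @export
neighborhood_density <- function(net, states, nodes = NULL) {
  net <- as_tessellation(net)
  stopifnot(length(states) == igraph::vcount(net), all(states %in% c(0, 1)))
  if (is.null(nodes)) nodes <- seq_len(igraph::vcount(net))
  k <- igraph::degree(net)
  alive <- alive_neighbor_counts(net, states)
  ifelse(k[nodes] == 0, 0, alive[nodes] / k[nodes])
}

alive_neighbor_counts <- function(net, states) {
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  as.integer(round(as.vector(A %*% as.numeric(states))))
}

#' Random initial configuration
#'
#' Each node is independently alive with probability `sigma` (the initial
#' alive fraction, 50% in the reference experiments).
#'
#' @inheritParams neighborhood_density
#' @param sigma Alive probability in `[0, 1]`.
#' @param seed Integer seed; the draw is reproducible given
#'   `(seed, N, sigma)`.
#' @return Integer 0/1 vector of length N.
#' @export
initial_state <- function(net, sigma = 0.5, seed = NULL) {
  net <- as_tessellation(net)
  stopifnot(sigma >= 0, sigma <= 1)
  n <- igraph::vcount(net)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  as.integer(stats::runif(n) < sigma)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' One synchronous update step
#'
#' All densities are computed from the current configuration; a dead node
#' becomes alive when the birth condition holds for its density, an alive
#' node stays alive when the survival condition holds, and every other node
#' is dead at the next step.
#'
#' @inheritParams neighborhood_density
#' @param rule An `llna_rule` or rule text.
#' @return The next binary state vector.
#' @examples
#' g <- igraph::make_lattice(c(5, 5), circular = TRUE)
#' llna_step(g, rep(c(1, 0), length.out = 25), "B3/S23")
#' @export
llna_step <- function(net, states, rule) {
  net <- as_tessellation(net)
  states <- as.integer(states)
  stopifnot(length(states) == igraph::vcount(net), all(states %in% 0:1))
  tab <- rule_tables(rule)
  k <- igraph::degree(net)
  alive <- alive_neighbor_counts(net, states)
  iv <- ifelse(k > 0, pmin((9L * alive) %/% k, 8L), 0L)
  as.integer(ifelse(states == 1L, tab$survival[iv + 1L], tab$birth[iv + 1L]))
}

#' Evolve a rule on a network
#'
#' Runs `t` synchronous steps from a random initial configuration and
#' returns the space-time diagram: a `(t+1) x N` binary matrix whose rows
#' are time steps (row 1 = initial configuration) and whose columns are
#' nodes. Downstream measures read each column as that node's binary time
#' series; whether the initial row is included there is controlled at
#' measurement time.
#'
#' @inheritParams llna_step
#' @param t Number of evolution steps (>= 1); 350 in the reference
#'   experiments.
#' @param sigma Initial alive fraction.
#' @param seed Integer seed for the initial configuration.
#' @param init Optional explicit initial state vector (overrides
#'   `sigma`/`seed`).
#' @return An `llna_diagram`: integer matrix with attributes `rule`, `t`,
#'   `sigma`, `seed`.
#' @examples
#' g <- igraph::sample_gnp(50, 0.1)
#' d <- llna_evolve(g, "B3/S23", t = 20, seed = 1)
#' dim(d)
#' @export
llna_evolve <- function(net, rule, t = 350, sigma = 0.5, seed = NULL,
                        init = NULL) {
  net <- as_tessellation(net)
  stopifnot(t >= 1)
  rule <- llna_rule(rule)
  if (is.null(init)) init <- initial_state(net, sigma, seed)
  init <- as.integer(init)
  stopifnot(length(init) == igraph::vcount(net), all(init %in% 0:1))
  csr <- tessellation_csr(net)
  tab <- rule_tables(rule)
  diagram <- evolve_kernel(csr$ptr, csr$idx, init, as.integer(t),
                           tab$birth, tab$survival)
  structure(diagram, class = c("llna_diagram", class(diagram)),
            rule = rule$name, t = t, sigma = sigma, seed = seed)
}

#' @export
print.llna_diagram <- function(x, ...) {
  cat("<llna_diagram> rule ", attr(x, "rule"), ", ", nrow(x) - 1L,
      " steps x ", ncol(x), " nodes, ",
      sprintf("%.1f%% alive overall\n", 100 * mean(x)), sep = "")
  invisible(x)
}

#' Order diagram columns by node degree
#'
#' Visualization convention only (low-degree nodes left, hubs right);
#' feature extraction is permutation-invariant and never reorders.
#'
#' @param diagram An `llna_diagram`.
#' @param net The tessellation the diagram was evolved on.
#' @return The diagram with columns sorted by ascending degree.
#' @export
order_by_degree <- function(diagram, net) {
  net <- as_tessellation(net)
  ord <- order(igraph::degree(net))
  out <- diagram[, ord, drop = FALSE]
  attributes(out)[c("rule", "t", "sigma", "seed")] <-
    attributes(diagram)[c("rule", "t", "sigma", "seed")]
  class(out) <- class(diagram)
  out
}
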