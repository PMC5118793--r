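with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Synthetic network generators
#'
#' Generators for the five network families used in the classification
#' experiments, all emitting simple undirected igraph graphs reproducible
#' per seed.
#'
#' * `generate_er()`: Erdos-Renyi random graph, each pair connected with
#'   probability `p = mean_degree / N`.
#' * `generate_ws()`: Watts-Strogatz small world; ring lattice with
#'   `mean_degree / 2` neighbours per side, each edge rewired with
#'   probability `rewire_p` (default 0.1) avoiding self-loops and duplicate
#'   edges, so the edge count stays exactly `N * mean_degree / 2`.
#' * `generate_ba()`: Barabasi-Albert growth with (possibly non-linear)
#'   preferential attachment probability proportional to `degree^alpha`;
#'   each new node brings `mean_degree / 2` edges.
#' * `generate_dm()`: Dorogovtsev-Mendes-style growth; each new node
#'   attaches to both endpoints of `mean_degree / 4` uniformly chosen
#'   existing edges (each attachment closes a triangle).
#' * `generate_geographical()`: N points uniform in the unit square,
#'   pairs connected with probability `c * exp(-lambda * s_ij)` where
#'   `s_ij` is the Euclidean distance and `c` is calibrated by bisection so
#'   the expected mean degree equals the target.
#'
#' @param N Number of nodes.
#' @param mean_degree Target mean degree.
#' @param seed Integer seed.
#' @param rewire_p Watts-Strogatz rewiring probability.
#' @param alpha Preferential-attachment exponent (1 = classic scale-free).
#' @param lambda Distance-decay scale factor of the geographical model.
#' @return An undirected simple `igraph` graph. Geographical graphs carry
#'   node coordinates as vertex attributes `x`, `y`.
#' @examples
#' g <- generate_er(200, 8, seed = 1)
#' mean(igraph::degree(g))
#' @name generators
NULL

#' @rdname generators
#' @export
generate_er <- function(N, mean_degree, seed = NULL) {
  stopifnot(mean_degree >= 0, mean_degree < N)
  with_seed(seed, igraph::sample_gnp(N, mean_degree / N, directed = FALSE))
}

#' @rdname generators
#' @export
generate_ws <- function(N, mean_degree, rewire_p = 0.1, seed = NULL) {
  if (mean_degree %% 2 != 0) {
    stop("small-world mean_degree must be even", call. = FALSE)
  }
  stopifnot(mean_degree < N, rewire_p >= 0, rewire_p <= 1)
  half <- mean_degree %/% 2L
  from <- rep(seq_len(N), each = half)
  to <- ((from + rep(seq_len(half), times = N) - 1L) %% N) + 1L
  edges <- cbind(from, to)
  with_seed(seed, {
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    present <- new.env(parent = emptyenv())
    for (e in seq_len(nrow(edges))) {
      assign(key(edges[e, 1], edges[e, 2]), TRUE, envir = present)
    }
    rewire <- stats::runif(nrow(edges)) < rewire_p
    for (e in which(rewire)) {
      i <- edges[e, 1]
      # keep the edge if no admissible new endpoint is found quickly
      for (try in 1:50) {
        j <- sample.int(N, 1)
        if (j != i && !exists(key(i, j), envir = present)) {
          rm(list = key(edges[e, 1], edges[e, 2]), envir = present)
          assign(key(i, j), TRUE, envir = present)
          edges[e, 2] <- j
          break
        }
      }
    }
    g <- igraph::make_empty_graph(N, directed = FALSE)
    igraph::add_edges(g, t(edges))
  })
}

#' @rdname generators
#' @export
generate_ba <- function(N, mean_degree, alpha = 1, seed = NULL) {
  m <- mean_degree / 2
  stopifnot(m >= 1, m == round(m))
  with_seed(seed, igraph::sample_pa(N, power = alpha, m = as.integer(m),
                                    directed = FALSE))
}

#' @rdname generators
#' @export
generate_dm <- function(N, mean_degree, seed = NULL) {
  stopifnot(N >= 4, mean_degree %% 2 == 0)
  m_e <- mean_degree / 4
  if (m_e != round(m_e)) {
    m_e <- max(1, round(m_e))
    warning("mean_degree not divisible by 4; attaching to ", m_e,
            " edge(s) per step (realized mean degree about ", 4 * m_e, ")")
  }
  m_e <- as.integer(m_e)
  with_seed(seed, {
    edges <- matrix(0L, nrow = 2L * m_e * N, ncol = 2)
    edges[1:3, ] <- cbind(c(1L, 2L, 1L), c(2L, 3L, 3L))
    n_edges <- 3L
    for (v in 4:N) {
      # resample until the selected edges have disjoint endpoint pairs
      for (try in 1:50) {
        sel <- sample.int(n_edges, min(m_e, n_edges))
        ends <- unique(as.vector(edges[sel, , drop = FALSE]))
        if (length(ends) == 2L * length(sel)) break
      }
      for (u in ends) {
        n_edges <- n_edges + 1L
        edges[n_edges, ] <- c(v, u)
      }
    }
    g <- igraph::make_empty_graph(N, directed = FALSE)
    igraph::simplify(igraph::add_edges(g, t(edges[seq_len(n_edges), ])))
  })
}

#' @rdname generators
#' @export
generate_geographical <- function(N, mean_degree, lambda = 10, seed = NULL) {
  stopifnot(mean_degree > 0, mean_degree < N)
  with_seed(seed, {
    x <- stats::runif(N)
    y <- stats::runif(N)
    w <- exp(-lambda * as.vector(stats::dist(cbind(x, y))))
    target <- N * mean_degree / 2
    expected <- function(c) sum(pmin(1, c * w))
    lo <- 0
    hi <- 1
    for (i in 1:60) {
      if (expected(hi) >= target) break
      hi <- hi * 2
    }
    if (expected(hi) < target) {
      stop("geographical calibration failed: max achievable mean degree ",
           signif(2 * expected(hi) / N, 4), call. = FALSE)
    }
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (expected(mid) < target) lo <- mid else hi <- mid
    }
    p <- pmin(1, hi * w)
    hit <- which(stats::runif(length(p)) < p)
    i <- rep.int(seq_len(N - 1), (N - 1):1)
    j <- sequence((N - 1):1, from = 2:N)
    g <- igraph::make_empty_graph(N, directed = FALSE)
    g <- igraph::add_edges(g, rbind(i[hit], j[hit]))
    igraph::set_vertex_attr(igraph::set_vertex_attr(g, "x", value = x),
                            "y", value = y)
  })
}

#' Perturb a network with edge noise
#'
#' Removes `round(noise_rate * E)` uniformly chosen existing edges and adds
#' the same number of uniformly chosen absent pairs, preserving the edge
#' count.
#'
#' @param net A tessellation.
#' @param noise_rate Fraction of edges to rewire, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The perturbed graph.
#' @export
perturb_network <- function(net, noise_rate, seed = NULL) {
  net <- as_tessellation(net)
  stopifnot(noise_rate >= 0, noise_rate <= 1)
  E <- igraph::ecount(net)
  n_swap <- round(noise_rate * E)
  if (n_swap == 0) return(net)
  with_seed(seed, {
    g <- igraph::delete_edges(net, sample.int(E, n_swap))
    N <- igraph::vcount(g)
    added <- 0L
    while (added < n_swap) {
      i <- sample.int(N, 1)
      j <- sample.int(N, 1)
      # added pairs are absent from the original network, so removed edges
      # never silently return
      if (i != j && !igraph::are_adjacent(net, i, j) &&
            !igraph::are_adjacent(g, i, j)) {
        g <- igraph::add_edges(g, c(i, j))
        added <- added + 1L
      }
    }
    g
  })
}

#' Generate one network of a named model class
#'
#' Dispatcher over the generators keyed by the class labels used in the
#' experiments: `"random"`, `"small_world"`, `"scalefree"` (linear BA),
#' `"geographical"`, `"ba_0.5"`, `"ba_1"`, `"ba_1.5"`, `"ba_2"` and `"dm"`.
#'
#' @param model Model name.
#' @param N Nodes.
#' @param mean_degree Target mean degree.
#' @param seed Integer seed.
#' @return An igraph graph.
#' @export
generate_network <- function(model, N, mean_degree, seed = NULL) {
  switch(model,
    random = generate_er(N, mean_degree, seed),
    small_world = generate_ws(N, mean_degree, seed = seed),
    scalefree = ,
    ba_1 = generate_ba(N, mean_degree, alpha = 1, seed = seed),
    ba_0.5 = generate_ba(N, mean_degree, alpha = 0.5, seed = seed),
    ba_1.5 = generate_ba(N, mean_degree, alpha = 1.5, seed = seed),
    ba_2 = generate_ba(N, mean_degree, alpha = 2, seed = seed),
    dm = generate_dm(N, mean_degree, seed),
    geographical = generate_geographical(N, mean_degree, seed = seed),
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

#' Build a labeled synthetic dataset
#'
#' Expands a design grid into one generated network per row, with a
#' deterministic per-network seed derived from the master seed so any
#' single network can be regenerated in isolation.
#'
#' @param spec A data frame with columns `model`, `N`, `mean_degree` and
#'   `replicates` (rows are expanded by their replicate count), or the
#'   output of [synthetic_dataset_spec()] / [scalefree_dataset_spec()].
#' @param master_seed Integer master seed.
#' @return A tibble with columns `model`, `N`, `mean_degree`, `replicate`,
#'   `seed` and a list-column `graph`.
#' @examples
#' spec <- synthetic_dataset_spec(mean_degrees = 4, Ns = 100, replicates = 2)
#' build_dataset(spec, master_seed = 1)
#' @export
build_dataset <- function(spec, master_seed = 1) {
  spec <- tibble::as_tibble(spec)
  stopifnot(all(c("model", "N", "mean_degree", "replicates") %in% names(spec)))
  grid <- tidyr::uncount(spec, weights = .data$replicates, .id = "replicate")
  grid$seed <- network_seed(master_seed, grid$model, grid$mean_degree,
                            grid$N, grid$replicate)
  # the generic scale-free class mixes linear and non-linear attachment,
  # cycling the exponent over replicates
  alphas <- c(1, 0.5, 1.5, 2)
  model_eff <- ifelse(grid$model == "scalefree",
                      paste0("ba_", alphas[(grid$replicate - 1) %% 4 + 1]),
                      grid$model)
  grid$graph <- purrr::pmap(
    list(model_eff, grid$N, grid$mean_degree, grid$seed),
    function(model, N, k, seed) generate_network(model, N, k, seed)
  )
  grid
}

# Deterministic, collision-spread per-network seed below 2^31.
network_seed <- function(master, model, mean_degree, N, replicate) {
  h <- vapply(model, function(m) {
    sum(utf8ToInt(m) * seq_along(utf8ToInt(m))) %% 100003
  }, numeric(1))
  v <- (as.numeric(master) * 2654435 + h * 97003 + mean_degree * 7919 +
          N * 104729 + replicate * 15485863)
  as.integer(v %% 2147483629)
}

#' Experiment design grids
#'
#' `synthetic_dataset_spec()` lays out the four-model design (random,
#' small-world, scale-free, geographical) crossed with mean degrees
#' 4-16 and network sizes; the full-size reference design uses
#' `Ns = c(500, 1000, 1500, 2000)` and 100 replicates per cell (11200
#' networks). `scalefree_dataset_spec()` lays out the five scale-free
#' classes (BA with alpha 0.5, 1, 1.5, 2 and Dorogovtsev-Mendes) at
#' N = 1000, mean degree 8. `rule_selection_spec()` is the four-model grid
#' at N = 500 used for rule scans.
#'
#' @param mean_degrees Mean-degree levels.
#' @param Ns Network sizes.
#' @param replicates Networks per design cell.
#' @return A design tibble for [build_dataset()].
#' @export
synthetic_dataset_spec <- function(mean_degrees = seq(4, 16, by = 2),
                                   Ns = c(500, 1000, 1500, 2000),
                                   replicates = 100) {
  tidyr::expand_grid(
    model = c("random", "small_world", "scalefree", "geographical"),
    mean_degree = mean_degrees, N = Ns, replicates = replicates
  )
}

#' @rdname synthetic_dataset_spec
#' @export
scalefree_dataset_spec <- function(Ns = 1000, mean_degrees = 8,
                                   replicates = 100) {
  tidyr::expand_grid(
    model = c("ba_0.5", "ba_1", "ba_1.5", "ba_2", "dm"),
    mean_degree = mean_degrees, N = Ns, replicates = replicates
  )
}

#' @rdname synthetic_dataset_spec
#' @export
rule_selection_spec <- function(mean_degrees = seq(4, 16, by = 2),
                                replicates = 50) {
  synthetic_dataset_spec(mean_degrees, Ns = 500, replicates = replicates)
}
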