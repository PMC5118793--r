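#' Point patterns and proximity networks
#'
#' A 2-D point pattern (e.g. stomata centroids extracted from a leaf image)
#' is turned into a family of proximity networks: after scaling all
#' pairwise distances by the maximum pairwise distance, points closer than
#' a threshold radius `delta` are connected. Edge sets are nested: raising
#' `delta` only adds edges.
#'
#' @param coords A two-column matrix/data frame of (x, y) positions, or a
#'   `point_pattern`.
#' @return `point_pattern()`: object with the coordinates and the
#'   normalized distance matrix.
#' @examples
#' pp <- point_pattern(cbind(runif(20), runif(20)))
#' igraph::ecount(build_threshold_network(pp, 0.3))
#' @export
point_pattern <- function(coords) {
  if (inherits(coords, "point_pattern")) return(coords)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 2)
  d <- as.matrix(stats::dist(coords))
  dmax <- max(d)
  if (dmax == 0) stop("all points coincide", call. = FALSE)
  structure(list(coords = coords, ndist = d / dmax),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat("<point_pattern> ", nrow(x$coords), " points\n", sep = "")
  invisible(x)
}

#' @rdname point_pattern
#' @param pattern A `point_pattern`.
#' @param delta Threshold radius in `[0, 1]` (units of the maximum pairwise
#'   distance); pairs with normalized distance `<= delta` are connected.
#' @return `build_threshold_network()`: an igraph graph.
#' @export
build_threshold_network <- function(pattern, delta) {
  pattern <- point_pattern(pattern)
  stopifnot(delta >= 0, delta <= 1)
  adj <- pattern$ndist <= delta
  diag(adj) <- FALSE
  as_tessellation(adj * 1)
}

#' Multi-threshold automaton descriptor of a point pattern
#'
#' Builds the proximity network at each threshold of an ascending sweep,
#' evolves the automaton on it, and concatenates the per-threshold
#' descriptors in sweep order. The default descriptor per threshold is the
#' three average measurements `[muS, muW, muL]`, giving a `3 * D` vector
#' for `D` thresholds; histogram variants give `20 * D` (or `60 * D`)
#' vectors. The default sweep runs from 0.25 to 1 in steps of 0.0625
#' (13 thresholds).
#'
#' @inheritParams build_threshold_network
#' @param rule Life-like rule.
#' @param t,sigma Automaton parameters.
#' @param deltas Ascending threshold sweep.
#' @param feature Descriptor per threshold: `"averages"` (default), `"hS"`,
#'   `"hW"`, `"hL"` or `"combined"`.
#' @param seed Integer seed (one evolution seed per threshold, derived).
#' @return A named numeric vector (names carry the threshold index).
#' @export
threshold_sweep_descriptor <- function(pattern, rule, t = 350, sigma = 0.5,
                                       deltas = seq(0.25, 1, by = 0.0625),
                                       feature = "averages", seed = 1) {
  pattern <- point_pattern(pattern)
  stopifnot(length(deltas) >= 1, !is.unsorted(deltas))
  cols <- feature_columns(feature)
  parts <- lapply(seq_along(deltas), function(i) {
    net <- build_threshold_network(pattern, deltas[i])
    d <- llna_evolve(net, rule, t = t, sigma = sigma,
                     seed = (seed + 7919 * i) %% 2147483629)
    f <- assemble_features(measure_diagram(d))
    v <- unlist(f[cols])
    names(v) <- sprintf("d%02d_%s", i, cols)
    v
  })
  unlist(parts)
}

#' Synthetic point patterns
#'
#' Test patterns standing in for segmented-image centroids: `"uniform"`
#' (homogeneous binomial process on the unit square), `"clustered"`
#' (parent-offspring process: Gaussian clusters around uniformly placed
#' parents) and `"regular"` (jittered square grid).
#'
#' @param kind Pattern type.
#' @param n_points Number of points (>= 10).
#' @param seed Integer seed.
#' @param cluster_sd Offspring spread of the clustered process.
#' @param n_parents Parent count of the clustered process.
#' @param jitter_sd Jitter of the regular grid (0 gives the exact lattice).
#' @return A `point_pattern`.
#' @export
synth_point_pattern <- function(kind = c("uniform", "clustered", "regular"),
                                n_points, seed = NULL, cluster_sd = 0.03,
                                n_parents = 5, jitter_sd = 0.01) {
  kind <- match.arg(kind)
  stopifnot(n_points >= 10)
  with_seed(seed, {
    coords <- switch(kind,
      uniform = cbind(stats::runif(n_points), stats::runif(n_points)),
      clustered = {
        px <- stats::runif(n_parents)
        py <- stats::runif(n_parents)
        par <- sample.int(n_parents, n_points, replace = TRUE)
        cbind((px[par] + stats::rnorm(n_points, 0, cluster_sd)) %% 1,
              (py[par] + stats::rnorm(n_points, 0, cluster_sd)) %% 1)
      },
      regular = {
        side <- ceiling(sqrt(n_points))
        gx <- (rep(seq_len(side), side) - 0.5) / side
        gy <- (rep(seq_len(side), each = side) - 0.5) / side
        keep <- seq_len(n_points)
        cbind(gx[keep] + stats::rnorm(n_points, 0, jitter_sd),
              gy[keep] + stats::rnorm(n_points, 0, jitter_sd))
      }
    )
    point_pattern(coords)
  })
}
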