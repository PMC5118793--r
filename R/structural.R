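#' Structural measurements of a network
#'
#' The comparison baseline used alongside the automaton descriptors:
#' mean degree `k`, average hierarchical degrees of levels 1 and 2 (mean
#' number of nodes at shortest-path distance exactly 1 and 2; level 1
#' equals the ordinary mean degree), average local clustering coefficient
#' `cc`, average shortest path length `l` (over reachable pairs on
#' disconnected graphs) and the degree Pearson correlation `rho_P`
#' (assortativity over edges).
#'
#' The hierarchical degree of level d is implemented as the ring size at
#' distance d; an alternative convention counting edges between consecutive
#' rings is available via `hier_convention = "edges"`.
#'
#' @param net A tessellation.
#' @param hier_convention `"ring"` (nodes at distance exactly d, default)
#'   or `"edges"` (edges between ring d-1 and ring d).
#' @return A one-row tibble with columns `mean_degree`, `hier_degree_1`,
#'   `hier_degree_2`, `clustering`, `path_length`, `assortativity`.
#' @examples
#' structural_measures(igraph::make_full_graph(5))
#' @export
structural_measures <- function(net, hier_convention = c("ring", "edges")) {
  net <- as_tessellation(net)
  hier_convention <- match.arg(hier_convention)
  N <- igraph::vcount(net)
  stopifnot(N > 0)
  deg <- igraph::degree(net)
  ring1 <- mean(igraph::ego_size(net, order = 1, mindist = 1))
  if (hier_convention == "ring") {
    ring2 <- mean(igraph::ego_size(net, order = 2, mindist = 2))
  } else {
    ring2 <- mean(vapply(seq_len(N), function(v) {
      d <- igraph::distances(net, v = v)[1, ]
      r1 <- which(d == 1)
      r2 <- which(d == 2)
      if (length(r2) == 0) return(0)
      sub <- igraph::as_adjacency_matrix(net, sparse = TRUE)[r1, r2,
                                                             drop = FALSE]
      sum(sub)
    }, numeric(1)))
  }
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  rho <- suppressWarnings(igraph::assortativity_degree(net))
  if (!is.finite(rho)) rho <- 0  # degree-regular graphs have no spread
  tibble::tibble(
    mean_degree = mean(deg),
    hier_degree_1 = ring1,
    hier_degree_2 = ring2,
    clustering = mean(cc),
    path_length = igraph::mean_distance(net, unconnected = TRUE),
    assortativity = rho
  )
}

#' Structural baseline feature matrix
#'
#' One row of structural measures per network of a dataset, aligned with
#' the dataset manifest.
#'
#' @param dataset A tibble from [build_dataset()] (needs the `graph`
#'   list-column), or a plain list of graphs.
#' @param include_mean_degree Keep the `mean_degree` column (dropped for
#'   tasks whose classes are defined partly by mean degree).
#' @return A tibble of structural features, with the manifest columns
#'   (`model`, `N`, `mean_degree` target, `replicate`) prefixed `spec_`
#'   when a manifest is available.
#' @export
structural_feature_matrix <- function(dataset, include_mean_degree = TRUE) {
  graphs <- if (is.data.frame(dataset)) dataset$graph else dataset
  rows <- dplyr::bind_rows(lapply(graphs, structural_measures))
  if (!include_mean_degree) rows$mean_degree <- NULL
  if (is.data.frame(dataset)) {
    meta <- dataset[intersect(c("model", "N", "mean_degree", "replicate"),
                              names(dataset))]
    names(meta) <- paste0("spec_", names(meta))
    rows <- dplyr::bind_cols(meta, rows)
  }
  rows
}
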