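#' Read and write networks
#'
#' Edge lists are whitespace-delimited text, one `i j` pair per line with
#' 0-based node ids and `#` comments; GraphML goes through igraph. Directed
#' or weighted inputs are symmetrized/binarized with a warning; self-loops
#' and duplicate edges are dropped with a warning.
#'
#' @param path File path.
#' @param format `"edge_list"` or `"graphml"`; guessed from the extension
#'   (`.graphml` vs anything else) when missing.
#' @param n_nodes Optional node count override for edge lists (covers
#'   trailing isolated nodes).
#' @return An undirected simple igraph graph.
#' @export
read_network <- function(path, format = NULL, n_nodes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format %||% if (grepl("\\.graphml$", path, ignore.case = TRUE))
    "graphml" else "edge_list"
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) {
      warning("directed GraphML input symmetrized")
      g <- igraph::as_undirected(g, mode = "collapse")
    }
    return(check_simplified(igraph::simplify(g), g, path))
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  keep <- nzchar(lines)
  if (!any(keep)) stop("empty graph in ", path, call. = FALSE)
  parts <- strsplit(lines[keep], "[[:space:]]+")
  bad <- which(lengths(parts) < 2 |
                 vapply(parts, function(p) anyNA(suppressWarnings(
                   as.integer(p[1:2]))), logical(1)))
  if (length(bad)) {
    stop("cannot parse edge list ", path, " at line ",
         which(keep)[bad[1]], ": '", lines[keep][bad[1]], "'", call. = FALSE)
  }
  edges <- do.call(rbind, lapply(parts, function(p) as.integer(p[1:2])))
  g_raw <- igraph::add_edges(
    igraph::make_empty_graph(max(max(edges) + 1L, n_nodes %||% 0L),
                             directed = FALSE),
    t(edges) + 1L)
  check_simplified(igraph::simplify(g_raw), g_raw, path)
}

check_simplified <- function(g, g_raw, path) {
  dropped <- igraph::ecount(g_raw) - igraph::ecount(g)
  if (dropped > 0) {
    warning(dropped, " self-loop/duplicate edge(s) dropped reading ", path)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_network
#' @param net Graph to write.
#' @export
write_network <- function(net, path, format = NULL) {
  net <- as_tessellation(net)
  format <- format %||% if (grepl("\\.graphml$", path, ignore.case = TRUE))
    "graphml" else "edge_list"
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net, names = FALSE) - 1L
    writeLines(paste(el[, 1], el[, 2]), path)
  }
  invisible(path)
}

#' Export a space-time diagram as a portable graymap
#'
#' Plain PGM (P2), white = alive, black = dead; rows are time steps.
#' Columns can be pre-ordered by degree with [order_by_degree()].
#'
#' @param diagram An `llna_diagram`.
#' @param path Output path.
#' @export
write_diagram_pgm <- function(diagram, path) {
  m <- unclass(diagram)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "1"), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-node measures and feature tables
#'
#' `write_measures()` writes one CSV row per node (entropy, lz) plus a
#' word-length count table alongside; `write_features()` writes a feature
#' matrix with its manifest columns.
#'
#' @param measures An `llna_measures`.
#' @param path CSV path (the word table goes to `<path>_words.csv`).
#' @export
write_measures <- function(measures, path) {
  utils::write.csv(measures$nodes, path, row.names = FALSE)
  words <- as.data.frame(table(length = measures$word_lengths),
                         stringsAsFactors = FALSE)
  utils::write.csv(words, sub("\\.csv$", "_words.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_measures
#' @param features A feature tibble from [feature_matrix()] or
#'   [dataset_features()].
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Write an experiment result record
#'
#' JSON record with the run settings, a hash of the configuration, the
#' per-repetition accuracies and the pooled confusion matrix; identical
#' configurations produce identical records.
#'
#' @param result An `llna_cv`.
#' @param path Output JSON path.
#' @param config Optional named list of run settings stored (and hashed)
#'   with the record.
#' @export
write_results <- function(result, path, config = list()) {
  stopifnot(inherits(result, "llna_cv"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite needed to write results", call. = FALSE)
  }
  rec <- list(
    config = config,
    config_hash = config_hash(config),
    classifier = result$classifier,
    folds = result$folds,
    repetitions = result$repetitions,
    mean_accuracy = result$mean_accuracy,
    sd_accuracy = result$sd_accuracy,
    accuracies = result$accuracies,
    confusion = as.data.frame.matrix(result$confusion)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  # polynomial rolling hash over the serialized config; stable across sessions
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 67108859
  sprintf("%08x", as.integer(h))
}
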