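#' Entropy histogram descriptor
#'
#' Relative frequencies of per-node entropies over 20 equal-width bins of
#' `[0, 1]`; the last bin is closed at 1. Frequencies sum to 1 when any
#' observation exists.
#'
#' @param values Per-node entropies in `[0, 1]`.
#' @param bins Number of bins (20 in the reference descriptor).
#' @return Numeric vector of `bins` relative frequencies.
#' @export
entropy_histogram <- function(values, bins = 20L) {
  if (any(values < 0 | values > 1)) {
    stop("entropy values must lie in [0, 1]", call. = FALSE)
  }
  unit_histogram(values, bins, upper = 1)
}

unit_histogram <- function(values, bins, upper) {
  idx <- pmin(floor(values / upper * bins), bins - 1L)
  counts <- tabulate(idx + 1L, nbins = bins)
  if (sum(counts) == 0) return(numeric(bins))
  counts / sum(counts)
}

#' Word-length histogram descriptor
#'
#' Word lengths binned as {1-2}, {3-4}, ..., {39-40} (20 bins of width 2).
#' Words longer than 40 are rare at the reference evolution length and are
#' discarded before normalization; frequencies sum to 1 over retained words.
#'
#' @param word_lengths Positive integer run lengths.
#' @param max_length Longest retained word (40).
#' @return Numeric vector of `max_length / 2` relative frequencies.
#' @export
word_histogram <- function(word_lengths, max_length = 40L) {
  stopifnot(max_length %% 2 == 0, all(word_lengths >= 1))
  bins <- max_length %/% 2L
  kept <- word_lengths[word_lengths <= max_length]
  counts <- tabulate((as.integer(kept) + 1L) %/% 2L, nbins = bins)
  if (sum(counts) == 0) return(numeric(bins))
  counts / sum(counts)
}

#' Lempel-Ziv histogram descriptor
#'
#' Per-node normalized LZ complexities histogrammed into 20 equal-width bins
#' over `[0, group_max]`, where `group_max` is the maximum complexity
#' observed over the group of samples being described (computed once per
#' dataset and reused, so all samples share one bin grid). Values above
#' `group_max` - possible when the grid was fixed on a different split -
#' are clipped into the last bin.
#'
#' @param values Per-node LZ complexities (>= 0).
#' @param group_max Positive upper edge of the bin grid.
#' @param bins Number of bins.
#' @return Numeric vector of `bins` relative frequencies.
#' @export
lz_histogram <- function(values, group_max, bins = 20L) {
  if (!is.numeric(group_max) || length(group_max) != 1 || group_max <= 0) {
    stop("group_max must be a positive scalar", call. = FALSE)
  }
  unit_histogram(pmin(values, group_max), bins, upper = group_max)
}

#' Assemble the feature vector of one diagram
#'
#' Builds the three 20-bin histogram descriptors (entropy `hS`, word length
#' `hW`, Lempel-Ziv `hL`), their 60-value concatenation, and the three
#' average measurements `muS` (mean node entropy), `muW` (mean word length)
#' and `muL` (mean node LZ complexity).
#'
#' @param measures An `llna_measures` object from [measure_diagram()].
#' @param group_max Upper edge for the LZ histogram grid; defaults to the
#'   sample's own maximum (pass the dataset-level maximum when building a
#'   feature matrix so samples are comparable).
#' @return A one-row tibble with columns `hS_00..hS_19`, `hW_00..hW_19`,
#'   `hL_00..hL_19`, `muS`, `muW`, `muL`.
#' @export
assemble_features <- function(measures, group_max = NULL) {
  stopifnot(inherits(measures, "llna_measures"))
  if (is.null(group_max)) group_max <- max(measures$nodes$lz, 1e-12)
  hS <- entropy_histogram(measures$nodes$entropy)
  hW <- word_histogram(measures$word_lengths)
  hL <- lz_histogram(measures$nodes$lz, group_max)
  vec <- c(hS, hW, hL)
  names(vec) <- c(sprintf("hS_%02d", 0:19), sprintf("hW_%02d", 0:19),
                  sprintf("hL_%02d", 0:19))
  out <- tibble::as_tibble(as.list(vec))
  out$muS <- mean(measures$nodes$entropy)
  out$muW <- if (length(measures$word_lengths)) mean(measures$word_lengths) else 0
  out$muL <- mean(measures$nodes$lz)
  out
}

#' Feature matrix for a collection of diagrams or measure sets
#'
#' Measures each diagram (if needed), fixes the LZ histogram grid at the
#' group maximum over all samples, and stacks one feature row per sample.
#'
#' @param x A list of `llna_diagram` or `llna_measures` objects.
#' @param labels Optional class labels (recycled checks apply) added as a
#'   `label` column.
#' @param group_max Optional externally fixed LZ grid upper edge (e.g. from
#'   a training split).
#' @param include_initial Passed to [measure_diagram()] for diagram input.
#' @return A tibble with 63 feature columns (and `label` if given).
#' @export
feature_matrix <- function(x, labels = NULL, group_max = NULL,
                           include_initial = TRUE) {
  measures <- lapply(x, function(el) {
    if (inherits(el, "llna_measures")) el
    else measure_diagram(el, include_initial = include_initial)
  })
  if (is.null(group_max)) {
    group_max <- max(vapply(measures, function(m) max(m$nodes$lz), numeric(1)),
                     1e-12)
  }
  rows <- lapply(measures, assemble_features, group_max = group_max)
  out <- dplyr::bind_rows(rows)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(out))
    out$label <- labels
  }
  attr(out, "group_max") <- group_max
  out
}

#' Column names of a descriptor variant
#'
#' Helper for selecting descriptor columns out of a feature matrix:
#' `"hS"`, `"hW"`, `"hL"` (20 columns each), `"combined"` (their 60-column
#' concatenation) or `"averages"` (`muS`, `muW`, `muL`).
#'
#' @param variant Descriptor variant name.
#' @return Character vector of column names.
#' @export
feature_columns <- function(variant = c("combined", "hS", "hW", "hL",
                                        "averages")) {
  variant <- match.arg(variant)
  switch(variant,
    hS = sprintf("hS_%02d", 0:19),
    hW = sprintf("hW_%02d", 0:19),
    hL = sprintf("hL_%02d", 0:19),
    combined = c(sprintf("hS_%02d", 0:19), sprintf("hW_%02d", 0:19),
                 sprintf("hL_%02d", 0:19)),
    averages = c("muS", "muW", "muL")
  )
}
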