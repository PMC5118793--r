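#' Shannon entropy of a binary series
#'
#' `H = -p0 log2 p0 - p1 log2 p1` with `0 log2 0 = 0`, where `p0`/`p1` are
#' the fractions of zeros and ones in the series. Bounded in `[0, 1]` bits.
#'
#' @param series Binary 0/1 vector (non-empty).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0, 1, 0, 1))
#' shannon_entropy(rep(0, 10))
#' @export
shannon_entropy <- function(series) {
  if (length(series) == 0) stop("empty series", call. = FALSE)
  stopifnot(all(series %in% 0:1))
  p1 <- mean(series)
  binary_entropy(p1)
}

binary_entropy <- function(p1) {
  p0 <- 1 - p1
  h <- numeric(length(p1))
  nz1 <- p1 > 0
  nz0 <- p0 > 0
  h[nz1] <- h[nz1] - p1[nz1] * log2(p1[nz1])
  h[nz0] <- h[nz0] - p0[nz0] * log2(p0[nz0])
  h
}

#' Word lengths of a binary series
#'
#' A word is a maximal run of ones: in `0011101100` there is one word of
#' length three and one of length two. Runs touching either end of the
#' series count as words, so the word lengths always sum to the number of
#' ones.
#'
#' @param series Binary 0/1 vector.
#' @return Integer vector of run lengths (possibly empty).
#' @examples
#' extract_words(c(0, 0, 1, 1, 1, 0, 1, 1, 0, 0))
#' @export
extract_words <- function(series) {
  stopifnot(all(series %in% 0:1))
  if (length(series) == 0) return(integer(0))
  r <- rle(as.integer(series))
  r$lengths[r$values == 1L]
}

#' Lempel-Ziv block decomposition
#'
#' Incremental-dictionary parsing: scanning left to right, each block is the
#' shortest prefix of the remaining sequence not already in the dictionary
#' (every new block extends a known block by one symbol). A trailing
#' remainder that matches an existing block is not counted. The 20-symbol
#' alternating sequence decomposes as `0|1|01|010|10|101|0101`, g = 7.
#'
#' @param series Binary 0/1 vector (non-empty).
#' @return A list with `blocks` (character vector) and `g` (block count).
#' @examples
#' lempel_ziv_blocks(rep(c(0, 1), 10))
#' @export
lempel_ziv_blocks <- function(series) {
  if (length(series) == 0) stop("empty series", call. = FALSE)
  stopifnot(all(series %in% 0:1))
  sym <- as.character(as.integer(series))
  dict <- character(0)
  blocks <- character(0)
  block <- ""
  for (s in sym) {
    block <- paste0(block, s)
    if (!(block %in% dict)) {
      dict <- c(dict, block)
      blocks <- c(blocks, block)
      block <- ""
    }
  }
  list(blocks = blocks, g = length(blocks))
}

#' Normalized Lempel-Ziv complexity
#'
#' The block count `g` normalized by the asymptotic rate of a random binary
#' sequence: `g / (l / log2 l)` for a series of length `l`. A random series
#' scores near 1, a constant one near 0 as `l` grows. The raw block count is
#' available from [lempel_ziv_blocks()] if another normalization is wanted.
#'
#' @param series Binary 0/1 vector of length >= 2.
#' @return Normalized complexity (>= 0).
#' @examples
#' lempel_ziv_complexity(rep(c(0, 1), 10)) # 7 / (20 / log2(20))
#' @export
lempel_ziv_complexity <- function(series) {
  l <- length(series)
  if (l < 2) stop("series must have length >= 2", call. = FALSE)
  stopifnot(all(series %in% 0:1))
  g <- lz_block_count(as.integer(series))
  g / (l / log2(l))
}

#' Measure a space-time diagram
#'
#' Per-node Shannon entropy and normalized Lempel-Ziv complexity of each
#' column's time series, plus the pooled word lengths over all columns (the
#' global word-length measurement of the diagram).
#'
#' @param diagram An `llna_diagram` (or any binary matrix, rows = time).
#' @param include_initial Keep the initial-configuration row in every node's
#'   series (default `TRUE`); set `FALSE` to measure only evolved rows.
#' @return An `llna_measures` object: a list with `nodes` (tibble of
#'   `node`, `entropy`, `lz`) and `word_lengths` (integer vector).
#' @examples
#' g <- igraph::sample_gnp(30, 0.2, directed = FALSE)
#' m <- measure_diagram(llna_evolve(g, "B3/S23", t = 30, seed = 1))
#' m$nodes
#' @export
measure_diagram <- function(diagram, include_initial = TRUE) {
  m <- unclass(diagram)
  stopifnot(is.matrix(m), all(m %in% 0:1))
  if (!include_initial && nrow(m) > 1) m <- m[-1, , drop = FALSE]
  storage.mode(m) <- "integer"
  n <- ncol(m)
  l <- nrow(m)
  p1 <- colMeans(m)
  lz <- lz_block_count_columns(m) / (l / log2(l))
  words <- unlist(lapply(seq_len(n), function(j) extract_words(m[, j])),
                  use.names = FALSE)
  structure(
    list(
      nodes = tibble::tibble(node = seq_len(n),
                             entropy = binary_entropy(p1),
                             lz = lz),
      word_lengths = as.integer(words)
    ),
    class = "llna_measures", series_length = l
  )
}

#' @export
print.llna_measures <- function(x, ...) {
  cat("<llna_measures> ", nrow(x$nodes), " nodes, ",
      length(x$word_lengths), " words pooled (series length ",
      attr(x, "series_length"), ")\n", sep = "")
  print(x$nodes, n = 5)
  invisible(x)
}
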