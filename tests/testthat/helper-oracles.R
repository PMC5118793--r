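# Independent reference implementations used as oracles.

# Classic Game-of-Life-style step on a toroidal matrix for an arbitrary
# B/S digit rule, via shifted copies (no shared code with the package).
gol_step <- function(m, birth = 3, survive = c(2, 3)) {
  shift <- function(m, di, dj) {
    m[(seq_len(nrow(m)) - 1 + di) %% nrow(m) + 1,
      (seq_len(ncol(m)) - 1 + dj) %% ncol(m) + 1]
  }
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  cnt <- Reduce(`+`, lapply(offs, function(d) shift(m, d[1], d[2])))
  ifelse(m == 1, as.integer(cnt %in% survive), as.integer(cnt %in% birth))
}

# Toroidal grid with Moore (8-cell) neighbourhood as an igraph graph;
# node (i, j) -> index (i-1)*nc + j (row-major).
moore_torus <- function(nr, nc = nr) {
  idx <- function(i, j) ((i - 1) %% nr) * nc + ((j - 1) %% nc) + 1
  edges <- integer(0)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
        edges <- c(edges, idx(i, j), idx(i + d[1], j + d[2]))
      }
    }
  }
  igraph::simplify(igraph::add_edges(
    igraph::make_empty_graph(nr * nc, directed = FALSE), edges))
}

# Naive per-node density + rule application straight from the definitions.
naive_step <- function(net, states, rule) {
  r <- llna_rule(rule)
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  n <- length(states)
  out <- integer(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    rho <- if (k == 0) 0 else sum(A[i, ] * states) / k
    digs <- if (states[i] == 1) r$survival else r$birth
    hit <- FALSE
    for (x in digs) {
      lo <- x / 9
      hi <- (x + 1) / 9
      if (x == 8) { if (rho >= lo && rho <= 1) hit <- TRUE }
      else if (rho >= lo && rho < hi) hit <- TRUE
    }
    out[i] <- as.integer(hit)
  }
  out
}

# Quadratic-time LZ parser kept deliberately simple.
naive_lz_count <- function(series) {
  s <- paste(series, collapse = "")
  dict <- character(0)
  g <- 0
  start <- 1
  len <- 1
  while (start + len - 1 <= nchar(s)) {
    block <- substr(s, start, start + len - 1)
    if (block %in% dict) {
      len <- len + 1
    } else {
      dict <- c(dict, block)
      g <- g + 1
      start <- start + len
      len <- 1
    }
  }
  g
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  igraph::sample_gnp(n, p, directed = FALSE)
}
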