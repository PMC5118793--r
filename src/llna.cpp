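#include <Rcpp.h>
#include <string>
#include <unordered_set>
using namespace Rcpp;

// Density interval of a node with `alive` living neighbours out of `k`.
// Integer arithmetic keeps the nine width-1/9 intervals exact for any
// rational density alive/k: interval = floor(9*alive/k), capped at 8 so the
// closed last interval [8/9, 1] absorbs density 1. Isolated nodes (k = 0)
// take density 0, hence interval 0.
static inline int density_interval(int alive, int k) {
  if (k <= 0) return 0;
  int idx = (9 * alive) / k;
  return idx > 8 ? 8 : idx;
}

// Synchronous evolution of a Life-like rule on a network given in CSR form
// (adj_ptr has N+1 entries, adj_idx the 0-based neighbour lists). Returns a
// (t+1) x N binary matrix whose row 0 is the initial state.
// [[Rcpp::export]]
IntegerMatrix evolve_kernel(IntegerVector adj_ptr, IntegerVector adj_idx,
                            IntegerVector init, int t,
                            LogicalVector birth, LogicalVector survival) {
  const int n = init.size();
  if (adj_ptr.size() != n + 1) stop("adjacency pointer length mismatch");
  if (birth.size() != 9 || survival.size() != 9) stop("rule tables must have 9 entries");
  IntegerMatrix diagram(t + 1, n);
  std::vector<int> cur(init.begin(), init.end()), nxt(n);
  for (int i = 0; i < n; ++i) diagram(0, i) = cur[i];
  for (int step = 1; step <= t; ++step) {
    for (int i = 0; i < n; ++i) {
      const int lo = adj_ptr[i], hi = adj_ptr[i + 1];
      int alive = 0;
      for (int e = lo; e < hi; ++e) alive += cur[adj_idx[e]];
      const int iv = density_interval(alive, hi - lo);
      nxt[i] = cur[i] ? (survival[iv] ? 1 : 0) : (birth[iv] ? 1 : 0);
    }
    std::swap(cur, nxt);
    for (int i = 0; i < n; ++i) diagram(step, i) = cur[i];
  }
  return diagram;
}

// Lempel-Ziv incremental-dictionary block count of a binary sequence: scan
// left to right, each block is the shortest prefix of the remainder not yet
// in the dictionary. A trailing remainder that matches an existing block is
// not counted.
// [[Rcpp::export]]
int lz_block_count(IntegerVector series) {
  const int n = series.size();
  if (n == 0) stop("empty series");
  std::unordered_set<std::string> dict;
  std::string block;
  int g = 0;
  for (int i = 0; i < n; ++i) {
    block.push_back(series[i] ? '1' : '0');
    if (dict.find(block) == dict.end()) {
      dict.insert(block);
      ++g;
      block.clear();
    }
  }
  return g;  // unfinished trailing block (already in dict) is not counted
}

// Per-column LZ block counts of a space-time diagram.
// [[Rcpp::export]]
IntegerVector lz_block_count_columns(IntegerMatrix diagram) {
  const int n = diagram.ncol(), l = diagram.nrow();
  IntegerVector out(n);
  std::string block;
  for (int j = 0; j < n; ++j) {
    std::unordered_set<std::string> dict;
    block.clear();
    int g = 0;
    for (int i = 0; i < l; ++i) {
      block.push_back(diagram(i, j) ? '1' : '0');
      if (dict.find(block) == dict.end()) {
        dict.insert(block);
        ++g;
        block.clear();
      }
    }
    out[j] = g;
  }
  return out;
}
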