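#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All-pairs shortest paths on a dense symmetric length matrix by repeated
// Dijkstra. len(u,v) >= 0 is the edge length, +Inf where no edge exists.
// The O(n^2)-per-source node selection is deliberate: connectome
// parcellations are small (n up to a few hundred) and moderately dense, so
// a heap buys nothing. Symmetry lets the relax step read the contiguous
// column of the current node; Inf edges relax to Inf and never win a
// comparison, so no finiteness test is needed in the hot loop.
// [[Rcpp::export]]
NumericMatrix cpp_apsp(NumericMatrix len) {
  const int n = len.nrow();
  NumericMatrix D(n, n);
  const double *L = len.begin();
  double *out = D.begin();
  std::vector<double> dist(n);
  std::vector<char> done(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(done.begin(), done.end(), 0);
    dist[s] = 0.0;
    for (int it = 0; it < n; ++it) {
      int u = -1;
      double du = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < du) { du = dist[v]; u = v; }
      if (u < 0) break;  // remaining nodes unreachable
      done[u] = 1;
      const double *lu = L + static_cast<size_t>(u) * n;  // column u == row u
      for (int v = 0; v < n; ++v) {
        const double nd = du + lu[v];
        if (nd < dist[v]) dist[v] = nd;
      }
    }
    double *col = out + static_cast<size_t>(s) * n;
    std::copy(dist.begin(), dist.end(), col);
  }
  return D;
}
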