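#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Multi-source Dijkstra on the 8-connected grid graph of a cost raster.
//
// Edge weight between neighbouring cells a, b is L * (cost_a + cost_b) / 2
// with L = 1 for orthogonal and sqrt(2) for diagonal moves (distance-
// weighted "geometric" accumulation, step lengths in cell units).
// Infinite cell costs mark impassable cells: no edge touches them.
//
// cost:    nr x nc matrix, non-negative, Inf = impassable
// sources: 1-based column-major cell indices, all passable
// returns: nr x nc matrix of minimal accumulated costs (Inf = unreachable)
// [[Rcpp::export(name = ".gridDijkstra")]]
NumericMatrix grid_dijkstra(NumericMatrix cost, IntegerVector sources) {
  const int nr = cost.nrow(), nc = cost.ncol();
  const double inf = std::numeric_limits<double>::infinity();
  const double SQRT2 = std::sqrt(2.0);
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), inf);

  typedef std::pair<double, int> QE;  // (distance, cell index 0-based)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k] - 1;
    if (s < 0 || s >= nr * nc) stop("source index out of range");
    if (!R_finite(cost[s])) stop("source cell is impassable");
    if (dist[s] > 0.0) {
      dist[s] = 0.0;
      pq.push(QE(0.0, s));
    }
  }
  if (pq.empty()) stop("no passable source cells");

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    const double d = top.first;
    const int u = top.second;
    if (d > dist[u]) continue;  // stale entry
    const int ur = u % nr, uc = u / nr;
    const double cu = cost[u];
    for (int k = 0; k < 8; ++k) {
      const int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      const int v = vc * nr + vr;
      const double cv = cost[v];
      if (!R_finite(cv)) continue;
      const double L = (dr[k] != 0 && dc[k] != 0) ? SQRT2 : 1.0;
      const double nd = d + L * (cu + cv) / 2.0;
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(QE(nd, v));
      }
    }
  }
  return dist;
}
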