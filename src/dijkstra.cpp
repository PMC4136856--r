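#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8-neighbour Dijkstra over a raster cost surface.
//
// Edge weight between adjacent cells a and b is mean(cost_a, cost_b) * d,
// with d = cell_size for orthogonal and sqrt(2) * cell_size for diagonal
// steps (the usual GIS cost-distance semantics). NA cells are impassable.
//
// Backlink codes record the compass direction of each cell's optimal
// predecessor: 0 = source, 1..8 = N, NE, E, SE, S, SW, W, NW. Neighbours
// are visited in that fixed order so tie-breaking is deterministic.
// [[Rcpp::export(name = ".dijkstra_grid")]]
List dijkstra_grid(NumericMatrix cost, double cell_size,
                   IntegerVector src_rows, IntegerVector src_cols) {
  const int nr = cost.nrow(), nc = cost.ncol();
  const int n = nr * nc;
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const double sqrt2 = std::sqrt(2.0);

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> back(n, NA_INTEGER);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int k = 0; k < src_rows.size(); ++k) {
    int r = src_rows[k] - 1, c = src_cols[k] - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source cell out of range");
    if (NumericMatrix::is_na(cost(r, c)))
      stop("source cell is impassable (nodata)");
    int id = r + c * nr;
    dist[id] = 0.0;
    back[id] = 0;
    pq.push(Node(0.0, id));
  }

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist[u]) continue;  // stale entry
    int ur = u % nr, uc = u / nr;
    double cu = cost(ur, uc);
    for (int k = 0; k < 8; ++k) {
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      double cv = cost(vr, vc);
      if (NumericMatrix::is_na(cv)) continue;
      double step = (k % 2 == 1) ? sqrt2 * cell_size : cell_size;
      double w = 0.5 * (cu + cv) * step;
      int v = vr + vc * nr;
      if (dist[u] + w < dist[v]) {
        dist[v] = dist[u] + w;
        // predecessor direction seen from v is the opposite compass step
        back[v] = ((k + 4) % 8) + 1;
        pq.push(Node(dist[v], v));
      }
    }
  }

  NumericMatrix acc(nr, nc);
  IntegerMatrix bl(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int id = r + c * nr;
      if (NumericMatrix::is_na(cost(r, c)) || !R_finite(dist[id])) {
        acc(r, c) = NA_REAL;
        bl(r, c) = NA_INTEGER;
      } else {
        acc(r, c) = dist[id];
        bl(r, c) = back[id];
      }
    }
  }
  return List::create(_["accumulation"] = acc, _["backlink"] = bl);
}
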