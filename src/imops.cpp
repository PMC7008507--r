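#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Connected-component labelling on a logical matrix.
// connectivity: 4 or 8. Labels are 1..k in scan order of first encounter.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int rr = cr + dr8[k], cctmp = cc + dc8[k];
          if (rr < 0 || rr >= nr || cctmp < 0 || cctmp >= nc) continue;
          if (mask(rr, cctmp) && lab(rr, cctmp) == 0) {
            lab(rr, cctmp) = next;
            stack.push_back(rr + cctmp * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Chamfer 3-4 distance transform: for each TRUE pixel, approximate Euclidean
// distance (in pixels) to the nearest FALSE pixel. FALSE pixels get 0.
// Border is treated as background-free (distance can grow past the edge).
// [[Rcpp::export(name = ".cpp_chamfer_dist")]]
NumericMatrix cpp_chamfer_dist(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  double big = 3.0 * (nr + nc) + 10.0;
  NumericMatrix d(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      d(r, c) = fg(r, c) ? big : 0.0;
  // forward pass
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = d(r, c);
      if (r > 0 && d(r - 1, c) + 3 < v) v = d(r - 1, c) + 3;
      if (c > 0 && d(r, c - 1) + 3 < v) v = d(r, c - 1) + 3;
      if (r > 0 && c > 0 && d(r - 1, c - 1) + 4 < v) v = d(r - 1, c - 1) + 4;
      if (r < nr - 1 && c > 0 && d(r + 1, c - 1) + 4 < v) v = d(r + 1, c - 1) + 4;
      d(r, c) = v;
    }
  }
  // backward pass
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = d(r, c);
      if (r < nr - 1 && d(r + 1, c) + 3 < v) v = d(r + 1, c) + 3;
      if (c < nc - 1 && d(r, c + 1) + 3 < v) v = d(r, c + 1) + 3;
      if (r < nr - 1 && c < nc - 1 && d(r + 1, c + 1) + 4 < v) v = d(r + 1, c + 1) + 4;
      if (r > 0 && c < nc - 1 && d(r - 1, c + 1) + 4 < v) v = d(r - 1, c + 1) + 4;
      d(r, c) = v;
    }
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      d(r, c) /= 3.0;
  return d;
}

struct WsNode {
  double elev;
  long order;
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.elev != b.elev) return a.elev > b.elev; // min-heap on elevation
    return a.order > b.order;                     // FIFO tie-break => deterministic
  }
};

// Seeded watershed by priority flooding: grow seed labels over `mask`
// in increasing order of `elev`. Unseeded mask pixels unreachable from a
// seed stay 0.
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerMatrix cpp_watershed(NumericMatrix elev, IntegerMatrix seeds,
                            LogicalMatrix mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long ord = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      lab(r, c) = seeds(r, c);
      if (seeds(r, c) > 0 && mask(r, c))
        pq.push({elev(r, c), ord++, r + c * nr});
    }
  }
  int dr[4] = {-1, 1, 0, 0};
  int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int cr = nd.idx % nr, cc = nd.idx / nr;
    int l = lab(cr, cc);
    for (int k = 0; k < 4; ++k) {
      int rr = cr + dr[k], ccn = cc + dc[k];
      if (rr < 0 || rr >= nr || ccn < 0 || ccn >= nc) continue;
      if (!mask(rr, ccn) || lab(rr, ccn) != 0) continue;
      lab(rr, ccn) = l;
      pq.push({elev(rr, ccn), ord++, rr + ccn * nr});
    }
  }
  return lab;
}
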