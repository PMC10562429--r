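#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Matrices are base-R numeric/integer matrices, column-major, [row, col].
// Linear indices below are 0-based; neighbourhood is 8-connected throughout.

static inline void neighbours8(int idx, int nr, int nc, int* out, int& n) {
  int r = idx % nr, c = idx / nr;
  n = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      if (dr == 0 && dc == 0) continue;
      int rr = r + dr, cc = c + dc;
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) out[n++] = rr + cc * nr;
    }
}

// ---- 8-connected component labelling -------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol(), npix = nr * nc;
  IntegerMatrix lab(nr, nc);
  int nb[8], nnb, next = 0;
  std::vector<int> stack;
  for (int i = 0; i < npix; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      neighbours8(p, nr, nc, nb, nnb);
      for (int k = 0; k < nnb; ++k)
        if (mask[nb[k]] && lab[nb[k]] == 0) { lab[nb[k]] = next; stack.push_back(nb[k]); }
    }
  }
  return lab;
}

// ---- seeded watershed (priority flood) -----------------------------------

struct QEntry {
  double intensity;
  long long order;   // insertion counter, FIFO tie-break
  int idx;
  int label;
};
struct QCompare {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.intensity != b.intensity) return a.intensity < b.intensity; // max-heap
    return a.order > b.order;                                          // FIFO
  }
};

// Flood from seed labels in order of decreasing intensity. Only pixels with
// intensity >= th2 are assignable; sub-threshold seed pixels keep their label.
// Ties broken by insertion order, so with a fixed seed map the result is
// deterministic and, for distinct intensities, identical to the repeated
// globally-highest-candidate assignment.
// [[Rcpp::export]]
IntegerMatrix cpp_seeded_watershed(NumericMatrix img, IntegerMatrix seeds, double th2) {
  int nr = img.nrow(), nc = img.ncol(), npix = nr * nc;
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("image and seed map must have identical dimensions");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  long long counter = 0;
  int nb[8], nnb;
  for (int i = 0; i < npix; ++i) lab[i] = seeds[i];
  // push unlabelled assignable neighbours of every seed pixel (raster order)
  for (int i = 0; i < npix; ++i) {
    if (lab[i] == 0) continue;
    neighbours8(i, nr, nc, nb, nnb);
    for (int k = 0; k < nnb; ++k) {
      int q = nb[k];
      if (lab[q] == 0 && img[q] >= th2)
        pq.push(QEntry{img[q], counter++, q, lab[i]});
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    if (lab[e.idx] != 0) continue;
    lab[e.idx] = e.label;
    neighbours8(e.idx, nr, nc, nb, nnb);
    for (int k = 0; k < nnb; ++k) {
      int q = nb[k];
      if (lab[q] == 0 && img[q] >= th2)
        pq.push(QEntry{img[q], counter++, q, e.label});
    }
  }
  return lab;
}

// ---- dynamics of regional maxima (union-find over descending levels) -----

struct DisjointSet {
  std::vector<int> parent;
  DisjointSet(int n) : parent(n, -1) {}
  int find(int x) {
    while (parent[x] >= 0) {
      if (parent[parent[x]] >= 0) parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void link(int child, int root) { parent[child] = root; }
};

// For every regional maximum (plateau) return its plateau pixels, its peak
// value and its dynamics: the minimal intensity drop separating it from a
// higher maximum (Inf for the globally highest). Pixels processed in
// descending intensity, ties by linear index; when components merge, the one
// with the higher peak (earlier creation on equal peaks) survives and the
// others are assigned dynamics = peak - merge level.
// [[Rcpp::export]]
List cpp_dynamics(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol(), npix = nr * nc;
  std::vector<int> ord(npix);
  for (int i = 0; i < npix; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return img[a] > img[b];
  });
  // component id per pixel root via union-find over pixel indices
  DisjointSet ds(npix);
  std::vector<int> comp_of_root(npix, -1);      // pixel root -> component id
  std::vector<double> peak;                     // per component
  std::vector<double> dyn;                      // NA until dead
  std::vector<int> created;                     // creation rank (for ties)
  std::vector<std::vector<int> > plateau;       // plateau pixel indices (1-based out)
  std::vector<char> processed(npix, 0);
  int nb[8], nnb;
  for (int oi = 0; oi < npix; ++oi) {
    int p = ord[oi];
    double v = img[p];
    // distinct processed neighbour components
    int roots[8]; int nroots = 0;
    neighbours8(p, nr, nc, nb, nnb);
    for (int k = 0; k < nnb; ++k) {
      if (!processed[nb[k]]) continue;
      int r = ds.find(nb[k]);
      bool seen = false;
      for (int t = 0; t < nroots; ++t) if (roots[t] == r) { seen = true; break; }
      if (!seen) roots[nroots++] = r;
    }
    if (nroots == 0) {
      int cid = (int)peak.size();
      comp_of_root[p] = cid;
      peak.push_back(v);
      dyn.push_back(NA_REAL);
      created.push_back(cid);
      plateau.push_back(std::vector<int>(1, p + 1));
    } else {
      // survivor: highest peak, earlier creation on ties
      int best = roots[0];
      for (int t = 1; t < nroots; ++t) {
        int a = roots[t];
        int ca = comp_of_root[a], cb = comp_of_root[best];
        if (peak[ca] > peak[cb] || (peak[ca] == peak[cb] && created[ca] < created[cb]))
          best = a;
      }
      int cbest = comp_of_root[best];
      for (int t = 0; t < nroots; ++t) {
        if (roots[t] == best) continue;
        int cdead = comp_of_root[roots[t]];
        dyn[cdead] = peak[cdead] - v;
        ds.link(roots[t], best);
      }
      ds.link(p, best);
      if (img[p] == peak[cbest]) plateau[cbest].push_back(p + 1);
    }
    processed[p] = 1;
  }
  int ncomp = (int)peak.size();
  NumericVector peaks(ncomp), dynamics(ncomp);
  List plats(ncomp);
  for (int c = 0; c < ncomp; ++c) {
    peaks[c] = peak[c];
    dynamics[c] = ISNA(dyn[c]) ? R_PosInf : dyn[c];
    plats[c] = IntegerVector(plateau[c].begin(), plateau[c].end());
  }
  return List::create(_["peak"] = peaks, _["dynamics"] = dynamics,
                      _["plateau"] = plats);
}

// ---- geodesic distance within a mask (Dijkstra, weights 1 / sqrt(2)) -----

// [[Rcpp::export]]
NumericMatrix cpp_geodesic_dist(LogicalMatrix mask, IntegerVector src) {
  int nr = mask.nrow(), nc = mask.ncol(), npix = nr * nc;
  const double SQ2 = std::sqrt(2.0);
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  typedef std::pair<double, int> DP;
  std::priority_queue<DP, std::vector<DP>, std::greater<DP> > pq;
  for (int s = 0; s < src.size(); ++s) {
    int i = src[s] - 1;
    if (i < 0 || i >= npix || !mask[i]) stop("source pixel outside mask");
    dist[i] = 0.0;
    pq.push(DP(0.0, i));
  }
  int nb[8], nnb;
  while (!pq.empty()) {
    DP top = pq.top(); pq.pop();
    if (top.first > dist[top.second]) continue;
    int p = top.second;
    int r = p % nr, c = p / nr;
    neighbours8(p, nr, nc, nb, nnb);
    for (int k = 0; k < nnb; ++k) {
      int q = nb[k];
      if (!mask[q]) continue;
      int qr = q % nr, qc = q / nr;
      double w = (qr != r && qc != c) ? SQ2 : 1.0;
      double nd = top.first + w;
      if (nd < dist[q]) { dist[q] = nd; pq.push(DP(nd, q)); }
    }
  }
  for (int i = 0; i < npix; ++i) if (!mask[i]) dist[i] = NA_REAL;
  return dist;
}

// ---- linear assignment (Jonker-Volgenant with potentials) ----------------

// Minimal-cost perfect assignment on a square cost matrix; forbidden pairs
// carry a large finite cost. Returns 1-based column assigned to each row.
// [[Rcpp::export]]
IntegerVector cpp_lap(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
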