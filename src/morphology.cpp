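// Low-level grid morphology and segmentation primitives.
// Matrices are column-major (R layout); masks are integer 0/1.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int idx(int r, int c, int nr) { return c * nr + r; }

// 8-connected neighbour offsets and step lengths
static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
static const double DL8[8] = {1, 1, 1, 1, M_SQRT2, M_SQRT2, M_SQRT2, M_SQRT2};

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(IntegerMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(idx(r, c, nr));
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int qr = pr + DR8[k], qc = pc + DC8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) != 0 && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(idx(qr, qc, nr));
          }
        }
      }
    }
  }
  return lab;
}

static std::vector<std::pair<int,int> > disk_offsets(double radius) {
  std::vector<std::pair<int,int> > off;
  int ir = (int)std::floor(radius);
  for (int dr = -ir; dr <= ir; ++dr)
    for (int dc = -ir; dc <= ir; ++dc)
      if ((double)dr * dr + (double)dc * dc <= radius * radius + 1e-9)
        off.push_back(std::make_pair(dr, dc));
  return off;
}

// [[Rcpp::export(name = ".dilate_disk")]]
IntegerMatrix dilate_disk(IntegerMatrix mask, double radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<std::pair<int,int> > off = disk_offsets(radius);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) continue;
      for (size_t k = 0; k < off.size(); ++k) {
        int qr = r + off[k].first, qc = c + off[k].second;
        if (qr >= 0 && qr < nr && qc >= 0 && qc < nc) out(qr, qc) = 1;
      }
    }
  return out;
}

// [[Rcpp::export(name = ".erode_disk")]]
IntegerMatrix erode_disk(IntegerMatrix mask, double radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<std::pair<int,int> > off = disk_offsets(radius);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) continue;
      bool keep = true;
      for (size_t k = 0; k < off.size() && keep; ++k) {
        int qr = r + off[k].first, qc = c + off[k].second;
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc || mask(qr, qc) == 0)
          keep = false;
      }
      if (keep) out(r, c) = 1;
    }
  return out;
}

// Fill holes: background components not connected to the image border.
// [[Rcpp::export(name = ".fill_holes")]]
IntegerMatrix fill_holes(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix reach(nr, nc); // background reachable from border (4-conn)
  std::queue<int> q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; c += (nc > 1 ? nc - 1 : 1)) {
      if (mask(r, c) == 0 && reach(r, c) == 0) { reach(r, c) = 1; q.push(idx(r, c, nr)); }
      if (nc == 1) break;
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; r += (nr > 1 ? nr - 1 : 1)) {
      if (mask(r, c) == 0 && reach(r, c) == 0) { reach(r, c) = 1; q.push(idx(r, c, nr)); }
      if (nr == 1) break;
    }
  }
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int pr = p % nr, pc = p / nr;
    for (int k = 0; k < 4; ++k) {
      int qr = pr + DR8[k], qc = pc + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (mask(qr, qc) == 0 && reach(qr, qc) == 0) {
        reach(qr, qc) = 1;
        q.push(idx(qr, qc, nr));
      }
    }
  }
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = (mask(r, c) != 0 || reach(r, c) == 0) ? 1 : 0;
  return out;
}

struct DNode {
  double d; int p; int lab;
  bool operator<(const DNode& o) const { return d > o.d; } // min-heap
};

// Multi-source geodesic label growth (grassfire / Voronoi partition).
// seeds: labelled pixels (>0); growth restricted to constraint!=0 when
// use_constraint, and to geodesic distance <= max_dist. Ties resolve to the
// nearest seed pixel by construction (Dijkstra order).
// [[Rcpp::export(name = ".grow_labels")]]
IntegerMatrix grow_labels(IntegerMatrix seeds, double max_dist,
                          IntegerMatrix constraint, bool use_constraint) {
  int nr = seeds.nrow(), nc = seeds.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<double> dist((size_t)nr * nc, R_PosInf);
  std::priority_queue<DNode> pq;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0) {
        int p = idx(r, c, nr);
        dist[p] = 0.0;
        lab(r, c) = seeds(r, c);
        DNode n; n.d = 0.0; n.p = p; n.lab = seeds(r, c);
        pq.push(n);
      }
  while (!pq.empty()) {
    DNode n = pq.top(); pq.pop();
    int pr = n.p % nr, pc = n.p / nr;
    if (n.d > dist[n.p]) continue;
    for (int k = 0; k < 8; ++k) {
      int qr = pr + DR8[k], qc = pc + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (use_constraint && constraint(qr, qc) == 0) continue;
      double nd = n.d + DL8[k];
      if (nd > max_dist) continue;
      int qp = idx(qr, qc, nr);
      if (nd < dist[qp]) {
        dist[qp] = nd;
        lab(qr, qc) = n.lab;
        DNode m; m.d = nd; m.p = qp; m.lab = n.lab;
        pq.push(m);
      }
    }
  }
  return lab;
}

struct WNode {
  double h; long ord; int p; int lab;
  bool operator<(const WNode& o) const {
    if (h != o.h) return h > o.h;      // lower "height" first
    return ord > o.ord;                 // FIFO among equals
  }
};

// Seeded watershed by priority flood: labels grow from seeds in order of
// increasing height (pass -intensity to flood bright objects), restricted
// to mask. Unreached mask pixels keep label 0.
// [[Rcpp::export(name = ".watershed_seeded")]]
IntegerMatrix watershed_seeded(NumericMatrix height, IntegerMatrix seeds,
                               IntegerMatrix mask) {
  int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<char> done((size_t)nr * nc, 0);
  std::priority_queue<WNode> pq;
  long ord = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c) != 0) {
        lab(r, c) = seeds(r, c);
        WNode n; n.h = height(r, c); n.ord = ord++; n.p = idx(r, c, nr);
        n.lab = seeds(r, c);
        pq.push(n);
      }
  while (!pq.empty()) {
    WNode n = pq.top(); pq.pop();
    if (done[n.p]) continue;
    done[n.p] = 1;
    lab(n.p % nr, n.p / nr) = n.lab;
    int pr = n.p % nr, pc = n.p / nr;
    for (int k = 0; k < 8; ++k) {
      int qr = pr + DR8[k], qc = pc + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      int qp = idx(qr, qc, nr);
      if (done[qp] || mask(qr, qc) == 0 || lab(qr, qc) > 0) continue;
      lab(qr, qc) = n.lab;
      WNode m; m.h = height(qr, qc); m.ord = ord++; m.p = qp; m.lab = n.lab;
      pq.push(m);
    }
  }
  return lab;
}

// Grey-scale max filter with a disk structuring element.
// [[Rcpp::export(name = ".max_filter_disk")]]
NumericMatrix max_filter_disk(NumericMatrix img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<std::pair<int,int> > off = disk_offsets(radius);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = R_NegInf;
      for (size_t k = 0; k < off.size(); ++k) {
        int qr = r + off[k].first, qc = c + off[k].second;
        if (qr >= 0 && qr < nr && qc >= 0 && qc < nc && img(qr, qc) > m)
          m = img(qr, qc);
      }
      out(r, c) = m;
    }
  return out;
}

// Distance to the nearest zero pixel (geodesic 8-neighbour chamfer,
// multi-source Dijkstra). Zero pixels get distance 0.
// [[Rcpp::export(name = ".dist_to_zero")]]
NumericMatrix dist_to_zero(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix dist(nr, nc);
  std::priority_queue<DNode> pq;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) {
        dist(r, c) = 0.0;
        DNode n; n.d = 0.0; n.p = idx(r, c, nr); n.lab = 0;
        pq.push(n);
      } else {
        dist(r, c) = R_PosInf;
      }
    }
  while (!pq.empty()) {
    DNode n = pq.top(); pq.pop();
    int pr = n.p % nr, pc = n.p / nr;
    if (n.d > dist(pr, pc)) continue;
    for (int k = 0; k < 8; ++k) {
      int qr = pr + DR8[k], qc = pc + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      double nd = n.d + DL8[k];
      if (nd < dist(qr, qc)) {
        dist(qr, qc) = nd;
        DNode m; m.d = nd; m.p = idx(qr, qc, nr); m.lab = 0;
        pq.push(m);
      }
    }
  }
  return dist;
}
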