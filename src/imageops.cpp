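#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8- or 4-connected component labeling by iterative flood fill.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Binary dilation with a disk of the given radius (in pixels).
// [[Rcpp::export]]
LogicalMatrix cpp_dilate(const LogicalMatrix& mask, double radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  int R = (int)std::floor(radius);
  std::vector<std::pair<int,int> > off;
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc)
      if ((double)(dr * dr + dc * dc) <= radius * radius + 1e-9)
        off.push_back(std::make_pair(dr, dc));
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (size_t k = 0; k < off.size(); ++k) {
        int r2 = r + off[k].first, c2 = c + off[k].second;
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) out(r2, c2) = true;
      }
    }
  return out;
}

// Grayscale max filter over a disk neighbourhood (for local-maximum detection).
// [[Rcpp::export]]
NumericMatrix cpp_maxfilter(const NumericMatrix& img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  int R = (int)std::floor(radius);
  std::vector<std::pair<int,int> > off;
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc)
      if ((double)(dr * dr + dc * dc) <= radius * radius + 1e-9)
        off.push_back(std::make_pair(dr, dc));
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = R_NegInf;
      for (size_t k = 0; k < off.size(); ++k) {
        int r2 = r + off[k].first, c2 = c + off[k].second;
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && img(r2, c2) > m)
          m = img(r2, c2);
      }
      out(r, c) = m;
    }
  return out;
}

// Two-pass chamfer distance (1, sqrt2) from each foreground pixel to the
// nearest background pixel.
// [[Rcpp::export]]
NumericMatrix cpp_disttrans(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e15, SQ2 = std::sqrt(2.0);
  NumericMatrix d(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) d(r, c) = mask(r, c) ? BIG : 0.0;
  // forward
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (d(r, c) == 0.0) continue;
      double v = d(r, c);
      if (r > 0 && d(r - 1, c) + 1 < v) v = d(r - 1, c) + 1;
      if (c > 0 && d(r, c - 1) + 1 < v) v = d(r, c - 1) + 1;
      if (r > 0 && c > 0 && d(r - 1, c - 1) + SQ2 < v) v = d(r - 1, c - 1) + SQ2;
      if (r < nr - 1 && c > 0 && d(r + 1, c - 1) + SQ2 < v) v = d(r + 1, c - 1) + SQ2;
      d(r, c) = v;
    }
  // backward
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      if (d(r, c) == 0.0) continue;
      double v = d(r, c);
      if (r < nr - 1 && d(r + 1, c) + 1 < v) v = d(r + 1, c) + 1;
      if (c < nc - 1 && d(r, c + 1) + 1 < v) v = d(r, c + 1) + 1;
      if (r < nr - 1 && c < nc - 1 && d(r + 1, c + 1) + SQ2 < v) v = d(r + 1, c + 1) + SQ2;
      if (r > 0 && c < nc - 1 && d(r - 1, c + 1) + SQ2 < v) v = d(r - 1, c + 1) + SQ2;
      d(r, c) = v;
    }
  return d;
}

struct WsNode {
  double v;
  long order;
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.v != b.v) return a.v > b.v;  // lower relief first
    return a.order > b.order;          // FIFO among ties
  }
};

// Marker-controlled watershed: flood the relief upward from the markers,
// restricted to mask. Unclaimed mask pixels adjacent to two basins keep the
// first claim (boundary pixels are assigned, not left as ridges).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& relief,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  const int nr = relief.nrow(), nc = relief.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        WsNode n; n.v = relief(r, c); n.order = order++; n.idx = r + c * nr;
        pq.push(n);
      }
  while (!pq.empty()) {
    WsNode n = pq.top();
    pq.pop();
    int r = n.idx % nr, c = n.idx / nr;
    int me = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2)) continue;
      lab(r2, c2) = me;
      WsNode m; m.v = relief(r2, c2); m.order = order++; m.idx = r2 + c2 * nr;
      pq.push(m);
    }
  }
  return lab;
}

static inline int nb(const LogicalMatrix& m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          int p2 = nb(img, r - 1, c), p3 = nb(img, r - 1, c + 1);
          int p4 = nb(img, r, c + 1), p5 = nb(img, r + 1, c + 1);
          int p6 = nb(img, r + 1, c), p7 = nb(img, r + 1, c - 1);
          int p8 = nb(img, r, c - 1), p9 = nb(img, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(r + c * nr);
        }
      for (size_t k = 0; k < kill.size(); ++k)
        img(kill[k] % nr, kill[k] / nr) = false;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}

// Separable convolution with reflect padding; kx runs along rows (vertical),
// ky along columns (horizontal).
// [[Rcpp::export]]
NumericMatrix cpp_convsep(const NumericMatrix& img, const NumericVector& kx,
                          const NumericVector& ky) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hx = (kx.size() - 1) / 2, hy = (ky.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int k = -hx; k <= hx; ++k) {
        int r2 = r + k;
        if (r2 < 0) r2 = -r2 - 1;
        if (r2 >= nr) r2 = 2 * nr - r2 - 1;
        s += img(r2, c) * kx[k + hx];
      }
      tmp(r, c) = s;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int k = -hy; k <= hy; ++k) {
        int c2 = c + k;
        if (c2 < 0) c2 = -c2 - 1;
        if (c2 >= nc) c2 = 2 * nc - c2 - 1;
        s += tmp(r, c2) * ky[k + hy];
      }
      out(r, c) = s;
    }
  return out;
}
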