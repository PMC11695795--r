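// 3D binary/greyscale morphology for voxel volumes stored as R arrays
// (column-major, first index = depth). All routines are deterministic:
// ties are broken by the lower linear index.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Grid {
  int d1, d2, d3;
  R_xlen_t n;
  Grid(const IntegerVector& dim) {
    if (dim.size() != 3) stop("dim must have length 3");
    d1 = dim[0]; d2 = dim[1]; d3 = dim[2];
    n = (R_xlen_t)d1 * d2 * d3;
  }
  inline R_xlen_t idx(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * k);
  }
  inline void coords(R_xlen_t p, int& i, int& j, int& k) const {
    i = (int)(p % d1);
    R_xlen_t r = p / d1;
    j = (int)(r % d2);
    k = (int)(r / d2);
  }
};

// neighbour offsets for 6- or 26-connectivity
std::vector<std::array<int,3> > neighbour_offsets(int conn) {
  std::vector<std::array<int,3> > off;
  if (conn == 6) {
    off = { {{-1,0,0}}, {{1,0,0}}, {{0,-1,0}}, {{0,1,0}}, {{0,0,-1}}, {{0,0,1}} };
  } else if (conn == 26) {
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          if (di || dj || dk) off.push_back({{di, dj, dk}});
  } else {
    stop("connectivity must be 6 or 26");
  }
  return off;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim, int conn) {
  Grid g(dim);
  if (mask.size() != g.n) stop("mask length does not match dim");
  std::vector<std::array<int,3> > off = neighbour_offsets(conn);
  IntegerVector lab(g.n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t p = 0; p < g.n; ++p) {
    if (!mask[p] || lab[p]) continue;
    ++next;
    lab[p] = next;
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      R_xlen_t q = stack.back(); stack.pop_back();
      int i, j, k; g.coords(q, i, j, k);
      for (size_t m = 0; m < off.size(); ++m) {
        int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= g.d1 || jj >= g.d2 || kk >= g.d3)
          continue;
        R_xlen_t r = g.idx(ii, jj, kk);
        if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
      }
    }
  }
  return lab;
}

// erosion/dilation with the radius-1 cross (6-neighbour) structuring
// element, applied `iters` times; outside the array counts as background.
static IntegerVector morph6(const IntegerVector& mask, const Grid& g,
                            int iters, bool erode) {
  IntegerVector cur = clone(mask);
  std::vector<std::array<int,3> > off = neighbour_offsets(6);
  for (int it = 0; it < iters; ++it) {
    IntegerVector nxt(g.n);
    for (R_xlen_t p = 0; p < g.n; ++p) {
      int i, j, k; g.coords(p, i, j, k);
      if (erode) {
        int keep = cur[p];
        if (keep) {
          for (size_t m = 0; m < off.size() && keep; ++m) {
            int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
            if (ii < 0 || jj < 0 || kk < 0 ||
                ii >= g.d1 || jj >= g.d2 || kk >= g.d3) { keep = 0; break; }
            if (!cur[g.idx(ii, jj, kk)]) keep = 0;
          }
        }
        nxt[p] = keep;
      } else {
        int on = cur[p];
        for (size_t m = 0; m < off.size() && !on; ++m) {
          int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
          if (ii < 0 || jj < 0 || kk < 0 ||
              ii >= g.d1 || jj >= g.d2 || kk >= g.d3) continue;
          if (cur[g.idx(ii, jj, kk)]) on = 1;
        }
        nxt[p] = on;
      }
    }
    cur = nxt;
  }
  return cur;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_erode3d(IntegerVector mask, IntegerVector dim, int iters) {
  Grid g(dim);
  if (mask.size() != g.n) stop("mask length does not match dim");
  return morph6(mask, g, iters, true);
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_dilate3d(IntegerVector mask, IntegerVector dim, int iters) {
  Grid g(dim);
  if (mask.size() != g.n) stop("mask length does not match dim");
  return morph6(mask, g, iters, false);
}

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// "No feature in range" is encoded as a large finite sentinel so the
// parabola intersections stay well defined.
static const double EDT_BIG = 1e20;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double fv = f[v[k]];
      s = ((f[q] + (double)q * q) - (fv + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k]) { // k == 0, replace
      v[0] = q; z[0] = -INF; z[1] = INF; k = 0;
    } else {
      ++k;
      v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double fv = f[v[k]];
    d[q] = std::min(EDT_BIG, (double)(q - v[k]) * (q - v[k]) + fv);
  }
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector feature, IntegerVector dim) {
  Grid g(dim);
  if (feature.size() != g.n) stop("mask length does not match dim");
  NumericVector dist(g.n);
  for (R_xlen_t p = 0; p < g.n; ++p) dist[p] = feature[p] ? 0.0 : EDT_BIG;
  int nmax = std::max(g.d1, std::max(g.d2, g.d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along first dimension
  for (int k = 0; k < g.d3; ++k)
    for (int j = 0; j < g.d2; ++j) {
      for (int i = 0; i < g.d1; ++i) f[i] = dist[g.idx(i, j, k)];
      dt1d(f, d, v, z, g.d1);
      for (int i = 0; i < g.d1; ++i) dist[g.idx(i, j, k)] = d[i];
    }
  // second dimension
  for (int k = 0; k < g.d3; ++k)
    for (int i = 0; i < g.d1; ++i) {
      for (int j = 0; j < g.d2; ++j) f[j] = dist[g.idx(i, j, k)];
      dt1d(f, d, v, z, g.d2);
      for (int j = 0; j < g.d2; ++j) dist[g.idx(i, j, k)] = d[j];
    }
  // third dimension
  for (int j = 0; j < g.d2; ++j)
    for (int i = 0; i < g.d1; ++i) {
      for (int k = 0; k < g.d3; ++k) f[k] = dist[g.idx(i, j, k)];
      dt1d(f, d, v, z, g.d3);
      for (int k = 0; k < g.d3; ++k) dist[g.idx(i, j, k)] = d[k];
    }
  for (R_xlen_t p = 0; p < g.n; ++p)
    dist[p] = (dist[p] >= 1e18) ? R_PosInf : std::sqrt(dist[p]);
  return dist;
}

//' Greyscale reconstruction by dilation (Vincent's hybrid algorithm).
//' marker must be <= mask everywhere; reconstruction floods marker under mask.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilation(NumericVector marker, NumericVector mask,
                                       IntegerVector dim, int conn) {
  Grid g(dim);
  if (marker.size() != g.n || mask.size() != g.n)
    stop("marker/mask length does not match dim");
  std::vector<std::array<int,3> > all = neighbour_offsets(conn);
  std::vector<std::array<int,3> > bwd, fwd;
  for (size_t m = 0; m < all.size(); ++m) {
    // raster order: linear offset sign decides backward vs forward
    long lin = all[m][0] + (long)g.d1 * (all[m][1] + (long)g.d2 * all[m][2]);
    if (lin < 0) bwd.push_back(all[m]); else fwd.push_back(all[m]);
  }
  NumericVector J = clone(marker);
  for (R_xlen_t p = 0; p < g.n; ++p)
    if (J[p] > mask[p]) stop("marker exceeds mask");
  // forward raster scan
  for (R_xlen_t p = 0; p < g.n; ++p) {
    int i, j, k; g.coords(p, i, j, k);
    double v = J[p];
    for (size_t m = 0; m < bwd.size(); ++m) {
      int ii = i + bwd[m][0], jj = j + bwd[m][1], kk = k + bwd[m][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.d1 || jj >= g.d2 || kk >= g.d3)
        continue;
      double w = J[g.idx(ii, jj, kk)];
      if (w > v) v = w;
    }
    J[p] = std::min(v, (double)mask[p]);
  }
  // backward raster scan + queue seeding
  std::queue<R_xlen_t> fifo;
  for (R_xlen_t p = g.n - 1; p >= 0; --p) {
    int i, j, k; g.coords(p, i, j, k);
    double v = J[p];
    for (size_t m = 0; m < fwd.size(); ++m) {
      int ii = i + fwd[m][0], jj = j + fwd[m][1], kk = k + fwd[m][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.d1 || jj >= g.d2 || kk >= g.d3)
        continue;
      double w = J[g.idx(ii, jj, kk)];
      if (w > v) v = w;
    }
    J[p] = std::min(v, (double)mask[p]);
    for (size_t m = 0; m < fwd.size(); ++m) {
      int ii = i + fwd[m][0], jj = j + fwd[m][1], kk = k + fwd[m][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.d1 || jj >= g.d2 || kk >= g.d3)
        continue;
      R_xlen_t q = g.idx(ii, jj, kk);
      if (J[q] < J[p] && J[q] < mask[q]) { fifo.push(p); break; }
    }
    if (p == 0) break;
  }
  // propagation
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    int i, j, k; g.coords(p, i, j, k);
    for (size_t m = 0; m < all.size(); ++m) {
      int ii = i + all[m][0], jj = j + all[m][1], kk = k + all[m][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.d1 || jj >= g.d2 || kk >= g.d3)
        continue;
      R_xlen_t q = g.idx(ii, jj, kk);
      if (J[q] < J[p] && mask[q] != J[q]) {
        J[q] = std::min(J[p], (double)mask[q]);
        fifo.push(q);
      }
    }
  }
  return J;
}

//' Regional maxima of f restricted to mask (voxels outside mask count as
//' lower than any value inside).
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector f, IntegerVector mask,
                                  IntegerVector dim, int conn) {
  Grid g(dim);
  if (f.size() != g.n || mask.size() != g.n)
    stop("f/mask length does not match dim");
  std::vector<std::array<int,3> > off = neighbour_offsets(conn);
  IntegerVector out(g.n, 0);
  std::vector<signed char> state(g.n, 0); // 0 unvisited, 1 visited
  std::vector<R_xlen_t> plateau, stack;
  for (R_xlen_t p = 0; p < g.n; ++p) {
    if (!mask[p] || state[p]) continue;
    double val = f[p];
    bool is_max = true;
    plateau.clear(); stack.clear();
    stack.push_back(p); state[p] = 1;
    while (!stack.empty()) {
      R_xlen_t q = stack.back(); stack.pop_back();
      plateau.push_back(q);
      int i, j, k; g.coords(q, i, j, k);
      for (size_t m = 0; m < off.size(); ++m) {
        int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= g.d1 || jj >= g.d2 || kk >= g.d3)
          continue;
        R_xlen_t r = g.idx(ii, jj, kk);
        if (!mask[r]) continue;
        if (f[r] > val) { is_max = false; continue; }
        if (f[r] == val && !state[r]) { state[r] = 1; stack.push_back(r); }
      }
    }
    if (is_max)
      for (size_t m = 0; m < plateau.size(); ++m) out[plateau[m]] = 1;
  }
  return out;
}

namespace {
struct WsNode {
  double pri;
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.pri != b.pri) return a.pri < b.pri;  // max-heap on priority
    return a.idx > b.idx;                      // then lowest index first
  }
};
}

//' Marker-based watershed by priority flooding: flood from markers in order
//' of decreasing priority (e.g. the distance transform), restricted to mask.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            IntegerVector mask, IntegerVector dim, int conn) {
  Grid g(dim);
  if (priority.size() != g.n || markers.size() != g.n || mask.size() != g.n)
    stop("input length does not match dim");
  std::vector<std::array<int,3> > off = neighbour_offsets(conn);
  IntegerVector lab(g.n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  for (R_xlen_t p = 0; p < g.n; ++p) {
    if (markers[p] > 0 && mask[p]) {
      lab[p] = markers[p];
      pq.push({priority[p], p});
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    R_xlen_t p = nd.idx;
    int i, j, k; g.coords(p, i, j, k);
    for (size_t m = 0; m < off.size(); ++m) {
      int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.d1 || jj >= g.d2 || kk >= g.d3)
        continue;
      R_xlen_t q = g.idx(ii, jj, kk);
      if (mask[q] && lab[q] == 0) {
        lab[q] = lab[p];
        pq.push({priority[q], q});
      }
    }
  }
  return lab;
}

//' Voxels of a labelled volume that touch a voxel with a different positive
//' label (used to sever watershed basins).
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label_boundary(IntegerVector lab, IntegerVector dim,
                                 int conn) {
  Grid g(dim);
  if (lab.size() != g.n) stop("labels length does not match dim");
  std::vector<std::array<int,3> > off = neighbour_offsets(conn);
  IntegerVector out(g.n, 0);
  for (R_xlen_t p = 0; p < g.n; ++p) {
    if (lab[p] <= 0) continue;
    int i, j, k; g.coords(p, i, j, k);
    for (size_t m = 0; m < off.size(); ++m) {
      int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.d1 || jj >= g.d2 || kk >= g.d3)
        continue;
      int l = lab[g.idx(ii, jj, kk)];
      if (l > 0 && l != lab[p]) { out[p] = 1; break; }
    }
  }
  return out;
}

//' Binary median (majority) filter over a cubic window of half-width radius;
//' windows are clipped at the array border. Ties count as foreground.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_majority3d(IntegerVector mask, IntegerVector dim, int radius) {
  Grid g(dim);
  if (mask.size() != g.n) stop("mask length does not match dim");
  IntegerVector out(g.n);
  for (int k = 0; k < g.d3; ++k) {
    int k0 = std::max(0, k - radius), k1 = std::min(g.d3 - 1, k + radius);
    for (int j = 0; j < g.d2; ++j) {
      int j0 = std::max(0, j - radius), j1 = std::min(g.d2 - 1, j + radius);
      for (int i = 0; i < g.d1; ++i) {
        int i0 = std::max(0, i - radius), i1 = std::min(g.d1 - 1, i + radius);
        int cnt = 0, ones = 0;
        for (int kk = k0; kk <= k1; ++kk)
          for (int jj = j0; jj <= j1; ++jj)
            for (int ii = i0; ii <= i1; ++ii) {
              ++cnt;
              ones += mask[g.idx(ii, jj, kk)];
            }
        out[g.idx(i, j, k)] = (2 * ones >= cnt) ? 1 : 0;
      }
    }
  }
  return out;
}

//' Separable box blur (one pass per axis), used to soften grey-level phantoms.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_boxblur3d(NumericVector vol, IntegerVector dim, int radius) {
  Grid g(dim);
  if (vol.size() != g.n) stop("volume length does not match dim");
  NumericVector cur = clone(vol);
  for (int axis = 0; axis < 3; ++axis) {
    NumericVector nxt(g.n);
    for (R_xlen_t p = 0; p < g.n; ++p) {
      int i, j, k; g.coords(p, i, j, k);
      double s = 0; int c = 0;
      for (int t = -radius; t <= radius; ++t) {
        int ii = i + (axis == 0 ? t : 0);
        int jj = j + (axis == 1 ? t : 0);
        int kk = k + (axis == 2 ? t : 0);
        if (ii < 0 || jj < 0 || kk < 0 || ii >= g.d1 || jj >= g.d2 || kk >= g.d3)
          continue;
        s += cur[g.idx(ii, jj, kk)];
        ++c;
      }
      nxt[p] = s / c;
    }
    cur = nxt;
  }
  return cur;
}
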