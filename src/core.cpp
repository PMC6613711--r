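// Low-level voxel-grid algorithms: exact Euclidean distance transform,
// first-order fast marching for the eikonal equation, connected-component
// labelling, steepest-descent backtracing and regional maxima detection.
// All arrays are passed as flat vectors in R's column-major layout with
// dims = (nx, ny, nz) and physical voxel spacing in mm.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Grid {
  int nx, ny, nz;
  double hx, hy, hz;
  Grid(IntegerVector dims, NumericVector h) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    hx = h[0]; hy = h[1]; hz = h[2];
  }
  inline R_xlen_t n() const { return (R_xlen_t)nx * ny * nz; }
  inline R_xlen_t idx(int x, int y, int z) const {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  }
  inline void coords(R_xlen_t i, int &x, int &y, int &z) const {
    x = (int)(i % nx);
    y = (int)((i / nx) % ny);
    z = (int)(i / ((R_xlen_t)nx * ny));
  }
};

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable with per-axis sample spacing.

// Infinities are mapped to BIG by the caller so the parabola intersections
// stay finite; any result >= BIG is mapped back to Inf afterwards.
static const double BIG = 1e30;

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  double h2 = h * h;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) {
        k--;
      } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = h2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector h) {
  // distance from each voxel to the nearest voxel where mask is FALSE
  Grid g(dims, h);
  R_xlen_t n = g.n();
  NumericVector out(n);
  std::vector<double> D((size_t)n);
  for (R_xlen_t i = 0; i < n; i++) D[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(g.nx, std::max(g.ny, g.nz));
  std::vector<double> f(nmax), d(nmax);

  // pass along x
  for (int z = 0; z < g.nz; z++)
    for (int y = 0; y < g.ny; y++) {
      for (int x = 0; x < g.nx; x++) f[x] = D[g.idx(x, y, z)];
      dt1d(f, d, g.nx, g.hx);
      for (int x = 0; x < g.nx; x++) D[g.idx(x, y, z)] = d[x];
    }
  // pass along y
  for (int z = 0; z < g.nz; z++)
    for (int x = 0; x < g.nx; x++) {
      for (int y = 0; y < g.ny; y++) f[y] = D[g.idx(x, y, z)];
      dt1d(f, d, g.ny, g.hy);
      for (int y = 0; y < g.ny; y++) D[g.idx(x, y, z)] = d[y];
    }
  // pass along z
  for (int y = 0; y < g.ny; y++)
    for (int x = 0; x < g.nx; x++) {
      for (int z = 0; z < g.nz; z++) f[z] = D[g.idx(x, y, z)];
      dt1d(f, d, g.nz, g.hz);
      for (int z = 0; z < g.nz; z++) D[g.idx(x, y, z)] = d[z];
    }
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (D[i] >= 0.5 * BIG) ? R_PosInf : std::sqrt(D[i]);
  return out;
}

// ---------------------------------------------------------------------------
// First-order fast marching: |grad T| = 1/S, T = 0 on seeds.
// Voxels with S <= 0 are impassable (T = Inf).

struct HeapNode {
  double t;
  R_xlen_t i;
  bool operator>(const HeapNode &o) const { return t > o.t; }
};

static double eikonal_update(const Grid &g, const std::vector<double> &T,
                             const std::vector<char> &state, R_xlen_t i,
                             double invS) {
  int x, y, z;
  g.coords(i, x, y, z);
  double hh[3] = {g.hx, g.hy, g.hz};
  int pos[3] = {x, y, z};
  int ext[3] = {g.nx, g.ny, g.nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)g.nx, (R_xlen_t)g.nx * g.ny};

  // Per axis: upwind value a (smallest accepted 1-neighbour) and, where the
  // 2-neighbour on the same side is accepted with a smaller value, the
  // second-order coefficients (Sethian): weight 9/(4h^2), k = (4T1 - T2)/3.
  double kk[3], ww[3];
  for (int d = 0; d < 3; d++) {
    kk[d] = INF;
    ww[d] = 0.0;
    double best = INF;
    int side = 0;
    if (pos[d] > 0 && state[i - stride[d]] == 2) {
      best = T[i - stride[d]];
      side = -1;
    }
    if (pos[d] < ext[d] - 1 && state[i + stride[d]] == 2 &&
        T[i + stride[d]] < best) {
      best = T[i + stride[d]];
      side = +1;
    }
    if (side == 0) continue;
    double h2 = hh[d] * hh[d];
    kk[d] = best;
    ww[d] = 1.0 / h2;
    int p2 = pos[d] + 2 * side;
    if (p2 >= 0 && p2 < ext[d]) {
      R_xlen_t j2 = i + 2 * side * stride[d];
      if (state[j2] == 2 && T[j2] <= best) {
        kk[d] = (4.0 * best - T[j2]) / 3.0;
        ww[d] = 9.0 / (4.0 * h2);
      }
    }
  }

  int ord[3] = {0, 1, 2};
  std::sort(ord, ord + 3, [&](int p, int q) { return kk[p] < kk[q]; });

  // solve sum_d ww_d (T - kk_d)^2 = invS^2 over the m smallest kk
  for (int m = 3; m >= 1; m--) {
    double A = 0.0, B = 0.0, C = -invS * invS;
    bool ok = true;
    for (int j = 0; j < m; j++) {
      int d = ord[j];
      if (kk[d] == INF) { ok = false; break; }
      A += ww[d];
      B += -2.0 * kk[d] * ww[d];
      C += kk[d] * kk[d] * ww[d];
    }
    if (!ok) continue;
    double disc = B * B - 4.0 * A * C;
    if (disc < 0) continue;
    double t = (-B + std::sqrt(disc)) / (2.0 * A);
    if (t >= kk[ord[m - 1]]) return t;
  }
  return INF;
}

// [[Rcpp::export(name = ".cpp_fast_march")]]
NumericVector cpp_fast_march(NumericVector speed, LogicalVector seed,
                             IntegerVector dims, NumericVector h) {
  Grid g(dims, h);
  R_xlen_t n = g.n();
  std::vector<double> T((size_t)n, INF);
  std::vector<char> state((size_t)n, 0); // 0 far, 1 trial, 2 accepted
  std::priority_queue<HeapNode, std::vector<HeapNode>, std::greater<HeapNode> > heap;

  for (R_xlen_t i = 0; i < n; i++) {
    if (seed[i]) {
      T[i] = 0.0;
      state[i] = 2;
    }
  }
  // seed the narrow band with exact local distances around accepted seeds,
  // which removes the point-source rarefaction error of plain first-order FMM
  R_xlen_t sz = (R_xlen_t)g.nx * g.ny;
  const R_xlen_t off[6] = {-1, 1, -(R_xlen_t)g.nx, (R_xlen_t)g.nx, -sz, sz};
  for (R_xlen_t i = 0; i < n; i++) {
    if (!seed[i]) continue;
    int x, y, z;
    g.coords(i, x, y, z);
    for (int dz = -2; dz <= 2; dz++)
      for (int dy = -2; dy <= 2; dy++)
        for (int dx = -2; dx <= 2; dx++) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
            continue;
          R_xlen_t j = g.idx(xx, yy, zz);
          if (state[j] == 2 || speed[j] <= 0) continue;
          double dist = std::sqrt(dx * g.hx * dx * g.hx +
                                  dy * g.hy * dy * g.hy +
                                  dz * g.hz * dz * g.hz);
          double t = dist / speed[j];
          if (t < T[j]) {
            T[j] = t;
            state[j] = 1;
            heap.push({t, j});
          }
        }
  }

  while (!heap.empty()) {
    HeapNode top = heap.top();
    heap.pop();
    R_xlen_t i = top.i;
    if (state[i] == 2 || top.t > T[i]) continue; // stale entry
    state[i] = 2;
    int x, y, z;
    g.coords(i, x, y, z);
    for (int k = 0; k < 6; k++) {
      int xx = x, yy = y, zz = z;
      if (k == 0) xx--; else if (k == 1) xx++;
      else if (k == 2) yy--; else if (k == 3) yy++;
      else if (k == 4) zz--; else zz++;
      if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
        continue;
      R_xlen_t j = i + off[k];
      if (state[j] == 2) continue;
      double s = speed[j];
      if (s <= 0 || !R_finite(s)) continue;
      double t = eikonal_update(g, T, state, j, 1.0 / s);
      if (t < T[j]) {
        T[j] = t;
        state[j] = 1;
        heap.push({t, j});
      }
    }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = (T[i] == INF) ? R_PosInf : T[i];
  return out;
}

// ---------------------------------------------------------------------------
// Connected components (6- or 26-connectivity), BFS labelling.

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  Grid g(dims, NumericVector::create(1.0, 1.0, 1.0));
  R_xlen_t n = g.n();
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int x, y, z;
      g.coords(i, x, y, z);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
              continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
              continue;
            R_xlen_t j = g.idx(xx, yy, zz);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Steepest-descent backtracing on an arrival-time field. Starting from a
// voxel, repeatedly step to the 26-neighbour with the smallest arrival time
// (strictly smaller than the current one; ties broken by lowest linear
// index), stopping on entry into the stop set or at T == 0. Returns 1-based
// linear indices of the path, including start and stopping voxel.

// [[Rcpp::export(name = ".cpp_backtrace")]]
IntegerVector cpp_backtrace(NumericVector T, LogicalVector stop_set,
                            IntegerVector dims, int start1) {
  Grid g(dims, NumericVector::create(1.0, 1.0, 1.0));
  R_xlen_t i = start1 - 1;
  std::vector<int> path;
  R_xlen_t maxsteps = g.n() + 1;
  for (R_xlen_t step = 0; step < maxsteps; step++) {
    path.push_back((int)(i + 1));
    if (stop_set[i] || T[i] <= 0.0) break;
    int x, y, z;
    g.coords(i, x, y, z);
    double best = T[i];
    R_xlen_t bestj = -1;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
            continue;
          R_xlen_t j = g.idx(xx, yy, zz);
          if (!R_finite(T[j])) continue;
          if (T[j] < best || (T[j] == best && bestj >= 0 && j < bestj)) {
            best = T[j];
            bestj = j;
          }
        }
    if (bestj < 0) break; // local minimum: cannot descend further
    i = bestj;
  }
  return IntegerVector(path.begin(), path.end());
}

// ---------------------------------------------------------------------------
// Regional maxima of a field restricted to a mask: voxels with no
// 26-neighbour inside the mask holding a strictly greater value.

// [[Rcpp::export(name = ".cpp_regional_max")]]
LogicalVector cpp_regional_max(NumericVector T, LogicalVector mask,
                               IntegerVector dims) {
  Grid g(dims, NumericVector::create(1.0, 1.0, 1.0));
  R_xlen_t n = g.n();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || !R_finite(T[i])) { out[i] = false; continue; }
    int x, y, z;
    g.coords(i, x, y, z);
    bool ismax = true;
    for (int dz = -1; dz <= 1 && ismax; dz++)
      for (int dy = -1; dy <= 1 && ismax; dy++)
        for (int dx = -1; dx <= 1 && ismax; dx++) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
            continue;
          R_xlen_t j = g.idx(xx, yy, zz);
          if (mask[j] && R_finite(T[j]) && T[j] > T[i]) ismax = false;
        }
    out[i] = ismax;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Nearest-source labelling: propagate integer labels from source voxels
// (labels > 0) across the mask by geodesic (26-neighbour Dijkstra) distance.
// Used to partition a vessel mask into node regions / edge subsegment discs.

// [[Rcpp::export(name = ".cpp_nearest_label")]]
IntegerVector cpp_nearest_label(IntegerVector labels, LogicalVector mask,
                                IntegerVector dims, NumericVector h) {
  Grid g(dims, h);
  R_xlen_t n = g.n();
  IntegerVector out(n);
  std::vector<double> dist((size_t)n, INF);
  std::priority_queue<HeapNode, std::vector<HeapNode>, std::greater<HeapNode> > heap;
  for (R_xlen_t i = 0; i < n; i++) {
    out[i] = 0;
    if (labels[i] > 0 && mask[i]) {
      out[i] = labels[i];
      dist[i] = 0.0;
      heap.push({0.0, i});
    }
  }
  while (!heap.empty()) {
    HeapNode top = heap.top();
    heap.pop();
    R_xlen_t i = top.i;
    if (top.t > dist[i]) continue;
    int x, y, z;
    g.coords(i, x, y, z);
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
            continue;
          R_xlen_t j = g.idx(xx, yy, zz);
          if (!mask[j]) continue;
          double step = std::sqrt(dx * g.hx * dx * g.hx +
                                  dy * g.hy * dy * g.hy +
                                  dz * g.hz * dz * g.hz);
          double nd = dist[i] + step;
          if (nd < dist[j]) {
            dist[j] = nd;
            out[j] = out[i];
            heap.push({nd, j});
          }
        }
  }
  return out;
}
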