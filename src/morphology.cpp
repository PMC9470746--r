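// Low-level raster morphology shared by the 2D and 3D pipelines.
// All arrays are column-major with dim (y, x) for images and (y, x, z) for
// volumes, matching R's array layout. Physical spacings are passed per axis
// so distance computations honor anisotropic voxels.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Grid {
  int ny, nx, nz;
  Grid(IntegerVector dim) {
    ny = dim[0];
    nx = dim[1];
    nz = (dim.size() > 2) ? dim[2] : 1;
  }
  inline R_xlen_t idx(int y, int x, int z) const {
    return (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y;
  }
  inline bool inside(int y, int x, int z) const {
    return y >= 0 && y < ny && x >= 0 && x < nx && z >= 0 && z < nz;
  }
};

} // namespace

// ---------------------------------------------------------------------------
// Connected-component labeling, 8-connected (2D) / 26-connected (3D).
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  R_xlen_t n = (R_xlen_t)g.ny * g.nx * g.nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int z = (int)(p / ((R_xlen_t)g.ny * g.nx));
      int r = (int)(p % ((R_xlen_t)g.ny * g.nx));
      int x = r / g.ny, y = r % g.ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (dy == 0 && dx == 0 && dz == 0) continue;
            int yy = y + dy, xx = x + dx, zz = z + dz;
            if (!g.inside(yy, xx, zz)) continue;
            R_xlen_t q = g.idx(yy, xx, zz);
            if (mask[q] && lab[q] == 0) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable per axis with physical spacing weights. Returns, for every
// voxel, the squared distance (um^2) to the nearest background voxel.
// Background voxels themselves are 0. Callers must guarantee at least one
// background voxel (pad if needed).

static void edt_1d(std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& zb,
                   int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF && f[v[k]] == INF) { // both infinite: skip parabola
      continue;
    }
    double s;
    while (true) {
      double fq = f[q], fv = f[v[k]];
      if (fv == INF) { s = -INF; }
      else if (fq == INF) { s = INF; }
      else {
        s = ((fq + w2 * q * q) - (fv + w2 * v[k] * v[k])) /
            (2.0 * w2 * (q - v[k]));
      }
      if (s <= zb[k]) { --k; }
      else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double fv = f[v[k]];
    d[q] = (fv == INF) ? INF : w2 * (q - v[k]) * (q - v[k]) + fv;
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  // spacing = c(sy, sx, sz) in um
  Grid g(dim);
  R_xlen_t n = (R_xlen_t)g.ny * g.nx * g.nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(g.ny, std::max(g.nx, g.nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // y axis
  double w2 = spacing[0] * spacing[0];
  for (int z = 0; z < g.nz; ++z)
    for (int x = 0; x < g.nx; ++x) {
      bool any = false;
      for (int y = 0; y < g.ny; ++y) { f[y] = D[g.idx(y, x, z)]; if (f[y] < INF) any = true; }
      if (!any) continue;
      edt_1d(f, d, v, zb, g.ny, w2);
      for (int y = 0; y < g.ny; ++y) D[g.idx(y, x, z)] = d[y];
    }
  // x axis
  w2 = spacing[1] * spacing[1];
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y) {
      bool any = false;
      for (int x = 0; x < g.nx; ++x) { f[x] = D[g.idx(y, x, z)]; if (f[x] < INF) any = true; }
      if (!any) continue;
      edt_1d(f, d, v, zb, g.nx, w2);
      for (int x = 0; x < g.nx; ++x) D[g.idx(y, x, z)] = d[x];
    }
  // z axis
  if (g.nz > 1) {
    w2 = spacing[2] * spacing[2];
    for (int x = 0; x < g.nx; ++x)
      for (int y = 0; y < g.ny; ++y) {
        bool any = false;
        for (int z = 0; z < g.nz; ++z) { f[z] = D[g.idx(y, x, z)]; if (f[z] < INF) any = true; }
        if (!any) continue;
        edt_1d(f, d, v, zb, g.nz, w2);
        for (int z = 0; z < g.nz; ++z) D[g.idx(y, x, z)] = d[z];
      }
  }
  D.attr("dim") = dim;
  return D;
}

// ---------------------------------------------------------------------------
// Seeded watershed by priority flooding on a height map (here: the EDT, so
// basins grow from the thickest parts outward). Voxels are popped in order
// of decreasing height; an unlabeled foreground neighbor inherits the label
// of the popping voxel. Deterministic: ties broken by linear index.

struct QEntry {
  double h;
  R_xlen_t i;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.h != b.h) return a.h < b.h; // max-heap on height
    return a.i > b.i;                 // then smallest index first
  }
};

// [[Rcpp::export(name = ".watershed_flood")]]
IntegerVector watershed_flood(NumericVector height, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  R_xlen_t n = (R_xlen_t)g.ny * g.nx * g.nz;
  IntegerVector lab(clone(seeds));
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  for (R_xlen_t i = 0; i < n; ++i)
    if (lab[i] > 0) pq.push({height[i], i});
  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    R_xlen_t p = e.i;
    int z = (int)(p / ((R_xlen_t)g.ny * g.nx));
    int r = (int)(p % ((R_xlen_t)g.ny * g.nx));
    int x = r / g.ny, y = r % g.ny;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          if (dy == 0 && dx == 0 && dz == 0) continue;
          int yy = y + dy, xx = x + dx, zz = z + dz;
          if (!g.inside(yy, xx, zz)) continue;
          R_xlen_t q = g.idx(yy, xx, zz);
          if (mask[q] && lab[q] == 0) {
            lab[q] = lab[p];
            pq.push({height[q], q});
          }
        }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// 2D sequential thinning. A pixel is deletable when it is 8-simple (Yokoi
// connectivity number for 8-connected foreground equals 1) and not a curve
// endpoint. Four directional subiterations (N, S, E, W border) per cycle
// keep the skeleton medial; deletion is sequential so connectivity can
// never break within a subiteration.

static inline int nb8(const std::vector<char>& m, int ny, int nx,
                      int y, int x, int k) {
  // neighbors in circular order starting E: E, NE, N, NW, W, SW, S, SE
  static const int dy[8] = { 0, -1, -1, -1,  0,  1, 1, 1 };
  static const int dx[8] = { 1,  1,  0, -1, -1, -1, 0, 1 };
  int yy = y + dy[k], xx = x + dx[k];
  if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) return 0;
  return m[(R_xlen_t)xx * ny + yy];
}

static bool simple2d(const std::vector<char>& m, int ny, int nx, int y, int x,
                     int* nfg) {
  int b[8];
  int cnt = 0;
  for (int k = 0; k < 8; ++k) { b[k] = nb8(m, ny, nx, y, x, k); cnt += b[k]; }
  *nfg = cnt;
  // Yokoi connectivity number for 8-connectivity:
  // sum over k in {0,2,4,6}: (1-b[k]) - (1-b[k])(1-b[k+1])(1-b[k+2])
  int c = 0;
  for (int k = 0; k < 8; k += 2) {
    int a0 = 1 - b[k];
    int a1 = 1 - b[(k + 1) % 8];
    int a2 = 1 - b[(k + 2) % 8];
    c += a0 - a0 * a1 * a2;
  }
  return c == 1;
}

// [[Rcpp::export(name = ".thin2d")]]
LogicalVector thin2d(LogicalVector mask, IntegerVector dim) {
  int ny = dim[0], nx = dim[1];
  R_xlen_t n = (R_xlen_t)ny * nx;
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  // border direction offsets (dy,dx): N, S, W, E in image terms
  static const int ddy[4] = { -1, 1, 0, 0 };
  static const int ddx[4] = { 0, 0, -1, 1 };
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      // two-phase: candidates with the directional border evaluated on the
      // state at pass start (prevents erosion cascades along the scan),
      // then sequential deletion with simpleness re-checked on the
      // evolving state (preserves connectivity)
      cand.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
          R_xlen_t p = (R_xlen_t)x * ny + y;
          if (!m[p]) continue;
          int yy = y + ddy[d], xx = x + ddx[d];
          bool borderBg = !(yy >= 0 && yy < ny && xx >= 0 && xx < nx) ||
                          !m[(R_xlen_t)xx * ny + yy];
          if (borderBg) cand.push_back(p);
        }
      for (R_xlen_t p : cand) {
        if (!m[p]) continue;
        int x = (int)(p / ny), y = (int)(p % ny);
        int nfg;
        if (simple2d(m, ny, nx, y, x, &nfg) && nfg >= 2) {
          m[p] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 3D curve thinning by sequential removal of simple points that are not
// curve endpoints, in six directional subiterations (U, D, N, S, E, W).
// Simple-point test (Malandain & Bertrand characterization):
//   C*  : number of 26-connected components of foreground within N26(p) == 1
//   Cbar: number of 6-connected components of background within N18(p)
//         that are 6-adjacent to p == 1

static const int N26dy[26] = {
  -1,0,1,-1,0,1,-1,0,1, -1,0,1,-1,1,-1,0,1, -1,0,1,-1,0,1,-1,0,1 };
static const int N26dx[26] = {
  -1,-1,-1,0,0,0,1,1,1, -1,-1,-1,0,0,1,1,1, -1,-1,-1,0,0,0,1,1,1 };
static const int N26dz[26] = {
  -1,-1,-1,-1,-1,-1,-1,-1,-1, 0,0,0,0,0,0,0,0, 1,1,1,1,1,1,1,1,1 };

static bool fg_at(const std::vector<char>& m, const Grid& g,
                  int y, int x, int z) {
  if (!g.inside(y, x, z)) return false;
  return m[g.idx(y, x, z)] != 0;
}

static int count_fg26(const std::vector<char>& m, const Grid& g,
                      int y, int x, int z) {
  int c = 0;
  for (int k = 0; k < 26; ++k)
    if (fg_at(m, g, y + N26dy[k], x + N26dx[k], z + N26dz[k])) ++c;
  return c;
}

static bool simple3d(const std::vector<char>& m, const Grid& g,
                     int y, int x, int z) {
  // local 3x3x3 occupancy (foreground), center excluded
  char loc[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int i = (dz + 1) * 9 + (dx + 1) * 3 + (dy + 1);
        loc[i] = fg_at(m, g, y + dy, x + dx, z + dz) ? 1 : 0;
      }
  loc[13] = 0; // center removed

  // C*: 26-components of foreground among the 26 neighbors
  int compFg = 0;
  char seen[27] = {0};
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !loc[i] || seen[i]) continue;
    ++compFg;
    if (compFg > 1) return false;
    std::vector<int> st{ i };
    seen[i] = 1;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c / 9, cx = (c % 9) / 3, cy = c % 3;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            int zz = cz + dz, xx = cx + dx, yy = cy + dy;
            if (zz < 0 || zz > 2 || xx < 0 || xx > 2 || yy < 0 || yy > 2) continue;
            int j = zz * 9 + xx * 3 + yy;
            if (j == 13 || j == c || !loc[j] || seen[j]) continue;
            seen[j] = 1;
            st.push_back(j);
          }
    }
  }
  if (compFg != 1) return false;

  // Cbar: 6-components of background within N18 that touch a face neighbor
  // N18 = positions with 1 or 2 nonzero offsets
  char inN18[27], bg[27];
  for (int i = 0; i < 27; ++i) {
    int cz = i / 9 - 1, cx = (i % 9) / 3 - 1, cy = i % 3 - 1;
    int nz = (cz != 0) + (cx != 0) + (cy != 0);
    inN18[i] = (nz == 1 || nz == 2) ? 1 : 0;
    bg[i] = (inN18[i] && !loc[i]) ? 1 : 0;
  }
  int compBg = 0;
  char seenB[27] = {0};
  for (int i = 0; i < 27; ++i) {
    if (!bg[i] || seenB[i]) continue;
    // start a new component only from a face neighbor (6-adjacent to center)
    int cz = i / 9 - 1, cx = (i % 9) / 3 - 1, cy = i % 3 - 1;
    int nz = (cz != 0) + (cx != 0) + (cy != 0);
    if (nz != 1) continue;
    ++compBg;
    if (compBg > 1) return false;
    std::vector<int> st{ i };
    seenB[i] = 1;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int az = c / 9 - 1, ax = (c % 9) / 3 - 1, ay = c % 3 - 1;
      static const int f6[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
      for (int k = 0; k < 6; ++k) {
        int zz = az + f6[k][2], xx = ax + f6[k][1], yy = ay + f6[k][0];
        if (zz < -1 || zz > 1 || xx < -1 || xx > 1 || yy < -1 || yy > 1) continue;
        int j = (zz + 1) * 9 + (xx + 1) * 3 + (yy + 1);
        if (!bg[j] || seenB[j]) continue;
        seenB[j] = 1;
        st.push_back(j);
      }
    }
  }
  return compBg == 1;
}

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  R_xlen_t n = (R_xlen_t)g.ny * g.nx * g.nz;
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  // face directions: U(z-1), D(z+1), N(y-1), S(y+1), W(x-1), E(x+1)
  static const int fd[6][3] = {
    {0,0,-1},{0,0,1},{-1,0,0},{1,0,0},{0,-1,0},{0,1,0} };
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // two-phase as in thin2d: fix the candidate border set first, then
      // delete sequentially with topology re-checked on the evolving state
      cand.clear();
      for (int z = 0; z < g.nz; ++z)
        for (int x = 0; x < g.nx; ++x)
          for (int y = 0; y < g.ny; ++y) {
            R_xlen_t p = g.idx(y, x, z);
            if (!m[p]) continue;
            int yy = y + fd[d][0], xx = x + fd[d][1], zz = z + fd[d][2];
            if (!fg_at(m, g, yy, xx, zz)) cand.push_back(p);
          }
      for (R_xlen_t p : cand) {
        if (!m[p]) continue;
        int z = (int)(p / ((R_xlen_t)g.ny * g.nx));
        int r = (int)(p % ((R_xlen_t)g.ny * g.nx));
        int x = r / g.ny, y = r % g.ny;
        int cnt = count_fg26(m, g, y, x, z);
        if (cnt < 2) continue; // endpoint or isolated: keep
        if (simple3d(m, g, y, x, z)) {
          m[p] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}
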