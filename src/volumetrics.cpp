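#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Column-major linear index helpers for a (nx, ny, nz) grid.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing. sigma is in voxel units per axis; kernel
// truncated at 3 sigma and renormalised (so constant fields stay constant).
// ---------------------------------------------------------------------------
static void smooth_axis(std::vector<double>& a, std::vector<double>& tmp,
                        int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> w(2 * radius + 1);
  double s = 0;
  for (int t = -radius; t <= radius; ++t) {
    w[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += w[t + radius];
  }
  for (double& v : w) v /= s;
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx[3] = {i, j, k};
        double acc = 0, wn = 0;
        for (int t = -radius; t <= radius; ++t) {
          int p = idx[axis] + t;
          if (p < 0 || p >= len) continue;  // renormalised at edges
          int q[3] = {i, j, k};
          q[axis] = p;
          acc += w[t + radius] * a[lin(q[0], q[1], q[2], nx, ny)];
          wn += w[t + radius];
        }
        tmp[lin(i, j, k, nx, ny)] = acc / wn;
      }
  a.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector field, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(field.begin(), field.end()), tmp(a.size());
  for (int ax = 0; ax < 3; ++ax) smooth_axis(a, tmp, nx, ny, nz, ax, sigma);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), anisotropic:
// distances in physical units given per-axis sample spacing. Returns distance
// to the nearest background (mask == 0) voxel, in the same units as spacing.
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  // lower envelope of parabolas f[q] + (w*(x-q))^2
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e30;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? BIG : 0.0;

  int dims[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    int len = dims[axis];
    std::vector<double> f(len), g(len);
    for (int k = 0; k < (axis == 2 ? 1 : nz); ++k)
      for (int j = 0; j < (axis == 1 ? 1 : ny); ++j)
        for (int i = 0; i < (axis == 0 ? 1 : nx); ++i) {
          for (int p = 0; p < len; ++p) {
            int q[3] = {i, j, k};
            q[axis] = p;
            f[p] = d[lin(q[0], q[1], q[2], nx, ny)];
          }
          dt1d(f, g, len, spacing[axis]);
          for (int p = 0; p < len; ++p) {
            int q[3] = {i, j, k};
            q[axis] = p;
            d[lin(q[0], q[1], q[2], nx, ny)] = g[p];
          }
        }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a scalar field at a given level. Each grid cell is
// split into the six tetrahedra sharing the main diagonal; face diagonals are
// translation-invariant so the triangulation is consistent (watertight) across
// cells. Vertices deduplicated by the grid edge they sit on. Voxel (0,0,0)
// centre maps to the physical origin; vertices are returned in mm.
// ---------------------------------------------------------------------------
struct Key {
  uint64_t k;
  bool operator==(const Key& o) const { return k == o.k; }
};
struct KeyHash {
  size_t operator()(const Key& x) const { return std::hash<uint64_t>()(x.k); }
};

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dim,
                        NumericVector spacing, double level) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> f(field.begin(), field.end());
  // nudge exact-level samples so interpolation parameters stay in (0,1)
  double eps = 1e-7 * (std::fabs(level) > 0 ? std::fabs(level) : 1.0);
  for (double& v : f)
    if (std::fabs(v - level) < eps) v = level + eps;

  // six tetrahedra along paths 0 -> a -> b -> 7 through corner bit codes
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  std::unordered_map<Key, int, KeyHash> vmap;
  std::vector<double> verts;  // x,y,z triples
  std::vector<int> faces;     // 1-based vertex index triples

  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;

  auto edge_vertex = [&](R_xlen_t ia, R_xlen_t ib, const int* ca, const int* cb) {
    R_xlen_t lo = ia < ib ? ia : ib, hi = ia < ib ? ib : ia;
    Key key{(uint64_t)lo * (uint64_t)nvox + (uint64_t)hi};
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = f[ia], fb = f[ib];
    double t = (level - fa) / (fb - fa);
    double p[3];
    for (int d = 0; d < 3; ++d)
      p[d] = (ca[d] + t * (cb[d] - ca[d])) * spacing[d];
    verts.push_back(p[0]);
    verts.push_back(p[1]);
    verts.push_back(p[2]);
    int id = (int)(verts.size() / 3);  // 1-based
    vmap.emplace(key, id);
    return id;
  };

  auto add_tri = [&](int a, int b, int c, const double* inpt) {
    // orient so the normal points away from the inside reference point
    const double* A = &verts[3 * (a - 1)];
    const double* B = &verts[3 * (b - 1)];
    const double* C = &verts[3 * (c - 1)];
    double u[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double v[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
    double nrm[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                     u[0] * v[1] - u[1] * v[0]};
    double cen[3] = {(A[0] + B[0] + C[0]) / 3.0 - inpt[0],
                     (A[1] + B[1] + C[1]) / 3.0 - inpt[1],
                     (A[2] + B[2] + C[2]) / 3.0 - inpt[2]};
    double dot = nrm[0] * cen[0] + nrm[1] * cen[1] + nrm[2] * cen[2];
    if (dot < 0) std::swap(b, c);
    faces.push_back(a);
    faces.push_back(b);
    faces.push_back(c);
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // corner coordinates and linear indices, bit code dx + 2dy + 4dz
        int cc[8][3];
        R_xlen_t ci[8];
        double cf[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cc[c][0] = i + (c & 1);
          cc[c][1] = j + ((c >> 1) & 1);
          cc[c][2] = k + ((c >> 2) & 1);
          ci[c] = lin(cc[c][0], cc[c][1], cc[c][2], nx, ny);
          cf[c] = f[ci[c]];
          (cf[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int in[4], nin = 0;
          for (int c = 0; c < 4; ++c)
            if (cf[T[c]] > level) in[nin++] = c;
          if (nin == 0 || nin == 4) continue;
          double inpt[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d)
              inpt[d] += cc[T[in[c]]][d] * spacing[d] / nin;
          if (nin == 1 || nin == 3) {
            int a = (nin == 1) ? in[0] : -1;
            if (nin == 3) {  // find the single outside corner's complement set
              bool isin[4] = {false, false, false, false};
              for (int c = 0; c < nin; ++c) isin[in[c]] = true;
              for (int c = 0; c < 4; ++c)
                if (!isin[c]) a = c;
              // a is the outside corner; triangle between it and the 3 inside
            }
            int others[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != a) others[m++] = c;
            int v1 = edge_vertex(ci[T[a]], ci[T[others[0]]], cc[T[a]], cc[T[others[0]]]);
            int v2 = edge_vertex(ci[T[a]], ci[T[others[1]]], cc[T[a]], cc[T[others[1]]]);
            int v3 = edge_vertex(ci[T[a]], ci[T[others[2]]], cc[T[a]], cc[T[others[2]]]);
            add_tri(v1, v2, v3, inpt);
          } else {  // nin == 2: quad split into two triangles
            int a = in[0], b = in[1];
            int out[2], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != a && c != b) out[m++] = c;
            int vac = edge_vertex(ci[T[a]], ci[T[out[0]]], cc[T[a]], cc[T[out[0]]]);
            int vad = edge_vertex(ci[T[a]], ci[T[out[1]]], cc[T[a]], cc[T[out[1]]]);
            int vbc = edge_vertex(ci[T[b]], ci[T[out[0]]], cc[T[b]], cc[T[out[0]]]);
            int vbd = edge_vertex(ci[T[b]], ci[T[out[1]]], cc[T[b]], cc[T[out[1]]]);
            add_tri(vac, vad, vbd, inpt);
            add_tri(vac, vbd, vbc, inpt);
          }
        }
      }

  int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) V(v, d) = verts[3 * v + d];
  IntegerMatrix F(nf, 3);
  for (int t = 0; t < nf; ++t)
    for (int d = 0; d < 3; ++d) F(t, d) = faces[3 * t + d];
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Plateau-aware regional maxima of a field restricted to a mask
// (26-connectivity); each maximal plateau becomes one marker label.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_marker_labels(NumericVector field, IntegerVector mask,
                                IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> cand(n, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = lin(i, j, k, nx, ny);
        if (!mask[idx]) continue;
        double v = field[idx];
        bool ok = true;
        for (int dk = -1; dk <= 1 && ok; ++dk)
          for (int dj = -1; dj <= 1 && ok; ++dj)
            for (int di = -1; di <= 1 && ok; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              R_xlen_t nb = lin(ii, jj, kk, nx, ny);
              if (mask[nb] && field[nb] > v) ok = false;
            }
        cand[idx] = ok ? 1 : 0;
      }
  // label connected plateaus of candidates (26-connectivity)
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = lin(i, j, k, nx, ny);
        if (!cand[idx] || lab[idx]) continue;
        ++next;
        lab[idx] = next;
        stack.clear();
        stack.push_back(idx);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          int ci = (int)(cur % nx), cj = (int)((cur / nx) % ny), ck = (int)(cur / ((R_xlen_t)nx * ny));
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (!di && !dj && !dk) continue;
                int ii = ci + di, jj = cj + dj, kk = ck + dk;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                  continue;
                R_xlen_t nb = lin(ii, jj, kk, nx, ny);
                if (cand[nb] && !lab[nb]) {
                  lab[nb] = next;
                  stack.push_back(nb);
                }
              }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Marker-based watershed by priority flooding: grow markers outward in order
// of decreasing field value (6-connectivity), deterministic FIFO tie-break.
// Every mask voxel receives a label.
// ---------------------------------------------------------------------------
struct QItem {
  double pri;
  uint64_t order;
  R_xlen_t idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.pri != b.pri) return a.pri < b.pri;  // max-heap on field value
    return a.order > b.order;                  // FIFO on ties
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector field, IntegerVector mask,
                            IntegerVector markers, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  uint64_t order = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push({field[i], order++, i});
    }
  const int off[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                         {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    R_xlen_t cur = it.idx;
    int ci = (int)(cur % nx), cj = (int)((cur / nx) % ny), ck = (int)(cur / ((R_xlen_t)nx * ny));
    for (int d = 0; d < 6; ++d) {
      int ii = ci + off[d][0], jj = cj + off[d][1], kk = ck + off[d][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t nb = lin(ii, jj, kk, nx, ny);
      if (mask[nb] && lab[nb] == 0) {
        lab[nb] = lab[cur];
        pq.push({field[nb], order++, nb});
      }
    }
  }
  return lab;
}
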