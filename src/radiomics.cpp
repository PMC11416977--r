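#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D arrays are passed as flat vectors with R's column-major layout:
// linear index = x + d1 * (y + d2 * z), 0-based.

static inline int reflect_index(int m, int n) {
  // half-sample symmetric boundary extension (..., x1, x0 | x0, x1, ...)
  while (m < 0 || m >= n) {
    if (m < 0) m = -m - 1;
    if (m >= n) m = 2 * n - 1 - m;
  }
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector arr, NumericVector kernel, int axis) {
  IntegerVector dim = arr.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int L = kernel.size();
  int off = (L - 1) / 2;
  NumericVector out(arr.size());
  out.attr("dim") = dim;
  int n = dim[axis - 1];
  // iterate over all lines along `axis`
  for (int z = 0; z < (axis == 3 ? 1 : d3); ++z) {
    for (int y = 0; y < (axis == 2 ? 1 : d2); ++y) {
      for (int x = 0; x < (axis == 1 ? 1 : d1); ++x) {
        // base index and stride of the line
        long base, stride;
        if (axis == 1)      { base = 0 + (long)d1 * (y + (long)d2 * z); stride = 1; }
        else if (axis == 2) { base = x + (long)d1 * (0 + (long)d2 * z); stride = d1; }
        else                { base = x + (long)d1 * (y + (long)d2 * 0); stride = (long)d1 * d2; }
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int k = 0; k < L; ++k) {
            int m = reflect_index(i + k - off, n);
            acc += kernel[k] * arr[base + stride * m];
          }
          out[base + stride * i] = acc;
        }
      }
    }
  }
  return out;
}

static const int NBR26[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},{-1,1,-1},{-1,1,0},{-1,1,1},
  {0,-1,-1},{0,-1,0},{0,-1,1},{0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},
  {1,-1,-1},{1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},{1,1,-1},{1,1,0},{1,1,1}
};

static inline int lvl_at(const IntegerVector &lv, int d1, int d2, int d3,
                         int x, int y, int z) {
  if (x < 0 || x >= d1 || y < 0 || y >= d2 || z < 0 || z >= d3) return NA_INTEGER;
  return lv[x + (long)d1 * (y + (long)d2 * z)];
}

// Symmetric co-occurrence counts per direction: ng x ng x ndir
// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector levels, int ng, IntegerMatrix offsets) {
  IntegerVector dim = levels.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int ndir = offsets.nrow();
  NumericVector counts((long)ng * ng * ndir);
  counts.attr("dim") = IntegerVector::create(ng, ng, ndir);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        int li = lvl_at(levels, d1, d2, d3, x, y, z);
        if (li == NA_INTEGER) continue;
        for (int d = 0; d < ndir; ++d) {
          int lj = lvl_at(levels, d1, d2, d3,
                          x + offsets(d, 0), y + offsets(d, 1), z + offsets(d, 2));
          if (lj == NA_INTEGER) continue;
          counts[(li - 1) + (long)ng * ((lj - 1) + (long)ng * d)] += 1.0;
          counts[(lj - 1) + (long)ng * ((li - 1) + (long)ng * d)] += 1.0;
        }
      }
  return counts;
}

// Run-length counts per direction: ng x maxlen x ndir
// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector levels, int ng, IntegerMatrix offsets) {
  IntegerVector dim = levels.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int ndir = offsets.nrow();
  int maxlen = std::max(d1, std::max(d2, d3));
  NumericVector counts((long)ng * maxlen * ndir);
  counts.attr("dim") = IntegerVector::create(ng, maxlen, ndir);
  for (int d = 0; d < ndir; ++d) {
    int dx = offsets(d, 0), dy = offsets(d, 1), dz = offsets(d, 2);
    for (int z = 0; z < d3; ++z)
      for (int y = 0; y < d2; ++y)
        for (int x = 0; x < d1; ++x) {
          int li = lvl_at(levels, d1, d2, d3, x, y, z);
          if (li == NA_INTEGER) continue;
          // run start: predecessor absent or different level
          int lp = lvl_at(levels, d1, d2, d3, x - dx, y - dy, z - dz);
          if (lp == li) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (lvl_at(levels, d1, d2, d3, cx, cy, cz) == li) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          counts[(li - 1) + (long)ng * ((len - 1) + (long)maxlen * d)] += 1.0;
        }
  }
  return counts;
}

// 26-connected zones of equal gray level; returns nzones x 2 matrix (level, size)
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels) {
  IntegerVector dim = levels.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  long n = (long)d1 * d2 * d3;
  std::vector<char> visited(n, 0);
  std::vector<int> zl, zs;
  std::vector<long> stack;
  for (long v = 0; v < n; ++v) {
    if (visited[v] || levels[v] == NA_INTEGER) continue;
    int lev = levels[v];
    int size = 0;
    stack.clear();
    stack.push_back(v);
    visited[v] = 1;
    while (!stack.empty()) {
      long c = stack.back(); stack.pop_back();
      ++size;
      int cx = (int)(c % d1);
      int cy = (int)((c / d1) % d2);
      int cz = (int)(c / ((long)d1 * d2));
      for (int k = 0; k < 26; ++k) {
        int nx = cx + NBR26[k][0], ny = cy + NBR26[k][1], nz = cz + NBR26[k][2];
        if (nx < 0 || nx >= d1 || ny < 0 || ny >= d2 || nz < 0 || nz >= d3) continue;
        long w = nx + (long)d1 * (ny + (long)d2 * nz);
        if (!visited[w] && levels[w] == lev) {
          visited[w] = 1;
          stack.push_back(w);
        }
      }
    }
    zl.push_back(lev); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) { out(i, 0) = zl[i]; out(i, 1) = zs[i]; }
  return out;
}

// Neighborhood gray-tone difference sums: ng x 2 matrix (n_i, s_i).
// Only voxels with at least one in-ROI 26-neighbor contribute.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, int ng) {
  IntegerVector dim = levels.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericMatrix out(ng, 2);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        int li = lvl_at(levels, d1, d2, d3, x, y, z);
        if (li == NA_INTEGER) continue;
        double s = 0.0; int cnt = 0;
        for (int k = 0; k < 26; ++k) {
          int lj = lvl_at(levels, d1, d2, d3,
                          x + NBR26[k][0], y + NBR26[k][1], z + NBR26[k][2]);
          if (lj == NA_INTEGER) continue;
          s += lj; ++cnt;
        }
        if (cnt == 0) continue;
        out(li - 1, 0) += 1.0;
        out(li - 1, 1) += std::fabs((double)li - s / cnt);
      }
  return out;
}

// Dependence counts: ng x 27 matrix (dependence 0..26 neighbors within alpha)
// [[Rcpp::export]]
NumericMatrix cpp_gldm_counts(IntegerVector levels, int ng, int alpha) {
  IntegerVector dim = levels.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        int li = lvl_at(levels, d1, d2, d3, x, y, z);
        if (li == NA_INTEGER) continue;
        int dep = 0;
        for (int k = 0; k < 26; ++k) {
          int lj = lvl_at(levels, d1, d2, d3,
                          x + NBR26[k][0], y + NBR26[k][1], z + NBR26[k][2]);
          if (lj == NA_INTEGER) continue;
          if (std::abs(lj - li) <= alpha) ++dep;
        }
        out(li - 1, dep) += 1.0;
      }
  return out;
}

// ---- marching tetrahedra over a padded binary mask -------------------------
// Cube corners coded k = x + 2y + 4z; six tetrahedra share diagonal 0-7.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

struct V3 { double x, y, z; };
static inline V3 vsub(V3 a, V3 b) { V3 r = {a.x-b.x, a.y-b.y, a.z-b.z}; return r; }
static inline V3 vcross(V3 a, V3 b) {
  V3 r = {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x}; return r;
}
static inline double vdot(V3 a, V3 b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

// linear interpolation to the level crossing on edge a-b
static inline V3 vcut(V3 pa, V3 pb, double va, double vb, double level) {
  double t = (vb == va) ? 0.5 : (level - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  V3 r = {pa.x + t * (pb.x - pa.x), pa.y + t * (pb.y - pa.y),
          pa.z + t * (pb.z - pa.z)};
  return r;
}

// Marching tetrahedra over the `level` iso-surface of a scalar field.
// The field must already be zero-padded so the surface is closed.
// Returns list(area, volume, vertices); coordinates are index * spacing.
// [[Rcpp::export]]
List cpp_mesh_field(NumericVector field, NumericVector spacing,
                    double level) {
  IntegerVector dim = field.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  double area = 0.0, volume = 0.0;
  std::vector<double> verts;
  for (int z = 0; z < d3 - 1; ++z)
    for (int y = 0; y < d2 - 1; ++y)
      for (int x = 0; x < d1 - 1; ++x) {
        double val[8];
        V3 pos[8];
        int insum = 0;
        for (int k = 0; k < 8; ++k) {
          int cx = x + (k & 1), cy = y + ((k >> 1) & 1), cz = z + ((k >> 2) & 1);
          val[k] = field[cx + (long)d1 * (cy + (long)d2 * cz)];
          pos[k].x = cx * spacing[0];
          pos[k].y = cy * spacing[1];
          pos[k].z = cz * spacing[2];
          insum += (val[k] > level);
        }
        if (insum == 0 || insum == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int nin = 0, nout = 0, inl[4], outl[4];
          for (int k = 0; k < 4; ++k) {
            if (val[vi[k]] > level) inl[nin++] = vi[k];
            else outl[nout++] = vi[k];
          }
          if (nin == 0 || nin == 4) continue;
          V3 tri[2][3];
          int ntri = 0;
          if (nin == 1) {
            tri[0][0] = vcut(pos[inl[0]], pos[outl[0]], val[inl[0]], val[outl[0]], level);
            tri[0][1] = vcut(pos[inl[0]], pos[outl[1]], val[inl[0]], val[outl[1]], level);
            tri[0][2] = vcut(pos[inl[0]], pos[outl[2]], val[inl[0]], val[outl[2]], level);
            ntri = 1;
          } else if (nin == 3) {
            tri[0][0] = vcut(pos[outl[0]], pos[inl[0]], val[outl[0]], val[inl[0]], level);
            tri[0][1] = vcut(pos[outl[0]], pos[inl[1]], val[outl[0]], val[inl[1]], level);
            tri[0][2] = vcut(pos[outl[0]], pos[inl[2]], val[outl[0]], val[inl[2]], level);
            ntri = 1;
          } else { // nin == 2: quad across the four cut edges
            V3 q0 = vcut(pos[inl[0]], pos[outl[0]], val[inl[0]], val[outl[0]], level);
            V3 q1 = vcut(pos[inl[0]], pos[outl[1]], val[inl[0]], val[outl[1]], level);
            V3 q2 = vcut(pos[inl[1]], pos[outl[1]], val[inl[1]], val[outl[1]], level);
            V3 q3 = vcut(pos[inl[1]], pos[outl[0]], val[inl[1]], val[outl[0]], level);
            tri[0][0] = q0; tri[0][1] = q1; tri[0][2] = q2;
            tri[1][0] = q0; tri[1][1] = q2; tri[1][2] = q3;
            ntri = 2;
          }
          // inside centroid for orientation
          V3 cin = {0, 0, 0};
          for (int k = 0; k < nin; ++k) {
            cin.x += pos[inl[k]].x; cin.y += pos[inl[k]].y; cin.z += pos[inl[k]].z;
          }
          cin.x /= nin; cin.y /= nin; cin.z /= nin;
          for (int q = 0; q < ntri; ++q) {
            V3 a = tri[q][0], b = tri[q][1], c = tri[q][2];
            V3 nrm = vcross(vsub(b, a), vsub(c, a));
            V3 cen = {(a.x+b.x+c.x)/3, (a.y+b.y+c.y)/3, (a.z+b.z+c.z)/3};
            if (vdot(nrm, vsub(cen, cin)) < 0) { V3 tmp = b; b = c; c = tmp;
              nrm = vcross(vsub(b, a), vsub(c, a)); }
            area += 0.5 * std::sqrt(vdot(nrm, nrm));
            volume += vdot(a, vcross(b, c)) / 6.0;
            verts.push_back(a.x); verts.push_back(a.y); verts.push_back(a.z);
            verts.push_back(b.x); verts.push_back(b.y); verts.push_back(b.z);
            verts.push_back(c.x); verts.push_back(c.y); verts.push_back(c.z);
          }
        }
      }
  size_t nv = verts.size() / 3;
  NumericMatrix vm(nv, 3);
  for (size_t i = 0; i < nv; ++i) {
    vm(i, 0) = verts[3 * i]; vm(i, 1) = verts[3 * i + 1]; vm(i, 2) = verts[3 * i + 2];
  }
  return List::create(_["area"] = area, _["volume"] = std::fabs(volume),
                      _["vertices"] = vm);
}

// max pairwise distances: full 3D and the three axis-dropped projections
// returns c(max3d, drop_axis1, drop_axis2, drop_axis3)
// [[Rcpp::export]]
NumericVector cpp_max_diameters(NumericMatrix verts) {
  int n = verts.nrow();
  double m3 = 0, m1 = 0, m2 = 0, mz = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = verts(i, 0) - verts(j, 0);
      double dy = verts(i, 1) - verts(j, 1);
      double dz = verts(i, 2) - verts(j, 2);
      double a = dy * dy + dz * dz;   // drop axis 1
      double b = dx * dx + dz * dz;   // drop axis 2
      double c = dx * dx + dy * dy;   // drop axis 3
      double d = dx * dx + a;
      if (d > m3) m3 = d;
      if (a > m1) m1 = a;
      if (b > m2) m2 = b;
      if (c > mz) mz = c;
    }
  return NumericVector::create(std::sqrt(m3), std::sqrt(m1),
                               std::sqrt(m2), std::sqrt(mz));
}
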