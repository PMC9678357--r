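#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3D topology-preserving thinning.
//
// A foreground voxel is "simple" (removable without changing topology) under
// the (26, 6) connectivity pair iff
//   (a) the foreground of its 26-neighborhood forms exactly one 26-connected
//       component, and
//   (b) the background of its 18-neighborhood contains exactly one
//       6-connected component that is 6-adjacent to the voxel.
// Simple points are removed sequentially (each removal re-tested on the
// current image), so topology preservation holds by construction; six
// directional subiterations keep the result centered. Voxels with at most one
// foreground 26-neighbor are curve endpoints and are never removed, so tubes
// reduce to centerlines rather than points.
// ---------------------------------------------------------------------------

namespace {

// neighborhood cell index: (dx+1) + 3*(dy+1) + 9*(dz+1), center = 13
inline int cellIndex(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

struct Vol {
  const std::vector<unsigned char>& v;
  int nx, ny, nz;
  Vol(const std::vector<unsigned char>& v_, int nx_, int ny_, int nz_)
    : v(v_), nx(nx_), ny(ny_), nz(nz_) {}
  inline int at(long x, long y, long z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return v[x + (long)nx * (y + (long)ny * z)];
  }
};

inline void neighborhood(const Vol& g, long x, long y, long z, int nb[27]) {
  int i = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++i)
        nb[i] = g.at(x + dx, y + dy, z + dz);
}

inline int countForeground(const int nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++n;
  return n;
}

// decode cell index back to offsets
inline void cellOffset(int i, int& dx, int& dy, int& dz) {
  dx = i % 3 - 1;
  dy = (i / 3) % 3 - 1;
  dz = i / 9 - 1;
}

// number of 26-connected foreground components in N26 (center excluded)
int fgComponents26(const int nb[27]) {
  int label[27];
  for (int i = 0; i < 27; ++i) label[i] = 0;
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || label[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    label[s] = ncomp;
    while (top) {
      int c = stack[--top];
      int cx, cy, cz;
      cellOffset(c, cx, cy, cz);
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || !nb[j] || label[j]) continue;
        int jx, jy, jz;
        cellOffset(j, jx, jy, jz);
        if (std::abs(jx - cx) <= 1 && std::abs(jy - cy) <= 1 &&
            std::abs(jz - cz) <= 1) {
          label[j] = ncomp;
          stack[top++] = j;
        }
      }
    }
  }
  return ncomp;
}

// number of 6-connected background components within the 18-neighborhood
// that touch the center by a face
int bgComponents6(const int nb[27]) {
  // mark cells belonging to the 18-neighborhood (squared offset <= 2)
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int dx, dy, dz;
    cellOffset(i, dx, dy, dz);
    in18[i] = (i != 13) && (dx * dx + dy * dy + dz * dz <= 2);
  }
  int label[27];
  for (int i = 0; i < 27; ++i) label[i] = 0;
  int ncomp = 0;
  int stack[27];
  static const int face[6] = {cellIndex(-1, 0, 0), cellIndex(1, 0, 0),
                              cellIndex(0, -1, 0), cellIndex(0, 1, 0),
                              cellIndex(0, 0, -1), cellIndex(0, 0, 1)};
  for (int f = 0; f < 6; ++f) {
    int s = face[f];
    if (nb[s] || label[s]) continue;  // foreground or already labeled
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    label[s] = ncomp;
    while (top) {
      int c = stack[--top];
      int cx, cy, cz;
      cellOffset(c, cx, cy, cz);
      for (int j = 0; j < 27; ++j) {
        if (!in18[j] || nb[j] || label[j]) continue;
        int jx, jy, jz;
        cellOffset(j, jx, jy, jz);
        if (std::abs(jx - cx) + std::abs(jy - cy) + std::abs(jz - cz) == 1) {
          label[j] = ncomp;
          stack[top++] = j;
        }
      }
    }
  }
  return ncomp;
}

inline bool isSimple(const int nb[27]) {
  return fgComponents26(nb) == 1 && bgComponents6(nb) == 1;
}

}  // namespace

// [[Rcpp::export(name = ".cppThin3d")]]
IntegerVector cppThin3d(IntegerVector img, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  std::vector<unsigned char> v(n);
  for (long i = 0; i < n; ++i) v[i] = img[i] != 0;
  Vol g(v, nx, ny, nz);

  static const int dirs[6][3] = {{0, 0, -1}, {0, 0, 1}, {0, -1, 0},
                                 {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};
  int nb[27];
  std::vector<long> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (long z = 0; z < nz; ++z)
        for (long y = 0; y < ny; ++y)
          for (long x = 0; x < nx; ++x) {
            long i = x + (long)nx * (y + (long)ny * z);
            if (!v[i]) continue;
            if (g.at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2]))
              continue;  // not a border point in this direction
            neighborhood(g, x, y, z, nb);
            if (countForeground(nb) <= 1) continue;  // endpoint / isolated
            if (isSimple(nb)) cand.push_back(i);
          }
      // sequential removal with re-check keeps every deletion simple
      for (size_t c = 0; c < cand.size(); ++c) {
        long i = cand[c];
        long x = i % nx, y = (i / nx) % ny, z = i / ((long)nx * ny);
        neighborhood(g, x, y, z, nb);
        if (countForeground(nb) <= 1) continue;
        if (isSimple(nb)) {
          v[i] = 0;
          changed = true;
        }
      }
    }
  }
  IntegerVector out(n);
  for (long i = 0; i < n; ++i) out[i] = v[i];
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope algorithm, per-axis sampling
// distances). Input: nonzero = foreground; output: squared distance from each
// voxel to the nearest zero voxel, in physical units.
// ---------------------------------------------------------------------------

namespace {

const double kInf = std::numeric_limits<double>::infinity();

// 1D squared distance transform with sample spacing s; f must be finite
// (callers cap unreached sites with a large sentinel)
void dt1d(std::vector<double>& f, std::vector<double>& d, std::vector<int>& v,
          std::vector<double>& zb, int n, double s) {
  int k = 0;
  v[0] = 0;
  zb[0] = -kInf;
  zb[1] = kInf;
  for (int q = 1; q < n; ++q) {
    double sq = s * q;
    double inter;
    while (true) {
      double sv = s * v[k];
      inter = (f[q] + sq * sq - f[v[k]] - sv * sv) / (2 * sq - 2 * sv);
      if (inter <= zb[k] && k > 0) {
        --k;
        continue;
      }
      break;
    }
    if (inter <= zb[k]) {  // k == 0 and still dominated: replace
      v[0] = q;
      zb[0] = -kInf;
      zb[1] = kInf;
    } else {
      ++k;
      v[k] = q;
      zb[k] = inter;
      zb[k + 1] = kInf;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = s * q;
    while (zb[k + 1] < sq) ++k;
    double sv = s * v[k];
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

}  // namespace

// [[Rcpp::export(name = ".cppEdt3d")]]
NumericVector cppEdt3d(IntegerVector bin, IntegerVector dim,
                       NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  // finite sentinel larger than any achievable squared distance
  const double ex = nx * spacing[0], ey = ny * spacing[1], ez = nz * spacing[2];
  const double big = 4.0 * (ex * ex + ey * ey + ez * ez) + 1.0;
  std::vector<double> D(n);
  for (long i = 0; i < n; ++i) D[i] = bin[i] ? big : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // x axis
  for (long z = 0; z < nz; ++z)
    for (long y = 0; y < ny; ++y) {
      long base = (long)nx * (y + (long)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = D[base + x];
      dt1d(f, d, v, zb, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) D[base + x] = d[x];
    }
  // y axis
  for (long z = 0; z < nz; ++z)
    for (long x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = D[x + (long)nx * (y + (long)ny * z)];
      dt1d(f, d, v, zb, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) D[x + (long)nx * (y + (long)ny * z)] = d[y];
    }
  // z axis
  for (long y = 0; y < ny; ++y)
    for (long x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = D[x + (long)nx * (y + (long)ny * z)];
      dt1d(f, d, v, zb, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) D[x + (long)nx * (y + (long)ny * z)] = d[z];
    }

  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = D[i];
  out.attr("dim") = dim;
  return out;
}
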