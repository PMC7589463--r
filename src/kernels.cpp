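// Low-level 3D grid kernels. All arrays are column-major (R layout),
// dims = (nx, ny, nz), linear index i + nx*(j + ny*k).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// Distance of every voxel to the nearest zero voxel of `mask`, in voxel units.
// Voxels outside the grid are NOT treated as background.
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  const double INF = 1e18;
  NumericVector out(n);
  for (long long t = 0; t < n; ++t) out[t] = mask[t] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  // axis x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = out[idx3(i, j, k, nx, ny)];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) out[idx3(i, j, k, nx, ny)] = d[i];
    }
  // axis y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = out[idx3(i, j, k, nx, ny)];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) out[idx3(i, j, k, nx, ny)] = d[j];
    }
  // axis z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = out[idx3(i, j, k, nx, ny)];
      dt1d(f, d, nz);
      for (int k = 0; k < nz; ++k) out[idx3(i, j, k, nx, ny)] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// City-block (6-connected) distance inside a mask; border mask voxels get 1,
// out-of-grid counts as background. Exact via two raster sweeps.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_manhattan_dist")]]
IntegerVector cpp_manhattan_dist(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  const int INF = INT_MAX / 4;
  IntegerVector d(n);
  for (long long t = 0; t < n; ++t) d[t] = mask[t] ? INF : 0;
  // forward
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long t = idx3(i, j, k, nx, ny);
        if (d[t] == 0) continue;
        int best = INF;
        best = std::min(best, (i > 0 ? d[idx3(i - 1, j, k, nx, ny)] : 0) + 1);
        best = std::min(best, (j > 0 ? d[idx3(i, j - 1, k, nx, ny)] : 0) + 1);
        best = std::min(best, (k > 0 ? d[idx3(i, j, k - 1, nx, ny)] : 0) + 1);
        d[t] = std::min((int)d[t], best);
      }
  // backward
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        long long t = idx3(i, j, k, nx, ny);
        if (d[t] == 0) continue;
        int best = (int)d[t];
        best = std::min(best, (i < nx - 1 ? d[idx3(i + 1, j, k, nx, ny)] : 0) + 1);
        best = std::min(best, (j < ny - 1 ? d[idx3(i, j + 1, k, nx, ny)] : 0) + 1);
        best = std::min(best, (k < nz - 1 ? d[idx3(i, j, k + 1, nx, ny)] : 0) + 1);
        d[t] = best;
      }
  return d;
}

// ---------------------------------------------------------------------------
// Separable correlation along one axis (axis in 1..3), symmetric padding
// (edge voxel repeated in mirror: a b c | c b a). origin is the kernel tap
// aligned with the output voxel (0-based).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_conv_axis")]]
NumericVector cpp_conv_axis(NumericVector x, IntegerVector dims,
                            NumericVector kernel, int axis, int origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int L = kernel.size();
  long long n = (long long)nx * ny * nz;
  NumericVector out(n);
  int nA = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  std::vector<double> line(nA), res(nA);
  auto reflect = [&](int p) {
    // symmetric half-sample boundary: ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
    while (p < 0 || p >= nA) {
      if (p < 0) p = -p - 1;
      if (p >= nA) p = 2 * nA - p - 1;
    }
    return p;
  };
  int outer1 = (axis == 1) ? ny : nx;
  int outer2 = (axis == 3) ? ny : nz;
  for (int b = 0; b < outer2; ++b)
    for (int a = 0; a < outer1; ++a) {
      for (int p = 0; p < nA; ++p) {
        int i, j, k;
        if (axis == 1) { i = p; j = a; k = b; }
        else if (axis == 2) { i = a; j = p; k = b; }
        else { i = a; j = b; k = p; }
        line[p] = x[idx3(i, j, k, nx, ny)];
      }
      for (int p = 0; p < nA; ++p) {
        double s = 0.0;
        for (int t = 0; t < L; ++t) s += kernel[t] * line[reflect(p + t - origin)];
        res[p] = s;
      }
      for (int p = 0; p < nA; ++p) {
        int i, j, k;
        if (axis == 1) { i = p; j = a; k = b; }
        else if (axis == 2) { i = a; j = p; k = b; }
        else { i = a; j = b; k = p; }
        out[idx3(i, j, k, nx, ny)] = res[p];
      }
    }
  return out;
}

// 13 unique 3D directions (positive half-space, lexicographic).
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// ---------------------------------------------------------------------------
// GLCM: symmetrised co-occurrence counts at Chebyshev distance 1, one
// Ng x Ng matrix per direction. levels: 1..Ng inside ROI, 0 outside.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_glcm")]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(Dimension(ng, ng, 13));
  for (int dIdx = 0; dIdx < 13; ++dIdx) {
    int dx = DIRS[dIdx][0], dy = DIRS[dIdx][1], dz = DIRS[dIdx][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = levels[idx3(i, j, k, nx, ny)];
          if (a == 0) continue;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
            continue;
          int b = levels[idx3(i2, j2, k2, nx, ny)];
          if (b == 0) continue;
          out[(a - 1) + ng * (b - 1) + (long long)ng * ng * dIdx] += 1.0;
          out[(b - 1) + ng * (a - 1) + (long long)ng * ng * dIdx] += 1.0;
        }
  }
  return out;
}

// ---------------------------------------------------------------------------
// GLRLM: run-length counts per direction. Returns Ng x Lmax x 13.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_glrlm")]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int lmax = std::max(nx, std::max(ny, nz));
  NumericVector out(Dimension(ng, lmax, 13));
  for (int dIdx = 0; dIdx < 13; ++dIdx) {
    int dx = DIRS[dIdx][0], dy = DIRS[dIdx][1], dz = DIRS[dIdx][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = levels[idx3(i, j, k, nx, ny)];
          if (a == 0) continue;
          // run starts here only if predecessor is absent or different
          int ip = i - dx, jp = j - dy, kp = k - dz;
          if (ip >= 0 && ip < nx && jp >= 0 && jp < ny && kp >= 0 && kp < nz &&
              levels[idx3(ip, jp, kp, nx, ny)] == a)
            continue;
          int len = 1;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          while (i2 >= 0 && i2 < nx && j2 >= 0 && j2 < ny && k2 >= 0 &&
                 k2 < nz && levels[idx3(i2, j2, k2, nx, ny)] == a) {
            ++len;
            i2 += dx; j2 += dy; k2 += dz;
          }
          out[(a - 1) + ng * (len - 1) + (long long)ng * lmax * dIdx] += 1.0;
        }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected zones of equal grey level. Returns matrix with one row per
// zone: (level, size, min city-block distance of zone to ROI border).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_zones")]]
IntegerMatrix cpp_zones(IntegerVector levels, IntegerVector dims,
                        IntegerVector dist) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, zd;
  std::vector<long long> stack;
  for (long long t0 = 0; t0 < n; ++t0) {
    if (seen[t0] || levels[t0] == 0) continue;
    int lev = levels[t0];
    int size = 0, dmin = INT_MAX;
    stack.clear();
    stack.push_back(t0);
    seen[t0] = 1;
    while (!stack.empty()) {
      long long t = stack.back();
      stack.pop_back();
      ++size;
      if (dist[t] < dmin) dmin = dist[t];
      int k = (int)(t / ((long long)nx * ny));
      int rem = (int)(t % ((long long)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int i2 = i + di, j2 = j + dj, k2 = k + dk;
            if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
              continue;
            long long t2 = idx3(i2, j2, k2, nx, ny);
            if (!seen[t2] && levels[t2] == lev) {
              seen[t2] = 1;
              stack.push_back(t2);
            }
          }
    }
    zl.push_back(lev);
    zs.push_back(size);
    zd.push_back(dmin);
  }
  IntegerMatrix out(zl.size(), 3);
  for (size_t r = 0; r < zl.size(); ++r) {
    out(r, 0) = zl[r];
    out(r, 1) = zs[r];
    out(r, 2) = zd[r];
  }
  return out;
}

// ---------------------------------------------------------------------------
// NGTDM accumulation: per level, count of valid voxels and sum |i - mean of
// in-ROI 26-neighbours|. Voxels need >= 1 in-ROI neighbour.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_ngtdm")]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2); // (n_i, s_i)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = levels[idx3(i, j, k, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 ||
                  k2 >= nz)
                continue;
              int b = levels[idx3(i2, j2, k2, nx, ny)];
              if (b > 0) { sum += b; ++cnt; }
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs(a - sum / cnt);
      }
  return out;
}

// ---------------------------------------------------------------------------
// NGLDM counts: dependence count j = number of 26-neighbours with
// |level difference| <= alpha. Returns Ng x 27 (columns j = 0..26).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_ngldm")]]
NumericMatrix cpp_ngldm(IntegerVector levels, IntegerVector dims, int ng,
                        int alpha) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = levels[idx3(i, j, k, nx, ny)];
        if (a == 0) continue;
        int dep = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 ||
                  k2 >= nz)
                continue;
              int b = levels[idx3(i2, j2, k2, nx, ny)];
              if (b > 0 && std::abs(b - a) <= alpha) ++dep;
            }
        out(a - 1, dep) += 1.0;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Local & global intensity peaks: mean intensity in a 1 cm^3 sphere
// (radius_mm) centred at each ROI voxel; sphere voxels outside the grid are
// excluded from the mean. Returns (local_peak, global_peak).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_peaks")]]
NumericVector cpp_peaks(NumericVector values, IntegerVector mask,
                        IntegerVector dims, double radius_mm,
                        double spacing_mm) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int r = (int)std::floor(radius_mm / spacing_mm);
  std::vector<int> offs;
  for (int dk = -r; dk <= r; ++dk)
    for (int dj = -r; dj <= r; ++dj)
      for (int di = -r; di <= r; ++di) {
        double d = spacing_mm * std::sqrt((double)(di * di + dj * dj + dk * dk));
        if (d <= radius_mm + 1e-12) {
          offs.push_back(di); offs.push_back(dj); offs.push_back(dk);
        }
      }
  int noff = offs.size() / 3;
  std::vector<long long> lin(noff);
  for (int o = 0; o < noff; ++o)
    lin[o] = offs[3 * o] + (long long)nx * (offs[3 * o + 1] +
             (long long)ny * offs[3 * o + 2]);
  double gmax = -std::numeric_limits<double>::infinity();
  double vmax = -std::numeric_limits<double>::infinity();
  double lpeak = -std::numeric_limits<double>::infinity();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long t = idx3(i, j, k, nx, ny);
        if (!mask[t]) continue;
        double s = 0.0;
        int c = 0;
        if (i >= r && i < nx - r && j >= r && j < ny - r && k >= r &&
            k < nz - r) {
          for (int o = 0; o < noff; ++o) s += values[t + lin[o]];
          c = noff;
        } else {
          for (int o = 0; o < noff; ++o) {
            int i2 = i + offs[3 * o], j2 = j + offs[3 * o + 1],
                k2 = k + offs[3 * o + 2];
            if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 ||
                k2 >= nz)
              continue;
            s += values[idx3(i2, j2, k2, nx, ny)];
            ++c;
          }
        }
        double m = s / c;
        if (m > gmax) gmax = m;
        double v = values[t];
        if (v > vmax + 1e-12) { vmax = v; lpeak = m; }
        else if (std::fabs(v - vmax) <= 1e-12 && m > lpeak) lpeak = m;
      }
  return NumericVector::create(lpeak, gmax);
}

// ---------------------------------------------------------------------------
// Marching tetrahedra iso-surface at 0.5 of a binary mask. Each cell split
// into 6 tetrahedra; binary values place all surface vertices at edge
// midpoints. The grid is implicitly padded with background, so the surface
// is always closed. Returns (mesh volume, mesh area) in voxel units.
// ---------------------------------------------------------------------------
static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};
// cube corner offsets (x,y,z)
static const int CORN[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

// [[Rcpp::export(name = ".cpp_mesh")]]
NumericVector cpp_mesh(NumericVector field, IntegerVector dims, double level,
                       int n_smooth, double lam, double mu) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto val = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return 0.0;
    return field[idx3(i, j, k, nx, ny)];
  };
  std::vector<double> VX, VY, VZ;
  std::vector<int> FA, FB, FC;
  std::map<std::pair<long long, std::pair<long long, long long> >, int> vmap;
  auto vid = [&](double p[3]) -> int {
    std::pair<long long, std::pair<long long, long long> > key(
        (long long)llround(p[0] * 1048576.0),
        std::make_pair((long long)llround(p[1] * 1048576.0),
                       (long long)llround(p[2] * 1048576.0)));
    std::map<std::pair<long long, std::pair<long long, long long> >,
             int>::iterator it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = VX.size();
    vmap[key] = id;
    VX.push_back(p[0]);
    VY.push_back(p[1]);
    VZ.push_back(p[2]);
    return id;
  };
  double P[4][3];
  int inb[4];
  auto addTri = [&](double a[3], double b[3], double c[3], double inPt[3]) {
    // orient the face so its normal points away from the inside reference
    double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double nvec[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                      u[0] * v[1] - u[1] * v[0]};
    double w[3] = {a[0] - inPt[0], a[1] - inPt[1], a[2] - inPt[2]};
    double dot = nvec[0] * w[0] + nvec[1] * w[1] + nvec[2] * w[2];
    int ia = vid(a), ib = vid(b), ic = vid(c);
    if (ia == ib || ib == ic || ia == ic) return; // degenerate sliver
    FA.push_back(ia);
    if (dot < 0) { FB.push_back(ic); FC.push_back(ib); }
    else { FB.push_back(ib); FC.push_back(ic); }
  };
  double CV[8];
  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        int any1 = 0, all1 = 1;
        for (int c = 0; c < 8; ++c) {
          CV[c] = val(i + CORN[c][0], j + CORN[c][1], k + CORN[c][2]);
          int in = CV[c] > level;
          any1 |= in;
          all1 &= in;
        }
        if (!any1 || all1) continue;
        double FV[4];
        for (int t = 0; t < 6; ++t) {
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = TETS[t][c];
            P[c][0] = i + CORN[cc][0];
            P[c][1] = j + CORN[cc][1];
            P[c][2] = k + CORN[cc][2];
            FV[c] = CV[cc];
            inb[c] = CV[cc] > level;
            nin += inb[c];
          }
          if (nin == 0 || nin == 4) continue;
          // inside reference: centroid of inside vertices
          double ref[3] = {0, 0, 0};
          int cnt = 0;
          for (int c = 0; c < 4; ++c)
            if (inb[c]) {
              ref[0] += P[c][0]; ref[1] += P[c][1]; ref[2] += P[c][2]; ++cnt;
            }
          ref[0] /= cnt; ref[1] /= cnt; ref[2] /= cnt;
          // linear interpolation of the level crossing on edge a (in) - b
          auto mid = [&](int a, int b, double out[3]) {
            double tpar = (level - FV[a]) / (FV[b] - FV[a]);
            if (!(tpar >= 0.0 && tpar <= 1.0)) tpar = 0.5;
            out[0] = P[a][0] + tpar * (P[b][0] - P[a][0]);
            out[1] = P[a][1] + tpar * (P[b][1] - P[a][1]);
            out[2] = P[a][2] + tpar * (P[b][2] - P[a][2]);
          };
          int ins[4], outs[4];
          int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) (inb[c] ? ins[ni++] : outs[no++]) = c;
          double q0[3], q1[3], q2[3], q3[3];
          if (nin == 1) {
            mid(ins[0], outs[0], q0); mid(ins[0], outs[1], q1);
            mid(ins[0], outs[2], q2);
            addTri(q0, q1, q2, P[ins[0]]);
          } else if (nin == 3) {
            mid(outs[0], ins[0], q0); mid(outs[0], ins[1], q1);
            mid(outs[0], ins[2], q2);
            addTri(q0, q1, q2, ref);
          } else { // nin == 2 -> quad
            mid(ins[0], outs[0], q0); mid(ins[0], outs[1], q1);
            mid(ins[1], outs[1], q2); mid(ins[1], outs[0], q3);
            addTri(q0, q1, q2, ref);
            addTri(q0, q2, q3, ref);
          }
        }
      }
  int nv = VX.size(), nf = FA.size();
  if (nf == 0) return NumericVector::create(0.0, 0.0);
  // Taubin lambda|mu smoothing: removes the half-voxel staircase without
  // the volume shrinkage of plain Laplacian smoothing
  if (n_smooth > 0) {
    std::vector<std::vector<int> > adj(nv);
    for (int f = 0; f < nf; ++f) {
      int vv[3] = {FA[f], FB[f], FC[f]};
      for (int e = 0; e < 3; ++e) {
        int x = vv[e], y = vv[(e + 1) % 3];
        adj[x].push_back(y);
        adj[y].push_back(x);
      }
    }
    for (int v = 0; v < nv; ++v) {
      std::sort(adj[v].begin(), adj[v].end());
      adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
    }
    std::vector<double> NX(nv), NY(nv), NZ(nv);
    for (int it = 0; it < 2 * n_smooth; ++it) {
      double w = (it % 2 == 0) ? lam : mu;
      for (int v = 0; v < nv; ++v) {
        double sx = 0, sy = 0, sz = 0;
        int m = adj[v].size();
        if (m == 0) { NX[v] = VX[v]; NY[v] = VY[v]; NZ[v] = VZ[v]; continue; }
        for (int e = 0; e < m; ++e) {
          sx += VX[adj[v][e]]; sy += VY[adj[v][e]]; sz += VZ[adj[v][e]];
        }
        NX[v] = VX[v] + w * (sx / m - VX[v]);
        NY[v] = VY[v] + w * (sy / m - VY[v]);
        NZ[v] = VZ[v] + w * (sz / m - VZ[v]);
      }
      VX.swap(NX); VY.swap(NY); VZ.swap(NZ);
    }
  }
  double vol6 = 0.0, area = 0.0;
  for (int f = 0; f < nf; ++f) {
    int a = FA[f], b = FB[f], c = FC[f];
    double u[3] = {VX[b] - VX[a], VY[b] - VY[a], VZ[b] - VZ[a]};
    double v[3] = {VX[c] - VX[a], VY[c] - VY[a], VZ[c] - VZ[a]};
    double n2[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                    u[0] * v[1] - u[1] * v[0]};
    area += 0.5 * std::sqrt(n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2]);
    vol6 += VX[a] * (VY[b] * VZ[c] - VZ[b] * VY[c]) -
            VY[a] * (VX[b] * VZ[c] - VZ[b] * VX[c]) +
            VZ[a] * (VX[b] * VY[c] - VY[b] * VX[c]);
  }
  // mesh-vertex bounding box extents per axis
  double bb[3] = {0, 0, 0};
  if (nv > 0) {
    double mn[3] = {VX[0], VY[0], VZ[0]}, mx[3] = {VX[0], VY[0], VZ[0]};
    for (int v = 1; v < nv; ++v) {
      mn[0] = std::min(mn[0], VX[v]); mx[0] = std::max(mx[0], VX[v]);
      mn[1] = std::min(mn[1], VY[v]); mx[1] = std::max(mx[1], VY[v]);
      mn[2] = std::min(mn[2], VZ[v]); mx[2] = std::max(mx[2], VZ[v]);
    }
    for (int a = 0; a < 3; ++a) bb[a] = mx[a] - mn[a];
  }
  return NumericVector::create(vol6 / 6.0, area, bb[0], bb[1], bb[2]);
}

// ---------------------------------------------------------------------------
// Incremental 3D convex hull. Points as n x 3 matrix. Returns
// list(volume, area, vertices = indices used). Degenerate inputs (coplanar)
// give volume 0 and NA area.
// ---------------------------------------------------------------------------
struct Face { int a, b, c; double nx, ny, nz, off; bool alive; };

// [[Rcpp::export(name = ".cpp_hull3d")]]
List cpp_hull3d(NumericMatrix pts) {
  int n = pts.nrow();
  auto X = [&](int i, int d) { return pts(i, d); };
  auto sub = [&](int i, int j, double o[3]) {
    o[0] = X(i, 0) - X(j, 0); o[1] = X(i, 1) - X(j, 1); o[2] = X(i, 2) - X(j, 2);
  };
  if (n < 4)
    return List::create(_["volume"] = 0.0, _["area"] = NA_REAL,
                        _["vertices"] = IntegerVector(0));
  // initial non-degenerate tetrahedron
  int p0 = 0, p1 = -1, p2 = -1, p3 = -1;
  for (int i = 1; i < n && p1 < 0; ++i) {
    double d[3]; sub(i, p0, d);
    if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] > 1e-18) p1 = i;
  }
  if (p1 >= 0)
    for (int i = 1; i < n && p2 < 0; ++i) {
      double u[3], v[3]; sub(p1, p0, u); sub(i, p0, v);
      double cx = u[1] * v[2] - u[2] * v[1], cy = u[2] * v[0] - u[0] * v[2],
             cz = u[0] * v[1] - u[1] * v[0];
      if (cx * cx + cy * cy + cz * cz > 1e-18) p2 = i;
    }
  if (p2 >= 0)
    for (int i = 1; i < n && p3 < 0; ++i) {
      double u[3], v[3], w[3];
      sub(p1, p0, u); sub(p2, p0, v); sub(i, p0, w);
      double det = u[0] * (v[1] * w[2] - v[2] * w[1]) -
                   u[1] * (v[0] * w[2] - v[2] * w[0]) +
                   u[2] * (v[0] * w[1] - v[1] * w[0]);
      if (std::fabs(det) > 1e-12) p3 = i;
    }
  if (p3 < 0)
    return List::create(_["volume"] = 0.0, _["area"] = NA_REAL,
                        _["vertices"] = IntegerVector(0));
  std::vector<Face> faces;
  double cen[3] = {
    (X(p0, 0) + X(p1, 0) + X(p2, 0) + X(p3, 0)) / 4.0,
    (X(p0, 1) + X(p1, 1) + X(p2, 1) + X(p3, 1)) / 4.0,
    (X(p0, 2) + X(p1, 2) + X(p2, 2) + X(p3, 2)) / 4.0};
  auto mkFace = [&](int a, int b, int c) {
    Face f; f.a = a; f.b = b; f.c = c; f.alive = true;
    double u[3], v[3]; sub(b, a, u); sub(c, a, v);
    f.nx = u[1] * v[2] - u[2] * v[1];
    f.ny = u[2] * v[0] - u[0] * v[2];
    f.nz = u[0] * v[1] - u[1] * v[0];
    f.off = f.nx * X(a, 0) + f.ny * X(a, 1) + f.nz * X(a, 2);
    // orient outward w.r.t. interior centroid
    if (f.nx * cen[0] + f.ny * cen[1] + f.nz * cen[2] > f.off) {
      std::swap(f.b, f.c);
      f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz; f.off = -f.off;
    }
    return f;
  };
  faces.push_back(mkFace(p0, p1, p2));
  faces.push_back(mkFace(p0, p1, p3));
  faces.push_back(mkFace(p0, p2, p3));
  faces.push_back(mkFace(p1, p2, p3));
  for (int i = 0; i < n; ++i) {
    if (i == p0 || i == p1 || i == p2 || i == p3) continue;
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double d = faces[f].nx * X(i, 0) + faces[f].ny * X(i, 1) +
                 faces[f].nz * X(i, 2) - faces[f].off;
      double scale = std::sqrt(faces[f].nx * faces[f].nx +
                               faces[f].ny * faces[f].ny +
                               faces[f].nz * faces[f].nz);
      if (d > 1e-9 * std::max(1.0, scale)) vis.push_back(f);
    }
    if (vis.empty()) continue;
    // horizon edges: edges of visible faces not shared with another visible
    std::vector<std::pair<int, int> > edges;
    for (size_t vIdx = 0; vIdx < vis.size(); ++vIdx) {
      Face& f = faces[vis[vIdx]];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int t = 0; t < 3; ++t) {
        bool shared = false;
        for (size_t s = 0; s < edges.size(); ++s)
          if (edges[s].first == e[t][1] && edges[s].second == e[t][0]) {
            edges.erase(edges.begin() + s);
            shared = true;
            break;
          }
        if (!shared) edges.push_back(std::make_pair(e[t][0], e[t][1]));
      }
      f.alive = false;
    }
    for (size_t s = 0; s < edges.size(); ++s)
      faces.push_back(mkFace(edges[s].first, edges[s].second, i));
    // prune dead faces occasionally
    if (faces.size() > 4096) {
      std::vector<Face> keep;
      for (size_t f = 0; f < faces.size(); ++f)
        if (faces[f].alive) keep.push_back(faces[f]);
      faces.swap(keep);
    }
  }
  double vol6 = 0.0, area = 0.0;
  std::vector<int> used;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    const Face& fc = faces[f];
    double mag = std::sqrt(fc.nx * fc.nx + fc.ny * fc.ny + fc.nz * fc.nz);
    area += 0.5 * mag;
    vol6 += X(fc.a, 0) * (X(fc.b, 1) * X(fc.c, 2) - X(fc.b, 2) * X(fc.c, 1)) -
            X(fc.a, 1) * (X(fc.b, 0) * X(fc.c, 2) - X(fc.b, 2) * X(fc.c, 0)) +
            X(fc.a, 2) * (X(fc.b, 0) * X(fc.c, 1) - X(fc.b, 1) * X(fc.c, 0));
    used.push_back(fc.a + 1);
    used.push_back(fc.b + 1);
    used.push_back(fc.c + 1);
  }
  std::sort(used.begin(), used.end());
  used.erase(std::unique(used.begin(), used.end()), used.end());
  return List::create(_["volume"] = vol6 / 6.0, _["area"] = area,
                      _["vertices"] = wrap(used));
}
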