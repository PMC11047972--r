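// Low-level volumetric kernels. All volumes are R arrays with dim = (nz, ny, nx),
// column-major, so linear index = z + nz*(y + ny*x), 0-based here.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double> &src, std::vector<double> &dst,
                      int nz, int ny, int nx, int axis,
                      const std::vector<double> &kern) {
  int r = (int)kern.size() / 2;
  int dims[3] = {nz, ny, nx};
  int n = dims[axis];
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int pos[3] = {z, y, x};
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int p = clampi(pos[axis] + k, 0, n - 1);
          int q[3] = {pos[0], pos[1], pos[2]};
          q[axis] = p;
          acc += kern[k + r] * src[idx3(q[0], q[1], q[2], nz, ny)];
        }
        dst[idx3(z, y, x, nz, ny)] = acc;
      }
    }
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

// [[Rcpp::export(name = ".nc_gaussian_blur3")]]
NumericVector nc_gaussian_blur3(NumericVector vol, IntegerVector dim, double sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  std::vector<double> k = gauss_kernel(sigma);
  blur_axis(a, b, nz, ny, nx, 0, k);
  blur_axis(b, a, nz, ny, nx, 1, k);
  blur_axis(a, b, nz, ny, nx, 2, k);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Frangi vesselness (bright tubes on dark background)
// ---------------------------------------------------------------------------

// Eigenvalues of a symmetric 3x3 matrix, analytic (Smith's trigonometric method).
static void eig_sym3(double a11, double a12, double a13,
                     double a22, double a23, double a33,
                     double ev[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-30) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
    double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    // det(B)/2 with B = (A - qI)/p
    double c11 = b11 / p, c12 = a12 / p, c13 = a13 / p;
    double c22 = b22 / p, c23 = a23 / p, c33 = b33 / p;
    double detB = c11 * (c22 * c33 - c23 * c23)
                - c12 * (c12 * c33 - c23 * c13)
                + c13 * (c12 * c23 - c22 * c13);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    double e1 = q + 2.0 * p * std::cos(phi);
    double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    double e2 = 3.0 * q - e1 - e3;
    ev[0] = e1; ev[1] = e2; ev[2] = e3;
  }
  // sort by |ev| ascending (Frangi convention)
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2 - i; ++j)
      if (std::fabs(ev[j]) > std::fabs(ev[j + 1])) {
        double t = ev[j]; ev[j] = ev[j + 1]; ev[j + 1] = t;
      }
}

// [[Rcpp::export(name = ".nc_frangi3")]]
NumericVector nc_frangi3(NumericVector vol, IntegerVector dim,
                         NumericVector sigmas, double fa, double fb) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> best(n, 0.0);
  std::vector<double> sm(n), tmp(n);
  std::vector<double> l1(n), l2(n), l3(n);

  for (int si = 0; si < sigmas.size(); ++si) {
    double sg = sigmas[si];
    double s2 = sg * sg;
    std::vector<double> src(vol.begin(), vol.end());
    std::vector<double> k = gauss_kernel(sg);
    blur_axis(src, tmp, nz, ny, nx, 0, k);
    blur_axis(tmp, src, nz, ny, nx, 1, k);
    blur_axis(src, sm, nz, ny, nx, 2, k);

    double smax = 0.0;
    for (int x = 0; x < nx; ++x) {
      int xm = clampi(x - 1, 0, nx - 1), xp = clampi(x + 1, 0, nx - 1);
      for (int y = 0; y < ny; ++y) {
        int ym = clampi(y - 1, 0, ny - 1), yp = clampi(y + 1, 0, ny - 1);
        for (int z = 0; z < nz; ++z) {
          int zm = clampi(z - 1, 0, nz - 1), zp = clampi(z + 1, 0, nz - 1);
          double c = sm[idx3(z, y, x, nz, ny)];
          double dxx = sm[idx3(z, y, xp, nz, ny)] - 2 * c + sm[idx3(z, y, xm, nz, ny)];
          double dyy = sm[idx3(z, yp, x, nz, ny)] - 2 * c + sm[idx3(z, ym, x, nz, ny)];
          double dzz = sm[idx3(zp, y, x, nz, ny)] - 2 * c + sm[idx3(zm, y, x, nz, ny)];
          double dxy = (sm[idx3(z, yp, xp, nz, ny)] - sm[idx3(z, ym, xp, nz, ny)]
                      - sm[idx3(z, yp, xm, nz, ny)] + sm[idx3(z, ym, xm, nz, ny)]) / 4.0;
          double dxz = (sm[idx3(zp, y, xp, nz, ny)] - sm[idx3(zm, y, xp, nz, ny)]
                      - sm[idx3(zp, y, xm, nz, ny)] + sm[idx3(zm, y, xm, nz, ny)]) / 4.0;
          double dyz = (sm[idx3(zp, yp, x, nz, ny)] - sm[idx3(zm, yp, x, nz, ny)]
                      - sm[idx3(zp, ym, x, nz, ny)] + sm[idx3(zm, ym, x, nz, ny)]) / 4.0;
          double ev[3];
          // gamma-normalized Hessian (scale^2)
          eig_sym3(s2 * dxx, s2 * dxy, s2 * dxz, s2 * dyy, s2 * dyz, s2 * dzz, ev);
          size_t id = (size_t)idx3(z, y, x, nz, ny);
          l1[id] = ev[0]; l2[id] = ev[1]; l3[id] = ev[2];
          double S = std::sqrt(ev[0] * ev[0] + ev[1] * ev[1] + ev[2] * ev[2]);
          if (S > smax) smax = S;
        }
      }
    }
    double fc = smax > 0 ? smax / 2.0 : 1.0;
    for (size_t id = 0; id < n; ++id) {
      double e2 = l2[id], e3 = l3[id];
      if (e2 >= 0.0 || e3 >= 0.0) continue; // bright tube requires both negative
      double e1 = l1[id];
      double Ra = std::fabs(e2) / std::fabs(e3);
      double Rb = std::fabs(e1) / std::sqrt(std::fabs(e2 * e3));
      double S = std::sqrt(e1 * e1 + e2 * e2 + e3 * e3);
      double v = (1.0 - std::exp(-(Ra * Ra) / (2.0 * fa * fa)))
               * std::exp(-(Rb * Rb) / (2.0 * fb * fb))
               * (1.0 - std::exp(-(S * S) / (2.0 * fc * fc)));
      if (v > best[id]) best[id] = v;
    }
  }
  NumericVector out(best.begin(), best.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning
// ---------------------------------------------------------------------------

// Simple-point test on the 3x3x3 neighborhood nb[27] (center nb[13]),
// index = (dz+1) + 3*(dy+1) + 9*(dx+1).
// Criterion (Malandain-Bertrand): exactly one 26-component of the object in
// N26* and exactly one 6-component of the background in N18 6-adjacent to the
// center.
static bool is_simple(const bool nb[27]) {
  // --- object components in N26* (26-connectivity) ---
  int comp[27];
  for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || comp[i] >= 0) continue;
    // BFS
    std::queue<int> q;
    q.push(i);
    comp[i] = ncomp;
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int cz = cur % 3, cy = (cur / 3) % 3, cx = cur / 9;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int tz = cz + dz, ty = cy + dy, tx = cx + dx;
            if (tz < 0 || tz > 2 || ty < 0 || ty > 2 || tx < 0 || tx > 2) continue;
            int t = tz + 3 * ty + 9 * tx;
            if (t == 13 || !nb[t] || comp[t] >= 0) continue;
            comp[t] = ncomp;
            q.push(t);
          }
    }
    ++ncomp;
  }
  if (ncomp != 1) return false;

  // --- background 6-components in N18 touching a 6-neighbor of the center ---
  // N18: neighbors with |dx|+|dy|+|dz| <= 2 (faces and edges).
  static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int cz = i % 3 - 1, cy = (i / 3) % 3 - 1, cx = i / 9 - 1;
    int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
    in18[i] = (m >= 1 && m <= 2);
  }
  int bcomp[27];
  for (int i = 0; i < 27; ++i) bcomp[i] = -1;
  int nb6 = 0;
  for (int s = 0; s < 6; ++s) {
    int i = (d6[s][2] + 1) + 3 * (d6[s][1] + 1) + 9 * (d6[s][0] + 1);
    if (nb[i] || bcomp[i] >= 0) continue; // must be background, unvisited
    std::queue<int> q;
    q.push(i);
    bcomp[i] = nb6;
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int cz = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cx = cur / 9 - 1;
      for (int s2 = 0; s2 < 6; ++s2) {
        int tz = cz + d6[s2][2], ty = cy + d6[s2][1], tx = cx + d6[s2][0];
        if (tz < -1 || tz > 1 || ty < -1 || ty > 1 || tx < -1 || tx > 1) continue;
        int t = (tz + 1) + 3 * (ty + 1) + 9 * (tx + 1);
        if (t == 13 || !in18[t] || nb[t] || bcomp[t] >= 0) continue;
        bcomp[t] = nb6;
        q.push(t);
      }
    }
    ++nb6;
  }
  return nb6 == 1;
}

// [[Rcpp::export(name = ".nc_thin3")]]
LogicalVector nc_thin3(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<char> m(n);
  for (size_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  static const int dirs[6][3] = { // (dz,dy,dx): U,D,N,S,E,W border checks
    {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

  auto at = [&](int z, int y, int x) -> char {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return m[idx3(z, y, x, nz, ny)];
  };

  // active voxel list to avoid full scans
  std::vector<int> active;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        if (m[idx3(z, y, x, nz, ny)]) active.push_back(idx3(z, y, x, nz, ny));

  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // candidates: border points in direction d
      std::vector<int> cand;
      for (int id : active) {
        if (!m[id]) continue;
        int z = id % nz, y = (id / nz) % ny, x = id / (nz * ny);
        if (!at(z + dirs[d][0], y + dirs[d][1], x + dirs[d][2]))
          cand.push_back(id);
      }
      for (int id : cand) {
        if (!m[id]) continue;
        int z = id % nz, y = (id / nz) % ny, x = id / (nz * ny);
        // neighborhood + neighbor count
        bool nb[27];
        int cnt = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              int i = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
              nb[i] = at(z + dz, y + dy, x + dx) != 0;
              if (i != 13 && nb[i]) ++cnt;
            }
        if (cnt <= 1) continue;        // curve endpoint (or isolated): keep
        if (!is_simple(nb)) continue;  // deletion would change topology
        m[id] = 0;                     // sequential deletion keeps test valid
        changed = true;
      }
    }
    if (changed) {
      // compact active list
      std::vector<int> nxt;
      nxt.reserve(active.size());
      for (int id : active) if (m[id]) nxt.push_back(id);
      active.swap(nxt);
    }
  }

  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 26-neighbor count stencil
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".nc_neighbor_count26")]]
IntegerVector nc_neighbor_count26(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  IntegerVector out(n);
  auto at = [&](int z, int y, int x) -> int {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return mask[idx3(z, y, x, nz, ny)] ? 1 : 0;
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int c = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (!dx && !dy && !dz) continue;
              c += at(z + dz, y + dy, x + dx);
            }
        out[idx3(z, y, x, nz, ny)] = c;
      }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear sampling at (x,y,z) 0-based voxel coordinates, border-clipped
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".nc_trilinear")]]
NumericVector nc_trilinear(NumericVector vol, IntegerVector dim, NumericMatrix xyz) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int np = xyz.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double x = xyz(i, 0), y = xyz(i, 1), z = xyz(i, 2);
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    int x1 = clampi(x0 + 1, 0, nx - 1), y1 = clampi(y0 + 1, 0, ny - 1),
        z1 = clampi(z0 + 1, 0, nz - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double c000 = vol[idx3(z0, y0, x0, nz, ny)], c001 = vol[idx3(z1, y0, x0, nz, ny)];
    double c010 = vol[idx3(z0, y1, x0, nz, ny)], c011 = vol[idx3(z1, y1, x0, nz, ny)];
    double c100 = vol[idx3(z0, y0, x1, nz, ny)], c101 = vol[idx3(z1, y0, x1, nz, ny)];
    double c110 = vol[idx3(z0, y1, x1, nz, ny)], c111 = vol[idx3(z1, y1, x1, nz, ny)];
    double c00 = c000 * (1 - fz) + c001 * fz;
    double c01 = c010 * (1 - fz) + c011 * fz;
    double c10 = c100 * (1 - fz) + c101 * fz;
    double c11 = c110 * (1 - fz) + c111 * fz;
    double c0 = c00 * (1 - fy) + c01 * fy;
    double c1 = c10 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fx) + c1 * fx;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Gaussian tube stamping (max-combined) for the synthetic renderer
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".nc_stamp_points")]]
NumericVector nc_stamp_points(NumericVector vol, IntegerVector dim,
                              NumericMatrix xyz, NumericVector intensity,
                              double sigma, int rs) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out = clone(vol);
  double s2 = 2.0 * sigma * sigma;
  for (int i = 0; i < xyz.nrow(); ++i) {
    double px = xyz(i, 0), py = xyz(i, 1), pz = xyz(i, 2);
    double I = intensity[i];
    int x0 = clampi((int)std::floor(px) - rs, 0, nx - 1);
    int x1 = clampi((int)std::ceil(px) + rs, 0, nx - 1);
    int y0 = clampi((int)std::floor(py) - rs, 0, ny - 1);
    int y1 = clampi((int)std::ceil(py) + rs, 0, ny - 1);
    int z0 = clampi((int)std::floor(pz) - rs, 0, nz - 1);
    int z1 = clampi((int)std::ceil(pz) + rs, 0, nz - 1);
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double r2 = (x - px) * (x - px) + (y - py) * (y - py) +
                      (z - pz) * (z - pz);
          double v = I * std::exp(-r2 / s2);
          int id = idx3(z, y, x, nz, ny);
          if (v > out[id]) out[id] = v;
        }
  }
  return out;
}
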