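// Low-level 3D image operators for vascular morphometry:
//  - exact Euclidean distance transform (Felzenszwalb & Huttenlocher, separable)
//  - distance-ordered homotopic thinning to a 1-voxel curve skeleton
//  - capsule (tube) rasterisation for the phantom renderer
//  - skeleton tracing with branch-point exclusion and straight-window selection
// All masks are column-major (x fastest), matching R arrays dim = c(nx, ny, nz).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------- EDT ------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (in voxel units) from each foreground voxel to the
// nearest background voxel; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  const double INF = 1e18;
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      int base = idx3(0, y, z, nx, ny);
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx, v, zb);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, ny, v, zb);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = d[y];
    }
  // along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, nz, v, zb);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = d[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Exact Euclidean distance transform restricted to foreground voxels, with
// distances capped at `cap` voxels. For each foreground voxel, background is
// searched over expanding Chebyshev shells; the scan stops once the shell
// radius squared exceeds the best squared distance found. Cost scales with
// the foreground size and local thickness, not the grid size — the right
// trade for sparse tubular masks whose radii are bounded.
// [[Rcpp::export]]
NumericVector cpp_edt_capped(LogicalVector mask, IntegerVector dim, double cap) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  int icap = (int)std::ceil(cap);
  double cap2 = cap * cap;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        double best = cap2;
        for (int e = 1; e <= icap; ++e) {
          if ((double)(e) * e >= best) break;
          // scan the Chebyshev shell of radius e (clipped to the grid;
          // out-of-grid voxels count as background)
          for (int dz = -e; dz <= e; ++dz) {
            int zz = z + dz;
            bool zface = (std::abs(dz) == e);
            for (int dy = -e; dy <= e; ++dy) {
              int yy = y + dy;
              bool yface = (std::abs(dy) == e);
              if (zface || yface) {
                for (int dx = -e; dx <= e; ++dx) {
                  int xx = x + dx;
                  double d2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
                  if (d2 >= best) continue;
                  if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                      zz < 0 || zz >= nz) continue;
                  if (!mask[idx3(xx, yy, zz, nx, ny)]) best = d2;
                }
              } else {
                for (int dx = -e; dx <= e; dx += 2 * e) {
                  int xx = x + dx;
                  double d2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
                  if (d2 >= best) continue;
                  if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                      zz < 0 || zz >= nz) continue;
                  if (!mask[idx3(xx, yy, zz, nx, ny)]) best = d2;
                }
              }
            }
          }
        }
        out[i] = std::sqrt(best);
      }
  return out;
}

// ------------------------------------------------------------- thinning ----

// 26-neighbourhood offsets (excluding centre), and N18 subset for the
// background connectivity test.
struct Nbhd {
  int off[26][3];
  bool adj26[26][26]; // 26-adjacency between neighbourhood cells
  bool adj6[26][26];  // 6-adjacency between neighbourhood cells
  bool is18[26];
  bool is6[26];
  Nbhd() {
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          off[k][0] = dx; off[k][1] = dy; off[k][2] = dz;
          int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
          is18[k] = (a <= 2);
          is6[k]  = (a == 1);
          ++k;
        }
    for (int i = 0; i < 26; ++i)
      for (int j = 0; j < 26; ++j) {
        int dx = std::abs(off[i][0] - off[j][0]);
        int dy = std::abs(off[i][1] - off[j][1]);
        int dz = std::abs(off[i][2] - off[j][2]);
        adj26[i][j] = (i != j) && dx <= 1 && dy <= 1 && dz <= 1;
        adj6[i][j]  = (i != j) && (dx + dy + dz == 1);
      }
  }
};
static const Nbhd NB;

// Topological simple-point test (26-connected foreground / 6-connected
// background): deleting p must leave exactly one foreground component among
// its 26 neighbours and exactly one background component in N18 touching a
// face neighbour.
static bool simple_from_nb(const char nb[26]) {
  int nfg = 0;
  for (int k = 0; k < 26; ++k) if (nb[k]) ++nfg;
  if (nfg == 0) return false;

  // foreground components (26-connectivity) among the 26 neighbours
  int comp = 0;
  bool seen[26] = {false};
  int stack[26];
  for (int k = 0; k < 26; ++k) {
    if (!nb[k] || seen[k]) continue;
    if (++comp > 1) return false;
    int top = 0;
    stack[top++] = k; seen[k] = true;
    while (top) {
      int c = stack[--top];
      for (int j = 0; j < 26; ++j)
        if (nb[j] && !seen[j] && NB.adj26[c][j]) { seen[j] = true; stack[top++] = j; }
    }
  }
  if (comp != 1) return false;

  // background components (6-connectivity) within N18 that touch a face
  // neighbour of p
  bool seenb[26] = {false};
  int compb = 0;
  for (int k = 0; k < 26; ++k) {
    if (!NB.is6[k] || nb[k] || seenb[k]) continue;
    ++compb;
    if (compb > 1) return false;
    int top = 0;
    stack[top++] = k; seenb[k] = true;
    while (top) {
      int c = stack[--top];
      for (int j = 0; j < 26; ++j)
        if (NB.is18[j] && !nb[j] && !seenb[j] && NB.adj6[c][j]) {
          seenb[j] = true; stack[top++] = j;
        }
    }
  }
  return compb == 1;
}

// gather the 26-neighbourhood occupancy of voxel (x,y,z); `noff` carries the
// precomputed linear offsets for the interior fast path
static inline void gather_nb(const std::vector<char>& m, int x, int y, int z,
                             int nx, int ny, int nz, R_xlen_t i,
                             const R_xlen_t* noff, char nb[26]) {
  if (x >= 1 && x < nx - 1 && y >= 1 && y < ny - 1 && z >= 1 && z < nz - 1) {
    for (int k = 0; k < 26; ++k) nb[k] = m[i + noff[k]];
  } else {
    for (int k = 0; k < 26; ++k) {
      int xx = x + NB.off[k][0], yy = y + NB.off[k][1], zz = z + NB.off[k][2];
      nb[k] = (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
                  ? m[idx3(xx, yy, zz, nx, ny)] : (char)0;
    }
  }
}

// Distance-ordered homotopic thinning with curve-endpoint preservation.
// Boundary voxels are eroded in increasing EDT order while they remain
// topologically simple; voxels with at most one foreground neighbour are kept
// so centrelines are not shortened. Squared Euclidean distances between
// lattice points are integers, so a bucket queue keyed by squared distance
// gives exact distance ordering in O(1) per operation.
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, NumericVector edt, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  R_xlen_t noff[26];
  for (int k = 0; k < 26; ++k)
    noff[k] = NB.off[k][0] + (R_xlen_t)nx * NB.off[k][1] +
              (R_xlen_t)nx * ny * NB.off[k][2];

  long maxkey = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (m[i]) {
      long k = (long)llround(edt[i] * edt[i]);
      if (k > maxkey) maxkey = k;
    }
  std::vector< std::vector<R_xlen_t> > buckets(maxkey + 2);
  std::vector<char> inq(n, 0);
  char nb[26];

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        if (!m[i]) continue;
        gather_nb(m, x, y, z, nx, ny, nz, i, noff, nb);
        int nfg = 0;
        for (int k = 0; k < 26; ++k) if (nb[k]) ++nfg;
        if (nfg < 26) {
          buckets[(long)llround(edt[i] * edt[i])].push_back(i);
          inq[i] = 1;
        }
      }

  for (long key = 0; key <= maxkey; ++key) {
    while (!buckets[key].empty()) {
      R_xlen_t i = buckets[key].back();
      buckets[key].pop_back();
      inq[i] = 0;
      if (!m[i]) continue;
      int z = (int)(i / ((R_xlen_t)nx * ny));
      int rem = (int)(i - (R_xlen_t)z * nx * ny);
      int y = rem / nx, x = rem % nx;
      gather_nb(m, x, y, z, nx, ny, nz, i, noff, nb);
      int nfg = 0;
      for (int k = 0; k < 26; ++k) if (nb[k]) ++nfg;
      if (nfg <= 1) continue; // curve endpoint (or isolated voxel): keep
      if (!simple_from_nb(nb)) continue;
      m[i] = 0;
      for (int k = 0; k < 26; ++k) {
        int xx = x + NB.off[k][0], yy = y + NB.off[k][1], zz = z + NB.off[k][2];
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz) {
          R_xlen_t j = idx3(xx, yy, zz, nx, ny);
          if (m[j] && !inq[j]) {
            long kj = (long)llround(edt[j] * edt[j]);
            if (kj < key) kj = key; // never move backwards in the sweep
            buckets[kj].push_back(j);
            inq[j] = 1;
          }
        }
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ----------------------------------------------------------- rasteriser ----

static inline double dist2_seg(double px, double py, double pz,
                               double ax, double ay, double az,
                               double bx, double by, double bz) {
  double vx = bx - ax, vy = by - ay, vz = bz - az;
  double wx = px - ax, wy = py - ay, wz = pz - az;
  double vv = vx * vx + vy * vy + vz * vz;
  double t = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  return dx * dx + dy * dy + dz * dz;
}

// Rasterise tube segments into `mask` (modified in place). Segment k runs
// from (x1,y1,z1) to (x2,y2,z2) with radius r (all mm, columns of `segs`).
// Voxel i (0-based) has centre origin + (i + 0.5) * spacing. Sub-voxel tubes
// are guaranteed a one-voxel centreline trace.
// [[Rcpp::export]]
void cpp_raster_tubes(NumericMatrix segs, LogicalVector mask, IntegerVector dim,
                      double spacing, NumericVector origin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  for (int s = 0; s < segs.nrow(); ++s) {
    double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    double r = segs(s, 6), r2 = r * r;
    double pad = r + spacing;
    int x0 = (int)std::floor((std::min(ax, bx) - pad - ox) / spacing - 0.5);
    int x1 = (int)std::ceil ((std::max(ax, bx) + pad - ox) / spacing - 0.5);
    int y0 = (int)std::floor((std::min(ay, by) - pad - oy) / spacing - 0.5);
    int y1 = (int)std::ceil ((std::max(ay, by) + pad - oy) / spacing - 0.5);
    int z0 = (int)std::floor((std::min(az, bz) - pad - oz) / spacing - 0.5);
    int z1 = (int)std::ceil ((std::max(az, bz) + pad - oz) / spacing - 0.5);
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
    if (x1 >= nx) x1 = nx - 1; if (y1 >= ny) y1 = ny - 1; if (z1 >= nz) z1 = nz - 1;
    for (int z = z0; z <= z1; ++z) {
      double pz = oz + (z + 0.5) * spacing;
      for (int y = y0; y <= y1; ++y) {
        double py = oy + (y + 0.5) * spacing;
        for (int x = x0; x <= x1; ++x) {
          double px = ox + (x + 0.5) * spacing;
          if (dist2_seg(px, py, pz, ax, ay, az, bx, by, bz) <= r2)
            mask[idx3(x, y, z, nx, ny)] = true;
        }
      }
    }
    // centreline trace so sub-voxel tubes are never lost
    double len = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay) +
                           (bz - az) * (bz - az));
    int nstep = std::max(1, (int)std::ceil(len / (0.4 * spacing)));
    for (int q = 0; q <= nstep; ++q) {
      double t = (double)q / nstep;
      int x = (int)std::floor((ax + t * (bx - ax) - ox) / spacing);
      int y = (int)std::floor((ay + t * (by - ay) - oy) / spacing);
      int z = (int)std::floor((az + t * (bz - az) - oz) / spacing);
      if (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz)
        mask[idx3(x, y, z, nx, ny)] = true;
    }
  }
}

// Project tube segments intersecting the depth slab [z_lo, z_hi) mm onto the
// en-face grid `mask2d` (nx x ny, modified in place); returns the number of
// newly covered pixels. Voxelisation matches cpp_raster_tubes so the
// generator's coverage bookkeeping equals the rendered, binarised footprint.
// [[Rcpp::export]]
int cpp_mark_footprint(NumericMatrix segs, LogicalVector mask2d, IntegerVector dim,
                       double spacing, double z_lo, double z_hi) {
  int nx = dim[0], ny = dim[1];
  int nz = (int)std::ceil(z_hi / spacing - 1e-9);
  int z0v = (int)std::floor(z_lo / spacing + 1e-9);
  int newpix = 0;
  for (int s = 0; s < segs.nrow(); ++s) {
    double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    double r = segs(s, 6), r2 = r * r;
    if (std::min(az, bz) - r >= z_hi || std::max(az, bz) + r < z_lo) continue;
    double pad = r + spacing;
    int x0 = (int)std::floor((std::min(ax, bx) - pad) / spacing - 0.5);
    int x1 = (int)std::ceil ((std::max(ax, bx) + pad) / spacing - 0.5);
    int y0 = (int)std::floor((std::min(ay, by) - pad) / spacing - 0.5);
    int y1 = (int)std::ceil ((std::max(ay, by) + pad) / spacing - 0.5);
    int za = (int)std::floor((std::min(az, bz) - pad) / spacing - 0.5);
    int zb = (int)std::ceil ((std::max(az, bz) + pad) / spacing - 0.5);
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (za < z0v) za = z0v;
    if (x1 >= nx) x1 = nx - 1; if (y1 >= ny) y1 = ny - 1; if (zb >= nz) zb = nz - 1;
    for (int y = y0; y <= y1; ++y) {
      double py = (y + 0.5) * spacing;
      for (int x = x0; x <= x1; ++x) {
        R_xlen_t i2 = x + (R_xlen_t)nx * y;
        if (mask2d[i2]) continue;
        double px = (x + 0.5) * spacing;
        bool hit = false;
        for (int z = za; z <= zb && !hit; ++z) {
          double pz = (z + 0.5) * spacing;
          if (dist2_seg(px, py, pz, ax, ay, az, bx, by, bz) <= r2) hit = true;
        }
        if (hit) { mask2d[i2] = true; ++newpix; }
      }
    }
    // centreline trace (matches the renderer's sub-voxel guarantee)
    double len = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay) +
                           (bz - az) * (bz - az));
    int nstep = std::max(1, (int)std::ceil(len / (0.4 * spacing)));
    for (int q = 0; q <= nstep; ++q) {
      double t = (double)q / nstep;
      double pz = az + t * (bz - az);
      if (pz < z_lo || pz >= z_hi) continue;
      int x = (int)std::floor((ax + t * (bx - ax)) / spacing);
      int y = (int)std::floor((ay + t * (by - ay)) / spacing);
      if (x >= 0 && x < nx && y >= 0 && y < ny) {
        R_xlen_t i2 = x + (R_xlen_t)nx * y;
        if (!mask2d[i2]) { mask2d[i2] = true; ++newpix; }
      }
    }
  }
  return newpix;
}

// Sample the binarised render directly: rasterise tubes, keep each vessel
// voxel with the per-slice probability that its noisy intensity exceeds the
// threshold (1 for shallow voxels), and scatter the (rare) background
// false-positives by sampling their Binomial count and uniform positions.
// Distributionally identical to threshold(grayscale(render)) but needs RNG
// draws only where the outcome is uncertain.
// [[Rcpp::export]]
LogicalVector cpp_render_mask(NumericMatrix segs, IntegerVector dim,
                              double spacing, NumericVector origin,
                              NumericVector p_vessel_by_z, double p_bg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector mask(n);
  if (segs.nrow()) cpp_raster_tubes(segs, mask, dim, spacing, origin);
  GetRNGstate();
  R_xlen_t nvess = 0;
  for (int z = 0; z < nz; ++z) {
    double p = p_vessel_by_z[z];
    R_xlen_t base = (R_xlen_t)nx * ny * z;
    for (R_xlen_t i = base; i < base + (R_xlen_t)nx * ny; ++i) {
      if (!mask[i]) continue;
      ++nvess;
      if (p >= 1.0) continue;
      if (p <= 0.0 || unif_rand() >= p) mask[i] = false;
    }
  }
  // background false positives
  R_xlen_t nbg = n - nvess;
  if (p_bg > 0 && nbg > 0) {
    double ndots = Rf_rbinom((double)nbg, p_bg);
    for (int k = 0; k < (int)ndots; ++k) {
      R_xlen_t i = (R_xlen_t)std::floor(unif_rand() * n);
      if (i >= 0 && i < n) mask[i] = true;
    }
  }
  PutRNGstate();
  mask.attr("dim") = dim;
  return mask;
}

// ----------------------------------------------------- skeleton tracing ----

// Trace the skeleton into simple paths between endpoints/junctions, exclude
// voxels within excl_factor x local diameter of any junction, retain straight
// windows (max perpendicular deviation of a (2*half+1)-voxel window from its
// chord <= chord_tol voxels), and emit one measurement per connected straight
// run at the window of minimal deviation. Returns a matrix with columns
// (x, y, z [1-based voxel index], diameter_voxels, deviation_voxels).
// [[Rcpp::export]]
NumericMatrix cpp_measure_skeleton(LogicalVector skel, NumericVector edt,
                                   IntegerVector dim, int half,
                                   double chord_tol, double excl_factor) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<R_xlen_t> vox;
  std::vector<int> id(n, -1);
  for (R_xlen_t i = 0; i < n; ++i)
    if (skel[i]) { id[i] = (int)vox.size(); vox.push_back(i); }
  int nv = (int)vox.size();
  if (nv == 0) return NumericMatrix(0, 5);

  std::vector<int> vx(nv), vy(nv), vz(nv);
  for (int v = 0; v < nv; ++v) {
    R_xlen_t i = vox[v];
    vz[v] = (int)(i / ((R_xlen_t)nx * ny));
    int rem = (int)(i - (R_xlen_t)vz[v] * nx * ny);
    vy[v] = rem / nx; vx[v] = rem % nx;
  }

  // adjacency (26-connectivity)
  std::vector< std::vector<int> > adj(nv);
  for (int v = 0; v < nv; ++v) {
    for (int k = 0; k < 26; ++k) {
      int xx = vx[v] + NB.off[k][0], yy = vy[v] + NB.off[k][1], zz = vz[v] + NB.off[k][2];
      if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz) {
        int j = id[idx3(xx, yy, zz, nx, ny)];
        if (j >= 0) adj[v].push_back(j);
      }
    }
  }

  std::vector<char> junction(nv, 0), excluded(nv, 0);
  for (int v = 0; v < nv; ++v) junction[v] = adj[v].size() >= 3;

  // exclusion zones around junctions: Euclidean radius excl_factor * local
  // diameter (local diameter = 2 * EDT at the junction), walked along the
  // skeleton
  for (int b = 0; b < nv; ++b) {
    if (!junction[b]) continue;
    double rad = excl_factor * 2.0 * edt[vox[b]];
    double rad2 = rad * rad;
    std::vector<int> stack;
    std::vector<char> seen(nv, 0);
    stack.push_back(b); seen[b] = 1; excluded[b] = 1;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      for (size_t q = 0; q < adj[c].size(); ++q) {
        int j = adj[c][q];
        if (seen[j]) continue;
        double dx = vx[j] - vx[b], dy = vy[j] - vy[b], dz = vz[j] - vz[b];
        if (dx * dx + dy * dy + dz * dz <= rad2) {
          seen[j] = 1; excluded[j] = 1; stack.push_back(j);
        }
      }
    }
  }

  // path tracing between terminals (endpoints / junctions)
  std::vector<char> visited(nv, 0); // interior (degree-2) voxels
  std::vector< std::vector<int> > paths;

  for (int v = 0; v < nv; ++v) {
    if (adj[v].size() == 2 && !junction[v]) continue;
    for (size_t q = 0; q < adj[v].size(); ++q) {
      int nxt = adj[v][q];
      if (junction[nxt] || adj[nxt].size() != 2) continue; // no interior
      if (visited[nxt]) continue;
      std::vector<int> path;
      path.push_back(v);
      int prev = v, cur = nxt;
      while (true) {
        path.push_back(cur);
        if (junction[cur] || adj[cur].size() != 2) break;
        visited[cur] = 1;
        int nx2 = (adj[cur][0] == prev) ? adj[cur][1] : adj[cur][0];
        prev = cur; cur = nx2;
        if (cur == path[0] && (int)path.size() > 2) break; // closed back
      }
      paths.push_back(path);
    }
  }
  // leftover cycles of pure degree-2 voxels
  for (int v = 0; v < nv; ++v) {
    if (visited[v] || adj[v].size() != 2 || junction[v]) continue;
    std::vector<int> path;
    int prev = -1, cur = v;
    while (true) {
      path.push_back(cur);
      visited[cur] = 1;
      int nx2 = (prev == -1) ? adj[cur][0]
                             : ((adj[cur][0] == prev) ? adj[cur][1] : adj[cur][0]);
      prev = cur; cur = nx2;
      if (cur == v || adj[cur].size() != 2 || junction[cur] || visited[cur]) break;
    }
    paths.push_back(path);
  }

  std::vector<double> ox, oy, oz, od, ov;
  int wlen = 2 * half + 1;
  for (size_t p = 0; p < paths.size(); ++p) {
    const std::vector<int>& pa = paths[p];
    int len = (int)pa.size();
    if (len < wlen) continue;
    std::vector<double> dev(len, -1.0); // -1: not a valid window centre
    for (int i = half; i < len - half; ++i) {
      int c = pa[i];
      if (excluded[c] || junction[c]) continue;
      int a = pa[i - half], b = pa[i + half];
      double axx = vx[a], ayy = vy[a], azz = vz[a];
      double ux = vx[b] - axx, uy = vy[b] - ayy, uz = vz[b] - azz;
      double un = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (un < 1e-9) continue;
      ux /= un; uy /= un; uz /= un;
      double mx = 0.0;
      for (int j = i - half; j <= i + half; ++j) {
        double wx = vx[pa[j]] - axx, wy = vy[pa[j]] - ayy, wz = vz[pa[j]] - azz;
        double t = wx * ux + wy * uy + wz * uz;
        double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
        double dd = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dd > mx) mx = dd;
      }
      if (mx <= chord_tol) dev[i] = mx;
    }
    // one measurement per connected straight run, at minimal deviation
    int i = half;
    while (i < len - half) {
      if (dev[i] < 0) { ++i; continue; }
      int best = i;
      int j = i;
      while (j < len - half && dev[j] >= 0) {
        if (dev[j] < dev[best]) best = j;
        ++j;
      }
      int c = pa[best];
      ox.push_back(vx[c] + 1); oy.push_back(vy[c] + 1); oz.push_back(vz[c] + 1);
      od.push_back(2.0 * edt[vox[c]]);
      ov.push_back(dev[best]);
      i = j;
    }
  }

  NumericMatrix out((int)ox.size(), 5);
  for (int i = 0; i < (int)ox.size(); ++i) {
    out(i, 0) = ox[i]; out(i, 1) = oy[i]; out(i, 2) = oz[i];
    out(i, 3) = od[i]; out(i, 4) = ov[i];
  }
  colnames(out) = CharacterVector::create("x", "y", "z", "diameter_vox", "deviation_vox");
  return out;
}
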