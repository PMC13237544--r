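// Low-level geometry kernels: separable Gaussian smoothing of voxel
// volumes, marching-tetrahedra isosurfacing with edge-welded vertices,
// brute-force k-nearest-neighbour search, 3D Euclidean distance
// transform, and point-to-triangle-mesh distance.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------
// Separable Gaussian smoothing (zero padding). Voxel units for sigma.
// [[Rcpp::export(name = ".cpp_gauss_smooth3")]]
NumericVector cpp_gauss_smooth3(NumericVector vol, double sigma) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double ksum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    ksum += ker[i + rad];
  }
  for (auto &k : ker) k /= ksum;
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n, 0.0);
  auto at = [&](std::vector<double> &v, int i, int j, int k) -> double & {
    return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  };
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        int lo = std::max(0, i - rad), hi = std::min(nx - 1, i + rad);
        for (int q = lo; q <= hi; ++q) s += at(a, q, j, k) * ker[q - i + rad];
        at(b, i, j, k) = s;
      }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        double s = 0.0;
        int lo = std::max(0, j - rad), hi = std::min(ny - 1, j + rad);
        for (int q = lo; q <= hi; ++q) s += at(b, i, q, k) * ker[q - j + rad];
        at(a, i, j, k) = s;
      }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      for (int k = 0; k < nz; ++k) {
        double s = 0.0;
        int lo = std::max(0, k - rad), hi = std::min(nz - 1, k + rad);
        for (int q = lo; q <= hi; ++q) s += at(a, i, j, q) * ker[q - k + rad];
        at(b, i, j, k) = s;
      }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = d;
  return out;
}

// ---------------------------------------------------------------------
// Marching tetrahedra. Voxel centers at 0-based integer coordinates.
// Emits vertices (voxel units) welded on grid edges and triangles with
// outward orientation (normals point from values > level to < level).
// [[Rcpp::export(name = ".cpp_mt_isosurface")]]
List cpp_mt_isosurface(NumericVector vol, double level) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  auto F = [&](int i, int j, int k) {
    return vol[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  };
  auto gid = [&](int i, int j, int k) -> long long {
    return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
  };
  static const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6-tetra decomposition of the cube around diagonal 0-6
  static const int tets[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},
                                 {0,3,7,6},{0,7,4,6},{0,4,5,6}};
  std::unordered_map<long long, int> emap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tris;

  double cx[8], cy[8], cz[8], cf[8];
  long long cg[8];

  auto edge_vertex = [&](int a, int b) -> int {
    long long ga = cg[a], gb = cg[b];
    long long key = ga < gb ? ga * (long long)(nx * (long long)ny * nz) + gb
                            : gb * (long long)(nx * (long long)ny * nz) + ga;
    auto it = emap.find(key);
    if (it != emap.end()) return it->second;
    double fa = cf[a], fb = cf[b];
    double t = (level - fa) / (fb - fa);
    if (t < 1e-6) t = 1e-6;
    if (t > 1 - 1e-6) t = 1 - 1e-6;
    vx.push_back(cx[a] + t * (cx[b] - cx[a]));
    vy.push_back(cy[a] + t * (cy[b] - cy[a]));
    vz.push_back(cz[a] + t * (cz[b] - cz[a]));
    int id = (int)vx.size() - 1;
    emap[key] = id;
    return id;
  };

  auto add_tri = [&](int v0, int v1, int v2,
                     double ox, double oy, double oz) {
    if (v0 == v1 || v1 == v2 || v0 == v2) return;
    // orient so normal points along (ox,oy,oz): inside -> outside
    double ax = vx[v1] - vx[v0], ay = vy[v1] - vy[v0], az = vz[v1] - vz[v0];
    double bx = vx[v2] - vx[v0], by = vy[v2] - vy[v0], bz = vz[v2] - vz[v0];
    double nxn = ay * bz - az * by;
    double nyn = az * bx - ax * bz;
    double nzn = ax * by - ay * bx;
    if (nxn * ox + nyn * oy + nzn * oz < 0) std::swap(v1, v2);
    tris.push_back(v0); tris.push_back(v1); tris.push_back(v2);
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          cf[c] = F(ii, jj, kk);
          cx[c] = ii; cy[c] = jj; cz[c] = kk;
          cg[c] = gid(ii, jj, kk);
          if (cf[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int p[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], nin = 0, out[4], nout = 0;
          for (int q = 0; q < 4; ++q) {
            if (cf[p[q]] > level) in[nin++] = p[q];
            else out[nout++] = p[q];
          }
          if (nin == 0 || nin == 4) continue;
          // outward direction: centroid(out) - centroid(in)
          double ixc = 0, iyc = 0, izc = 0, oxc = 0, oyc = 0, ozc = 0;
          for (int q = 0; q < nin; ++q) {
            ixc += cx[in[q]]; iyc += cy[in[q]]; izc += cz[in[q]];
          }
          for (int q = 0; q < nout; ++q) {
            oxc += cx[out[q]]; oyc += cy[out[q]]; ozc += cz[out[q]];
          }
          double ox = oxc / nout - ixc / nin;
          double oy = oyc / nout - iyc / nin;
          double oz = ozc / nout - izc / nin;
          if (nin == 1) {
            int a = edge_vertex(in[0], out[0]);
            int b = edge_vertex(in[0], out[1]);
            int c2 = edge_vertex(in[0], out[2]);
            add_tri(a, b, c2, ox, oy, oz);
          } else if (nin == 3) {
            int a = edge_vertex(in[0], out[0]);
            int b = edge_vertex(in[1], out[0]);
            int c2 = edge_vertex(in[2], out[0]);
            add_tri(a, b, c2, ox, oy, oz);
          } else { // nin == 2, nout == 2 -> quad
            int a = edge_vertex(in[0], out[0]);
            int b = edge_vertex(in[0], out[1]);
            int c2 = edge_vertex(in[1], out[1]);
            int e = edge_vertex(in[1], out[0]);
            add_tri(a, b, c2, ox, oy, oz);
            add_tri(a, c2, e, ox, oy, oz);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)tris.size() / 3;
  NumericMatrix V(nv, 3);
  for (int q = 0; q < nv; ++q) {
    V(q, 0) = vx[q]; V(q, 1) = vy[q]; V(q, 2) = vz[q];
  }
  IntegerMatrix Fm(nf, 3);
  for (int q = 0; q < nf; ++q) {
    Fm(q, 0) = tris[3 * q] + 1;       // 1-based for R
    Fm(q, 1) = tris[3 * q + 1] + 1;
    Fm(q, 2) = tris[3 * q + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ---------------------------------------------------------------------
// Brute-force kNN: indices (1-based) and distances of the k nearest
// rows of ref for each row of query.
// [[Rcpp::export(name = ".cpp_knn_brute")]]
List cpp_knn_brute(NumericMatrix query, NumericMatrix ref, int k) {
  int nq = query.nrow(), nr = ref.nrow();
  if (k > nr) k = nr;
  IntegerMatrix idx(nq, k);
  NumericMatrix dst(nq, k);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
  }
  std::vector<double> bd(k);
  std::vector<int> bi(k);
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int nb = 0;
    for (int j = 0; j < nr; ++j) {
      double dx = rx[j] - qx, dy = ry[j] - qy, dz = rz[j] - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (nb < k) {
        int p = nb++;
        while (p > 0 && bd[p - 1] > d2) {
          bd[p] = bd[p - 1]; bi[p] = bi[p - 1]; --p;
        }
        bd[p] = d2; bi[p] = j;
      } else if (d2 < bd[k - 1]) {
        int p = k - 1;
        while (p > 0 && bd[p - 1] > d2) {
          bd[p] = bd[p - 1]; bi[p] = bi[p - 1]; --p;
        }
        bd[p] = d2; bi[p] = j;
      }
    }
    for (int q = 0; q < k; ++q) {
      idx(i, q) = bi[q] + 1;
      dst(i, q) = std::sqrt(bd[q]);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// ---------------------------------------------------------------------
// Uniform-grid accelerated kNN for 3D point sets.
struct GridNN {
  std::vector<double> px, py, pz;
  double x0, y0, z0, cell;
  int nx, ny, nz;
  std::vector<std::vector<int> > buckets;
  GridNN(const NumericMatrix &ref) {
    int n = ref.nrow();
    px.resize(n); py.resize(n); pz.resize(n);
    double xa = R_PosInf, xb = R_NegInf, ya = R_PosInf, yb = R_NegInf,
           za = R_PosInf, zb = R_NegInf;
    for (int i = 0; i < n; ++i) {
      px[i] = ref(i, 0); py[i] = ref(i, 1); pz[i] = ref(i, 2);
      xa = std::min(xa, px[i]); xb = std::max(xb, px[i]);
      ya = std::min(ya, py[i]); yb = std::max(yb, py[i]);
      za = std::min(za, pz[i]); zb = std::max(zb, pz[i]);
    }
    // regularize extents so nearly planar / collinear point sets do not
    // collapse the cell size
    double ex = xb - xa, ey = yb - ya, ez = zb - za;
    double maxext = std::max(ex, std::max(ey, ez));
    if (maxext <= 0) maxext = 1.0;
    ex = std::max(ex, 0.05 * maxext);
    ey = std::max(ey, 0.05 * maxext);
    ez = std::max(ez, 0.05 * maxext);
    double vol = ex * ey * ez;
    cell = std::cbrt(vol / std::max(n, 1)) * 1.5;
    if (!(cell > 0) || !std::isfinite(cell)) cell = 1.0;
    x0 = xa; y0 = ya; z0 = za;
    nx = std::max(1, (int)((xb - xa) / cell) + 1);
    ny = std::max(1, (int)((yb - ya) / cell) + 1);
    nz = std::max(1, (int)((zb - za) / cell) + 1);
    // cap the grid size
    while ((double)nx * ny * nz > 4e6) {
      cell *= 2;
      nx = std::max(1, (int)((xb - xa) / cell) + 1);
      ny = std::max(1, (int)((yb - ya) / cell) + 1);
      nz = std::max(1, (int)((zb - za) / cell) + 1);
    }
    buckets.resize((size_t)nx * ny * nz);
    for (int i = 0; i < n; ++i) {
      int cx = (int)((px[i] - x0) / cell), cy = (int)((py[i] - y0) / cell),
          cz = (int)((pz[i] - z0) / cell);
      buckets[(size_t)cx + (size_t)nx * ((size_t)cy + (size_t)ny * cz)]
        .push_back(i);
    }
  }
  // k nearest (indices 0-based, squared distances) of point q
  void query(double qx, double qy, double qz, int k,
             std::vector<int> &bi, std::vector<double> &bd) const {
    bi.clear(); bd.clear();
    int cx = (int)((qx - x0) / cell), cy = (int)((qy - y0) / cell),
        cz = (int)((qz - z0) / cell);
    int rmax = std::max(std::max(nx, ny), nz);
    for (int r = 0; r <= rmax; ++r) {
      // stop once the kth best is closer than any cell in ring r
      if ((int)bi.size() >= k && r >= 1) {
        double ring_min = (r - 1) * cell;
        if (bd[k - 1] <= ring_min * ring_min) break;
      }
      int xlo = std::max(cx - r, 0), xhi = std::min(cx + r, nx - 1);
      int ylo = std::max(cy - r, 0), yhi = std::min(cy + r, ny - 1);
      int zlo = std::max(cz - r, 0), zhi = std::min(cz + r, nz - 1);
      for (int ix = xlo; ix <= xhi; ++ix) {
        for (int iy = ylo; iy <= yhi; ++iy) {
          for (int iz = zlo; iz <= zhi; ++iz) {
            if (std::max(std::abs(ix - cx),
                std::max(std::abs(iy - cy), std::abs(iz - cz))) != r)
              continue;
            const std::vector<int> &b =
              buckets[(size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz)];
            for (size_t q = 0; q < b.size(); ++q) {
              int j = b[q];
              double dx = px[j] - qx, dy = py[j] - qy, dz = pz[j] - qz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if ((int)bi.size() < k) {
                int p = (int)bi.size();
                bi.push_back(j); bd.push_back(d2);
                while (p > 0 && bd[p - 1] > d2) {
                  bd[p] = bd[p - 1]; bi[p] = bi[p - 1]; --p;
                }
                bd[p] = d2; bi[p] = j;
              } else if (d2 < bd[k - 1]) {
                int p = k - 1;
                while (p > 0 && bd[p - 1] > d2) {
                  bd[p] = bd[p - 1]; bi[p] = bi[p - 1]; --p;
                }
                bd[p] = d2; bi[p] = j;
              }
            }
          }
        }
      }
    }
  }
};

// [[Rcpp::export(name = ".cpp_grid_knn")]]
List cpp_grid_knn(NumericMatrix query, NumericMatrix ref, int k) {
  int nq = query.nrow(), nr = ref.nrow();
  if (k > nr) k = nr;
  GridNN grid(ref);
  IntegerMatrix idx(nq, k);
  NumericMatrix dst(nq, k);
  std::vector<int> bi;
  std::vector<double> bd;
  for (int i = 0; i < nq; ++i) {
    grid.query(query(i, 0), query(i, 1), query(i, 2), k, bi, bd);
    for (int q = 0; q < k; ++q) {
      idx(i, q) = bi[q] + 1;
      dst(i, q) = std::sqrt(bd[q]);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// ---------------------------------------------------------------------
// Squared 1D distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double> &f, std::vector<double> &out) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) / (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = q - v[kk];
    out[q] = dq * dq + f[v[kk]];
  }
}

// Euclidean distance (voxel units) from each foreground voxel to the
// nearest background voxel; 0 on background. Volume boundary counts as
// background so tubes touching the edge stay finite.
// [[Rcpp::export(name = ".cpp_edt3")]]
NumericVector cpp_edt3(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t n = (size_t)nx * ny * nz;
  const double INF = 1e18;
  std::vector<double> g(n);
  for (size_t q = 0; q < n; ++q) g[q] = mask[q] ? INF : 0.0;
  auto at = [&](std::vector<double> &v, int i, int j, int k) -> double & {
    return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  };
  std::vector<double> f, o;
  // x
  f.resize(nx); o.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = at(g, i, j, k);
      dt1d(f, o);
      for (int i = 0; i < nx; ++i) at(g, i, j, k) = o[i];
    }
  // y
  f.resize(ny); o.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = at(g, i, j, k);
      dt1d(f, o);
      for (int j = 0; j < ny; ++j) at(g, i, j, k) = o[j];
    }
  // z
  f.resize(nz); o.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = at(g, i, j, k);
      dt1d(f, o);
      for (int k = 0; k < nz; ++k) at(g, i, j, k) = o[k];
    }
  NumericVector out(n);
  for (size_t q = 0; q < n; ++q) {
    double dd = g[q];
    // boundary clamp: distance to volume edge
    size_t rem = q;
    int i = (int)(rem % nx); rem /= nx;
    int j = (int)(rem % ny); rem /= ny;
    int k = (int)rem;
    if (mask[q]) {
      double be = std::min(std::min(i + 1, nx - i),
                  std::min(std::min(j + 1, ny - j), std::min(k + 1, nz - k)));
      if (be * be < dd) dd = be * be;
    }
    out[q] = std::sqrt(dd);
  }
  out.attr("dim") = d;
  return out;
}

// ---------------------------------------------------------------------
// Closest point on triangle (Ericson, Real-Time Collision Detection).
static double point_tri_d2(double px, double py, double pz,
                           const double *a, const double *b, const double *c) {
  double abx = b[0]-a[0], aby = b[1]-a[1], abz = b[2]-a[2];
  double acx = c[0]-a[0], acy = c[1]-a[1], acz = c[2]-a[2];
  double apx = px-a[0], apy = py-a[1], apz = pz-a[2];
  double d1 = abx*apx + aby*apy + abz*apz;
  double d2 = acx*apx + acy*apy + acz*apz;
  double qx, qy, qz;
  if (d1 <= 0 && d2 <= 0) { qx=a[0]; qy=a[1]; qz=a[2]; }
  else {
    double bpx = px-b[0], bpy = py-b[1], bpz = pz-b[2];
    double d3 = abx*bpx + aby*bpy + abz*bpz;
    double d4 = acx*bpx + acy*bpy + acz*bpz;
    if (d3 >= 0 && d4 <= d3) { qx=b[0]; qy=b[1]; qz=b[2]; }
    else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        qx=a[0]+v*abx; qy=a[1]+v*aby; qz=a[2]+v*abz;
      } else {
        double cpx = px-c[0], cpy = py-c[1], cpz = pz-c[2];
        double d5 = abx*cpx + aby*cpy + abz*cpz;
        double d6 = acx*cpx + acy*cpy + acz*cpz;
        if (d6 >= 0 && d5 <= d6) { qx=c[0]; qy=c[1]; qz=c[2]; }
        else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            qx=a[0]+w*acx; qy=a[1]+w*acy; qz=a[2]+w*acz;
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              qx=b[0]+w*(c[0]-b[0]); qy=b[1]+w*(c[1]-b[1]); qz=b[2]+w*(c[2]-b[2]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              qx=a[0]+abx*v+acx*w; qy=a[1]+aby*v+acy*w; qz=a[2]+abz*v+acz*w;
            }
          }
        }
      }
    }
  }
  double dx = px-qx, dy = py-qy, dz = pz-qz;
  return dx*dx + dy*dy + dz*dz;
}

// closest point on a triangle (same algorithm as point_tri_d2 but
// returning the point)
static void point_tri_closest(double px, double py, double pz,
                              const double *a, const double *b,
                              const double *c, double *q) {
  double abx = b[0]-a[0], aby = b[1]-a[1], abz = b[2]-a[2];
  double acx = c[0]-a[0], acy = c[1]-a[1], acz = c[2]-a[2];
  double apx = px-a[0], apy = py-a[1], apz = pz-a[2];
  double d1 = abx*apx + aby*apy + abz*apz;
  double d2 = acx*apx + acy*apy + acz*apz;
  if (d1 <= 0 && d2 <= 0) { q[0]=a[0]; q[1]=a[1]; q[2]=a[2]; return; }
  double bpx = px-b[0], bpy = py-b[1], bpz = pz-b[2];
  double d3 = abx*bpx + aby*bpy + abz*bpz;
  double d4 = acx*bpx + acy*bpy + acz*bpz;
  if (d3 >= 0 && d4 <= d3) { q[0]=b[0]; q[1]=b[1]; q[2]=b[2]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    q[0]=a[0]+v*abx; q[1]=a[1]+v*aby; q[2]=a[2]+v*abz; return;
  }
  double cpx = px-c[0], cpy = py-c[1], cpz = pz-c[2];
  double d5 = abx*cpx + aby*cpy + abz*cpz;
  double d6 = acx*cpx + acy*cpy + acz*cpz;
  if (d6 >= 0 && d5 <= d6) { q[0]=c[0]; q[1]=c[1]; q[2]=c[2]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    q[0]=a[0]+w*acx; q[1]=a[1]+w*acy; q[2]=a[2]+w*acz; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    q[0]=b[0]+w*(c[0]-b[0]); q[1]=b[1]+w*(c[1]-b[1]);
    q[2]=b[2]+w*(c[2]-b[2]); return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  q[0]=a[0]+abx*v+acx*w; q[1]=a[1]+aby*v+acy*w; q[2]=a[2]+abz*v+acz*w;
}

// Project points onto the triangulated surface: candidate faces are
// those incident to the 3 nearest vertices of each point.
// [[Rcpp::export(name = ".cpp_project_points")]]
List cpp_project_points(NumericMatrix pts, NumericMatrix V,
                        IntegerMatrix Fc) {
  int np = pts.nrow(), nv = V.nrow(), nf = Fc.nrow();
  std::vector<int> cnt(nv + 1, 0);
  for (int f = 0; f < nf; ++f)
    for (int q = 0; q < 3; ++q) cnt[Fc(f, q)]++;
  std::vector<int> start(nv + 1, 0);
  for (int v = 1; v <= nv; ++v) start[v] = start[v - 1] + cnt[v];
  std::vector<int> inc(start[nv]);
  std::vector<int> fill(nv, 0);
  for (int f = 0; f < nf; ++f)
    for (int q = 0; q < 3; ++q) {
      int v = Fc(f, q) - 1;
      inc[start[v] + fill[v]++] = f;
    }
  GridNN grid(V);
  NumericMatrix out(np, 3);
  NumericVector dist(np);
  std::vector<int> bi;
  std::vector<double> bd;
  double q3[3];
  for (int i = 0; i < np; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    grid.query(px, py, pz, std::min(3, nv), bi, bd);
    double best = bd[0];
    double bx = V(bi[0], 0), by = V(bi[0], 1), bz = V(bi[0], 2);
    for (size_t q = 0; q < bi.size(); ++q) {
      int v = bi[q];
      for (int s = start[v]; s < start[v + 1]; ++s) {
        int f = inc[s];
        double a[3] = {V(Fc(f,0)-1,0), V(Fc(f,0)-1,1), V(Fc(f,0)-1,2)};
        double b[3] = {V(Fc(f,1)-1,0), V(Fc(f,1)-1,1), V(Fc(f,1)-1,2)};
        double c[3] = {V(Fc(f,2)-1,0), V(Fc(f,2)-1,1), V(Fc(f,2)-1,2)};
        point_tri_closest(px, py, pz, a, b, c, q3);
        double dx = px-q3[0], dy = py-q3[1], dz = pz-q3[2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) {
          best = d2; bx = q3[0]; by = q3[1]; bz = q3[2];
        }
      }
    }
    out(i, 0) = bx; out(i, 1) = by; out(i, 2) = bz;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["points"] = out, _["dist"] = dist);
}

// Distance from each point to the triangulated surface: nearest 3
// vertices by brute force, min distance over their incident faces.
// [[Rcpp::export(name = ".cpp_point_mesh_dist")]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix V,
                                  IntegerMatrix Fc) {
  int np = pts.nrow(), nv = V.nrow(), nf = Fc.nrow();
  // vertex -> incident faces (CSR)
  std::vector<int> cnt(nv + 1, 0);
  for (int f = 0; f < nf; ++f)
    for (int q = 0; q < 3; ++q) cnt[Fc(f, q)]++;   // 1-based shifts
  std::vector<int> start(nv + 1, 0);
  for (int v = 1; v <= nv; ++v) start[v] = start[v - 1] + cnt[v];
  std::vector<int> inc(start[nv]);
  std::vector<int> fill(nv, 0);
  for (int f = 0; f < nf; ++f)
    for (int q = 0; q < 3; ++q) {
      int v = Fc(f, q) - 1;
      inc[start[v] + fill[v]++] = f;
    }
  NumericVector out(np);
  const int K = 3;
  GridNN grid(V);
  std::vector<int> bi;
  std::vector<double> bd;
  for (int i = 0; i < np; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    grid.query(px, py, pz, std::min(K, nv), bi, bd);
    int nb = (int)bi.size();
    double best = bd[0]; // at worst the nearest-vertex distance
    // incident faces of the nb nearest vertices
    for (int q = 0; q < nb; ++q) {
      int v = bi[q];
      for (int s = start[v]; s < start[v + 1]; ++s) {
        int f = inc[s];
        double a[3] = {V(Fc(f,0)-1,0), V(Fc(f,0)-1,1), V(Fc(f,0)-1,2)};
        double b[3] = {V(Fc(f,1)-1,0), V(Fc(f,1)-1,1), V(Fc(f,1)-1,2)};
        double c[3] = {V(Fc(f,2)-1,0), V(Fc(f,2)-1,1), V(Fc(f,2)-1,2)};
        double d2 = point_tri_d2(px, py, pz, a, b, c);
        if (d2 < best) best = d2;
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
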