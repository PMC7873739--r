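// Geometric queries against triangle meshes and voxel morphology.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

inline double dot3(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
inline void sub3(const double* a, const double* b, double* o) {
  o[0]=a[0]-b[0]; o[1]=a[1]-b[1]; o[2]=a[2]-b[2];
}

// closest point on triangle (Ericson, Real-Time Collision Detection)
void closest_on_tri(const double* p, const double* a, const double* b,
                    const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  sub3(b, a, ab); sub3(c, a, ac); sub3(p, a, ap);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) { for(int i=0;i<3;++i) out[i]=a[i]; return; }
  double bp[3]; sub3(p, b, bp);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) { for(int i=0;i<3;++i) out[i]=b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for(int i=0;i<3;++i) out[i]=a[i]+v*ab[i]; return;
  }
  double cp[3]; sub3(p, c, cp);
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) { for(int i=0;i<3;++i) out[i]=c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for(int i=0;i<3;++i) out[i]=a[i]+w*ac[i]; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for(int i=0;i<3;++i) out[i]=b[i]+w*(c[i]-b[i]); return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for(int i=0;i<3;++i) out[i]=a[i]+ab[i]*v+ac[i]*w;
}

struct TriGrid2D { // bins of triangle ids over the xy bounding box
  double x0, y0, cell;
  int nbx, nby;
  std::vector<std::vector<int>> bins;
};

TriGrid2D build_grid2d(const NumericMatrix& V, const IntegerMatrix& F) {
  TriGrid2D g;
  double x0=R_PosInf, x1=R_NegInf, y0=R_PosInf, y1=R_NegInf;
  for (int i = 0; i < V.nrow(); ++i) {
    x0 = std::min(x0, V(i,0)); x1 = std::max(x1, V(i,0));
    y0 = std::min(y0, V(i,1)); y1 = std::max(y1, V(i,1));
  }
  int nt = F.nrow();
  int target = std::max(8, (int)std::sqrt((double)nt));
  g.cell = std::max((x1-x0), (y1-y0)) / target;
  if (!(g.cell > 0)) g.cell = 1.0;
  g.x0 = x0 - 1e-9; g.y0 = y0 - 1e-9;
  g.nbx = std::max(1, (int)std::ceil((x1 - g.x0) / g.cell) + 1);
  g.nby = std::max(1, (int)std::ceil((y1 - g.y0) / g.cell) + 1);
  g.bins.assign((size_t)g.nbx * g.nby, {});
  for (int t = 0; t < nt; ++t) {
    double tx0=R_PosInf, tx1=R_NegInf, ty0=R_PosInf, ty1=R_NegInf;
    for (int c = 0; c < 3; ++c) {
      int v = F(t,c) - 1;
      tx0 = std::min(tx0, V(v,0)); tx1 = std::max(tx1, V(v,0));
      ty0 = std::min(ty0, V(v,1)); ty1 = std::max(ty1, V(v,1));
    }
    int ix0 = std::max(0, (int)((tx0 - g.x0)/g.cell));
    int ix1 = std::min(g.nbx-1, (int)((tx1 - g.x0)/g.cell));
    int iy0 = std::max(0, (int)((ty0 - g.y0)/g.cell));
    int iy1 = std::min(g.nby-1, (int)((ty1 - g.y0)/g.cell));
    for (int iy = iy0; iy <= iy1; ++iy)
      for (int ix = ix0; ix <= ix1; ++ix)
        g.bins[(size_t)iy*g.nbx + ix].push_back(t);
  }
  return g;
}

} // namespace

// Parity (even-odd) point-in-mesh test by casting a +z ray per query point.
// Query xy coordinates are nudged by a tiny deterministic offset so rays do
// not pass exactly through mesh vertices/edges.
// [[Rcpp::export(name = ".points_in_mesh_cpp")]]
LogicalVector points_in_mesh_cpp(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix F) {
  TriGrid2D g = build_grid2d(V, F);
  int n = P.nrow();
  LogicalVector out(n);
  const double eps = 1e-7;
  for (int q = 0; q < n; ++q) {
    double px = P(q,0) + eps * 0.718, py = P(q,1) + eps * 1.133, pz = P(q,2);
    int ix = (int)((px - g.x0)/g.cell), iy = (int)((py - g.y0)/g.cell);
    if (ix < 0 || iy < 0 || ix >= g.nbx || iy >= g.nby) { out[q] = false; continue; }
    int cross = 0;
    for (int t : g.bins[(size_t)iy*g.nbx + ix]) {
      int i0 = F(t,0)-1, i1 = F(t,1)-1, i2 = F(t,2)-1;
      double ax = V(i0,0)-px, ay = V(i0,1)-py;
      double bx = V(i1,0)-px, by = V(i1,1)-py;
      double cx = V(i2,0)-px, cy = V(i2,1)-py;
      // signed areas of projected sub-triangles
      double d1 = ax*by - ay*bx;
      double d2 = bx*cy - by*cx;
      double d3 = cx*ay - cy*ax;
      bool has_neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
      bool has_pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
      if (has_neg && has_pos) continue; // xy-projection misses triangle
      double area = d1 + d2 + d3;
      if (area == 0) continue; // degenerate in projection
      double w1 = d2 / area, w2 = d3 / area, w3 = d1 / area;
      double z = w1*V(i0,2) + w2*V(i1,2) + w3*V(i2,2);
      if (z > pz) ++cross;
    }
    out[q] = (cross % 2) == 1;
  }
  return out;
}

// All intersection parameters t (can be negative) of the line
// origin + t*dir with the mesh, sorted ascending.
// [[Rcpp::export(name = ".ray_mesh_hits_cpp")]]
NumericVector ray_mesh_hits_cpp(NumericVector origin, NumericVector dir,
                                NumericMatrix V, IntegerMatrix F) {
  std::vector<double> hits;
  double o[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  for (int t = 0; t < F.nrow(); ++t) {
    int i0 = F(t,0)-1, i1 = F(t,1)-1, i2 = F(t,2)-1;
    double a[3] = {V(i0,0), V(i0,1), V(i0,2)};
    double b[3] = {V(i1,0), V(i1,1), V(i1,2)};
    double c[3] = {V(i2,0), V(i2,1), V(i2,2)};
    double e1[3], e2[3];
    sub3(b, a, e1); sub3(c, a, e2);
    double p[3] = {d[1]*e2[2]-d[2]*e2[1], d[2]*e2[0]-d[0]*e2[2], d[0]*e2[1]-d[1]*e2[0]};
    double det = dot3(e1, p);
    if (std::fabs(det) < 1e-14) continue;
    double inv = 1.0/det;
    double s[3]; sub3(o, a, s);
    double u = dot3(s, p) * inv;
    if (u < -1e-12 || u > 1 + 1e-12) continue;
    double qv[3] = {s[1]*e1[2]-s[2]*e1[1], s[2]*e1[0]-s[0]*e1[2], s[0]*e1[1]-s[1]*e1[0]};
    double v = dot3(d, qv) * inv;
    if (v < -1e-12 || u + v > 1 + 1e-12) continue;
    hits.push_back(dot3(e2, qv) * inv);
  }
  std::sort(hits.begin(), hits.end());
  return wrap(hits);
}

// Closest point on a triangle mesh for each query point, via a uniform 3D
// triangle grid with expanding-shell search. Returns distance, closest point
// and (1-based) triangle id.
// [[Rcpp::export(name = ".closest_point_mesh_cpp")]]
List closest_point_mesh_cpp(NumericMatrix P, NumericMatrix V, IntegerMatrix F,
                            double max_dist = 1e300) {
  int nt = F.nrow(), nq = P.nrow();
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < V.nrow(); ++i)
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(lo[c], V(i,c));
      hi[c] = std::max(hi[c], V(i,c));
    }
  double ext = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2], 1e-9});
  int target = std::max(4, (int)std::cbrt((double)nt));
  double cell = ext / target;
  int nb[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] -= 1e-9;
    nb[c] = std::max(1, (int)std::ceil((hi[c]-lo[c]) / cell) + 1);
  }
  std::vector<std::vector<int>> bins((size_t)nb[0]*nb[1]*nb[2]);
  auto bidx = [&](int ix, int iy, int iz) {
    return (size_t)ix + (size_t)nb[0]*((size_t)iy + (size_t)nb[1]*iz);
  };
  for (int t = 0; t < nt; ++t) {
    double t0[3] = {R_PosInf,R_PosInf,R_PosInf}, t1[3] = {R_NegInf,R_NegInf,R_NegInf};
    for (int c = 0; c < 3; ++c) {
      int v = F(t,c)-1;
      for (int k = 0; k < 3; ++k) {
        t0[k] = std::min(t0[k], V(v,k));
        t1[k] = std::max(t1[k], V(v,k));
      }
    }
    int i0[3], i1[3];
    for (int k = 0; k < 3; ++k) {
      i0[k] = std::max(0, (int)((t0[k]-lo[k])/cell));
      i1[k] = std::min(nb[k]-1, (int)((t1[k]-lo[k])/cell));
    }
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix)
          bins[bidx(ix,iy,iz)].push_back(t);
  }

  NumericVector dist(nq);
  NumericMatrix CP(nq, 3);
  IntegerVector tri(nq);
  int maxshell = std::max({nb[0], nb[1], nb[2]});
  for (int q = 0; q < nq; ++q) {
    double p[3] = {P(q,0), P(q,1), P(q,2)};
    int ci[3];
    for (int k = 0; k < 3; ++k) {
      ci[k] = (int)((p[k]-lo[k])/cell);
      ci[k] = std::max(0, std::min(nb[k]-1, ci[k]));
    }
    double best = R_PosInf, bestp[3] = {0,0,0};
    int bestt = -1;
    for (int shell = 0; shell <= maxshell; ++shell) {
      // once a candidate is found, only shells that could still contain a
      // closer triangle need scanning; beyond max_dist the caller does not
      // need the exact value
      if (bestt >= 0 && (double)(shell-1) * cell > best) break;
      if ((double)(shell-1) * cell > max_dist) break;
      bool any = false;
      int x0 = std::max(0, ci[0]-shell), x1 = std::min(nb[0]-1, ci[0]+shell);
      int y0 = std::max(0, ci[1]-shell), y1 = std::min(nb[1]-1, ci[1]+shell);
      int z0 = std::max(0, ci[2]-shell), z1 = std::min(nb[2]-1, ci[2]+shell);
      for (int iz = z0; iz <= z1; ++iz)
        for (int iy = y0; iy <= y1; ++iy)
          for (int ix = x0; ix <= x1; ++ix) {
            // only the surface of the shell
            if (shell > 0 &&
                ix != ci[0]-shell && ix != ci[0]+shell &&
                iy != ci[1]-shell && iy != ci[1]+shell &&
                iz != ci[2]-shell && iz != ci[2]+shell) continue;
            any = true;
            for (int t : bins[bidx(ix,iy,iz)]) {
              int i0 = F(t,0)-1, i1 = F(t,1)-1, i2 = F(t,2)-1;
              double a[3] = {V(i0,0), V(i0,1), V(i0,2)};
              double b[3] = {V(i1,0), V(i1,1), V(i1,2)};
              double c[3] = {V(i2,0), V(i2,1), V(i2,2)};
              double cp[3];
              closest_on_tri(p, a, b, c, cp);
              double dd = 0;
              for (int k = 0; k < 3; ++k) dd += (cp[k]-p[k])*(cp[k]-p[k]);
              dd = std::sqrt(dd);
              if (dd < best) { best = dd; bestt = t; for (int k=0;k<3;++k) bestp[k]=cp[k]; }
            }
          }
      if (!any && shell > maxshell) break;
    }
    dist[q] = best;
    tri[q] = bestt + 1;
    for (int k = 0; k < 3; ++k) CP(q,k) = bestp[k];
  }
  return List::create(_["distance"] = dist, _["point"] = CP, _["face"] = tri);
}

// 26-connected component labelling of a logical 3D array.
// [[Rcpp::export(name = ".label_components_cpp")]]
List label_components_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int64_t n = (int64_t)nx*ny*nz;
  IntegerVector lab(n);
  std::vector<int64_t> sizes;
  std::vector<int64_t> stack;
  int cur = 0;
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    int64_t sz = 0;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      int64_t v = stack.back(); stack.pop_back();
      ++sz;
      int k = (int)(v / ((int64_t)nx*ny));
      int64_t r = v - (int64_t)k*nx*ny;
      int j = (int)(r / nx), i = (int)(r - (int64_t)j*nx);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i+di, jj = j+dj, kk = k+dk;
            if (ii<0||jj<0||kk<0||ii>=nx||jj>=ny||kk>=nz) continue;
            int64_t w = (int64_t)ii + (int64_t)nx*((int64_t)jj + (int64_t)ny*kk);
            if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
          }
    }
    sizes.push_back(sz);
  }
  lab.attr("dim") = dims;
  NumericVector szs(sizes.size());
  for (size_t i = 0; i < sizes.size(); ++i) szs[i] = (double)sizes[i];
  return List::create(_["labels"] = lab, _["sizes"] = szs);
}

// Slice-wise (2D, 4-connected) hole filling along the third axis: background
// not reachable from the slice border becomes foreground.
// [[Rcpp::export(name = ".fill_holes_2d_cpp")]]
LogicalVector fill_holes_2d_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out = clone(mask);
  std::vector<char> reach((size_t)nx*ny);
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k) {
    int64_t base = (int64_t)k*nx*ny;
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    auto push = [&](int i, int j) {
      int idx = i + nx*j;
      if (!reach[idx] && !mask[base + idx]) { reach[idx] = 1; stack.push_back(idx); }
    };
    for (int i = 0; i < nx; ++i) { push(i, 0); push(i, ny-1); }
    for (int j = 0; j < ny; ++j) { push(0, j); push(nx-1, j); }
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      int j = idx / nx, i = idx - nx*j;
      if (i > 0) push(i-1, j);
      if (i < nx-1) push(i+1, j);
      if (j > 0) push(i, j-1);
      if (j < ny-1) push(i, j+1);
    }
    for (int idx = 0; idx < nx*ny; ++idx)
      if (!mask[base+idx] && !reach[idx]) out[base+idx] = true;
  }
  out.attr("dim") = dims;
  return out;
}
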