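// Isosurface extraction by marching tetrahedra on a regular voxel lattice.
// Each lattice cell (8 voxel centers) is split into the 6 Kuhn tetrahedra
// sharing the main diagonal; the decomposition is translation-consistent, so
// faces match across cells and the output is watertight by construction.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct VKey {
  uint64_t k;
  bool operator==(const VKey& o) const { return k == o.k; }
};
struct VKeyHash {
  size_t operator()(const VKey& v) const { return std::hash<uint64_t>()(v.k); }
};

// corner bit layout: bit0 = +x, bit1 = +y, bit2 = +z
const int KUHN_TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

} // namespace

// [[Rcpp::export(name = ".marching_tets_cpp")]]
List marching_tets_cpp(NumericVector field, IntegerVector dims,
                       double iso, NumericVector spacing,
                       NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  std::unordered_map<VKey, int, VKeyHash> vmap;
  std::vector<double> verts;   // xyz triples
  std::vector<int> tris;       // 0-based vertex index triples

  auto gidx = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };
  auto val = [&](int64_t g) -> double { return field[g]; };
  auto coord = [&](int64_t g, double* p) {
    int k = (int)(g / ((int64_t)nx * ny));
    int64_t r = g - (int64_t)k * nx * ny;
    int j = (int)(r / nx);
    int i = (int)(r - (int64_t)j * nx);
    p[0] = ox + i * sx; p[1] = oy + j * sy; p[2] = oz + k * sz;
  };

  // vertex on the edge between lattice points g1 and g2 (deduplicated)
  auto edge_vertex = [&](int64_t g1, int64_t g2) -> int {
    if (g1 > g2) std::swap(g1, g2);
    VKey key{ (uint64_t)g1 * 0x100000000ULL ^ (uint64_t)g2 };
    // combine uniquely: g1 < g2 < 2^31 so pack into 64 bits
    key.k = ((uint64_t)g1 << 32) | (uint64_t)g2;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double v1 = val(g1), v2 = val(g2);
    double t = (v2 == v1) ? 0.5 : (iso - v1) / (v2 - v1);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double p1[3], p2[3];
    coord(g1, p1); coord(g2, p2);
    int id = (int)(verts.size() / 3);
    for (int c = 0; c < 3; ++c) verts.push_back(p1[c] + t * (p2[c] - p1[c]));
    vmap.emplace(key, id);
    return id;
  };

  // emit a triangle with outward orientation (normal away from inside region)
  auto emit = [&](int a, int b, int c, const double* in_pt, const double* out_pt) {
    const double* p0 = &verts[3 * a];
    const double* p1 = &verts[3 * b];
    const double* p2 = &verts[3 * c];
    double u[3] = {p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2]};
    double v[3] = {p2[0]-p0[0], p2[1]-p0[1], p2[2]-p0[2]};
    double n[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0]};
    double d[3] = {out_pt[0]-in_pt[0], out_pt[1]-in_pt[1], out_pt[2]-in_pt[2]};
    double s = n[0]*d[0] + n[1]*d[1] + n[2]*d[2];
    if (s >= 0) { tris.push_back(a); tris.push_back(b); tris.push_back(c); }
    else        { tris.push_back(a); tris.push_back(c); tris.push_back(b); }
  };

  int64_t cg[8];
  double cpt[8][3];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        // quick reject: all 8 corners on one side
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cg[c] = gidx(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          if (val(cg[c]) >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int c = 0; c < 8; ++c) coord(cg[c], cpt[c]);
        for (int t = 0; t < 6; ++t) {
          int64_t tg[4];
          const double* tp[4];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            int corner = KUHN_TETS[t][c];
            tg[c] = cg[corner];
            tp[c] = cpt[corner];
            in[c] = val(tg[c]) >= iso;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // centroids of inside / outside vertices for orientation
          double cin[3] = {0,0,0}, cout[3] = {0,0,0};
          for (int c = 0; c < 4; ++c)
            for (int d = 0; d < 3; ++d)
              (in[c] ? cin : cout)[d] += tp[c][d];
          for (int d = 0; d < 3; ++d) { cin[d] /= nin; cout[d] /= (4 - nin); }

          if (nin == 1 || nin == 3) {
            int apex = -1;
            bool apex_in = (nin == 1);
            for (int c = 0; c < 4; ++c) if (in[c] == apex_in) apex = c;
            int others[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != apex) others[m++] = c;
            int v0 = edge_vertex(tg[apex], tg[others[0]]);
            int v1 = edge_vertex(tg[apex], tg[others[1]]);
            int v2 = edge_vertex(tg[apex], tg[others[2]]);
            emit(v0, v1, v2, cin, cout);
          } else { // 2-2: quad split into two triangles
            int a[2], b[2], na = 0, nb = 0;
            for (int c = 0; c < 4; ++c) (in[c] ? a[na++] : b[nb++]) = c;
            int v00 = edge_vertex(tg[a[0]], tg[b[0]]);
            int v01 = edge_vertex(tg[a[0]], tg[b[1]]);
            int v10 = edge_vertex(tg[a[1]], tg[b[0]]);
            int v11 = edge_vertex(tg[a[1]], tg[b[1]]);
            emit(v00, v01, v11, cin, cout);
            emit(v00, v11, v10, cin, cout);
          }
        }
      }
    }
  }

  NumericMatrix V(verts.size() / 3, 3);
  for (size_t r = 0; r < verts.size() / 3; ++r)
    for (int c = 0; c < 3; ++c) V(r, c) = verts[3 * r + c];
  IntegerMatrix F(tris.size() / 3, 3);
  for (size_t r = 0; r < tris.size() / 3; ++r)
    for (int c = 0; c < 3; ++c) F(r, c) = tris[3 * r + c] + 1; // 1-based for R
  return List::create(_["vertices"] = V, _["faces"] = F);
}
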