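// Isoparametric 10-node tetrahedron (C3D10) linear-elastic stiffness
// assembly. Straight-edged elements (constant Jacobian), 4-point Gauss rule.
// Returns lower-triangle triplets (1-based dof indices) for sparse assembly.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double GA = 0.5854101966249685; // 4-pt Gauss barycentric coords
const double GB = 0.1381966011250105;

// dN/dL for the 10 shape functions at barycentric point L (4 components).
// Node order: corners 1-4; midsides (1,2),(2,3),(1,3),(1,4),(2,4),(3,4).
void shape_grad_L(const double* L, double dNdL[10][4]) {
  for (int i = 0; i < 10; ++i)
    for (int a = 0; a < 4; ++a) dNdL[i][a] = 0.0;
  for (int i = 0; i < 4; ++i) dNdL[i][i] = 4.0 * L[i] - 1.0;
  const int pairs[6][2] = {{0,1},{1,2},{0,2},{0,3},{1,3},{2,3}};
  for (int m = 0; m < 6; ++m) {
    int a = pairs[m][0], b = pairs[m][1];
    dNdL[4+m][a] = 4.0 * L[b];
    dNdL[4+m][b] = 4.0 * L[a];
  }
}

} // namespace

// [[Rcpp::export(name = ".tet10_assemble_cpp")]]
List tet10_assemble_cpp(NumericMatrix nodes, IntegerMatrix elems,
                        NumericVector Evec, NumericVector nuvec) {
  int ne = elems.nrow();
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t)ne * 465);
  tj.reserve((size_t)ne * 465);
  tx.reserve((size_t)ne * 465);

  const double gp[4][4] = {
    {GA, GB, GB, GB}, {GB, GA, GB, GB}, {GB, GB, GA, GB}, {GB, GB, GB, GA}
  };
  double dNdL[10][4];

  for (int e = 0; e < ne; ++e) {
    // corner coordinates
    double X[4][3];
    for (int c = 0; c < 4; ++c) {
      int nid = elems(e, c) - 1;
      for (int k = 0; k < 3; ++k) X[c][k] = nodes(nid, k);
    }
    // A = [1 x y z] rows; gradients of barycentric coords from A^{-1}
    double A[4][4], Ainv[4][4];
    for (int r = 0; r < 4; ++r) {
      A[r][0] = 1.0;
      for (int k = 0; k < 3; ++k) A[r][k+1] = X[r][k];
    }
    // Gauss-Jordan 4x4 inverse
    double M[4][8];
    for (int r = 0; r < 4; ++r)
      for (int c = 0; c < 4; ++c) { M[r][c] = A[r][c]; M[r][c+4] = (r==c) ? 1.0 : 0.0; }
    double det = 1.0;
    for (int col = 0; col < 4; ++col) {
      int piv = col;
      for (int r = col+1; r < 4; ++r)
        if (std::fabs(M[r][col]) > std::fabs(M[piv][col])) piv = r;
      if (piv != col) { for (int c = 0; c < 8; ++c) std::swap(M[piv][c], M[col][c]); det = -det; }
      double d = M[col][col];
      det *= d;
      if (d == 0.0) stop("degenerate tetrahedron in element %d", e + 1);
      for (int c = 0; c < 8; ++c) M[col][c] /= d;
      for (int r = 0; r < 4; ++r) {
        if (r == col) continue;
        double f = M[r][col];
        if (f != 0.0)
          for (int c = 0; c < 8; ++c) M[r][c] -= f * M[col][c];
      }
    }
    for (int r = 0; r < 4; ++r)
      for (int c = 0; c < 4; ++c) Ainv[r][c] = M[r][c+4];
    double vol = det / 6.0;
    if (vol <= 0) stop("non-positive element volume in element %d", e + 1);
    // grad L_a = column a of Ainv rows 1..3  (L = Ainv^T [1 x y z]^T)
    double gL[4][3];
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < 3; ++k) gL[a][k] = Ainv[k+1][a];

    double E = Evec[e], nu = nuvec[e];
    double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
    double mu = E / (2.0 * (1.0 + nu));

    double Ke[30][30];
    for (int r = 0; r < 30; ++r)
      for (int c = 0; c < 30; ++c) Ke[r][c] = 0.0;

    for (int g = 0; g < 4; ++g) {
      shape_grad_L(gp[g], dNdL);
      double dN[10][3];
      for (int i = 0; i < 10; ++i)
        for (int k = 0; k < 3; ++k) {
          double s = 0;
          for (int a = 0; a < 4; ++a) s += dNdL[i][a] * gL[a][k];
          dN[i][k] = s;
        }
      double w = vol / 4.0;
      // K_ab (3x3 block) = w * [ lam * dNa ⊗ dNb + mu * (dNb ⊗ dNa) + mu * (dNa·dNb) I ]
      for (int i = 0; i < 10; ++i) {
        for (int j = 0; j < 10; ++j) {
          double dotij = dN[i][0]*dN[j][0] + dN[i][1]*dN[j][1] + dN[i][2]*dN[j][2];
          for (int r = 0; r < 3; ++r)
            for (int c = 0; c < 3; ++c) {
              double v = lam * dN[i][r] * dN[j][c] + mu * dN[i][c] * dN[j][r];
              if (r == c) v += mu * dotij;
              Ke[3*i + r][3*j + c] += w * v;
            }
        }
      }
    }

    int gd[30];
    for (int i = 0; i < 10; ++i) {
      int nid = elems(e, i) - 1;
      for (int k = 0; k < 3; ++k) gd[3*i + k] = 3*nid + k; // 0-based dof
    }
    for (int p = 0; p < 30; ++p)
      for (int q = p; q < 30; ++q) {
        int I = gd[p], J = gd[q];
        if (I < J) std::swap(I, J);
        ti.push_back(I + 1);
        tj.push_back(J + 1);
        tx.push_back(Ke[p][q]);
      }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}
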