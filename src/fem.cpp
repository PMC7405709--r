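// Nonlinear total-Lagrangian FEM core for incompressible Ogden solids on
// 8-node hexahedra. Deviatoric response is integrated at 2x2x2 Gauss
// points through a spectral (principal-stretch) Ogden stress; the
// volumetric penalty is integrated at the element centre (selective
// reduced integration, which avoids volumetric locking of the trilinear
// brick). Element tangents are finite-difference perturbations of the
// exact internal-force routine, so material and geometric stiffness are
// captured consistently. Follower pressure acts on oriented quad facets of
// the deformed inner surface. Crack faces are handled by node-pair
// penalties (free / unilateral contact / bonded).
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double GP = 0.5773502691896257; // 1/sqrt(3)

// hex node natural coordinates
static const double XI[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
static const double ET[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
static const double ZE[8] = {-1, -1, -1, -1, 1, 1, 1, 1};

struct QuadPoint {
  double dNdX[8][3];
  double wdet;
};

// shape-function derivatives in natural coordinates at (xi, eta, zeta)
static void shape_grad_nat(double xi, double eta, double zeta,
                           double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    dN[a][0] = 0.125 * XI[a] * (1 + ET[a] * eta) * (1 + ZE[a] * zeta);
    dN[a][1] = 0.125 * ET[a] * (1 + XI[a] * xi) * (1 + ZE[a] * zeta);
    dN[a][2] = 0.125 * ZE[a] * (1 + XI[a] * xi) * (1 + ET[a] * eta);
  }
}

static double det3(const double A[3][3]) {
  return A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
         A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
         A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
}

static bool inv3(const double A[3][3], double Ai[3][3]) {
  double d = det3(A);
  if (d == 0.0) return false;
  double id = 1.0 / d;
  Ai[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) * id;
  Ai[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) * id;
  Ai[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) * id;
  Ai[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) * id;
  Ai[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) * id;
  Ai[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) * id;
  Ai[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) * id;
  Ai[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) * id;
  Ai[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) * id;
  return true;
}

// geometry (reference gradients and weights) of one element:
// 8 Gauss points + centre point (index 8, weight 8)
static bool element_geometry(const double Xe[8][3], QuadPoint qp[9]) {
  double pts[9][3];
  int q = 0;
  for (int k = 0; k < 2; ++k)
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < 2; ++i) {
        pts[q][0] = (i ? GP : -GP);
        pts[q][1] = (j ? GP : -GP);
        pts[q][2] = (k ? GP : -GP);
        ++q;
      }
  pts[8][0] = pts[8][1] = pts[8][2] = 0.0;
  for (q = 0; q < 9; ++q) {
    double dN[8][3];
    shape_grad_nat(pts[q][0], pts[q][1], pts[q][2], dN);
    double J0[3][3] = {{0}};
    for (int a = 0; a < 8; ++a)
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k) J0[j][k] += Xe[a][j] * dN[a][k];
    double d = det3(J0);
    if (d <= 0.0) return false;
    double Ji[3][3];
    inv3(J0, Ji);
    for (int a = 0; a < 8; ++a)
      for (int j = 0; j < 3; ++j) {
        qp[q].dNdX[a][j] = dN[a][0] * Ji[0][j] + dN[a][1] * Ji[1][j] +
                           dN[a][2] * Ji[2][j];
      }
    qp[q].wdet = (q < 8 ? 1.0 : 8.0) * d;
  }
  return true;
}

// cyclic Jacobi eigensolver for symmetric 3x3; eigenvalues in w,
// eigenvectors in columns of V
static void eig_sym3(const double Ain[3][3], double w[3], double V[3][3]) {
  double A[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      A[i][j] = Ain[i][j];
      V[i][j] = (i == j) ? 1.0 : 0.0;
    }
  for (int sweep = 0; sweep < 24; ++sweep) {
    double off = std::fabs(A[0][1]) + std::fabs(A[0][2]) + std::fabs(A[1][2]);
    if (off < 1e-15 * (std::fabs(A[0][0]) + std::fabs(A[1][1]) +
                       std::fabs(A[2][2]) + 1e-300))
      break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(A[p][q]) < 1e-300) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0);
        double s = t * c;
        double tau = s / (1.0 + c);
        double app = A[p][p], aqq = A[q][q], apq = A[p][q];
        A[p][p] = app - t * apq;
        A[q][q] = aqq + t * apq;
        A[p][q] = A[q][p] = 0.0;
        for (int r = 0; r < 3; ++r) {
          if (r != p && r != q) {
            double arp = A[r][p], arq = A[r][q];
            A[r][p] = A[p][r] = arp - s * (arq + tau * arp);
            A[r][q] = A[q][r] = arq + s * (arp - tau * arq);
          }
          double vrp = V[r][p], vrq = V[r][q];
          V[r][p] = vrp - s * (vrq + tau * vrp);
          V[r][q] = vrq + s * (vrp - tau * vrq);
        }
      }
  }
  w[0] = A[0][0];
  w[1] = A[1][1];
  w[2] = A[2][2];
}

struct Material {
  std::vector<double> mu, alpha;
  double kappa; // penalty bulk modulus (MPa)
};

// internal force of one element; returns false on an inverted configuration
static bool hex_internal_force(const QuadPoint qp[9], const double ue[24],
                               const Material& mat, double fe[24]) {
  for (int i = 0; i < 24; ++i) fe[i] = 0.0;
  const int nterm = (int)mat.mu.size();
  for (int q = 0; q < 9; ++q) {
    // deformation gradient F = I + u^T dNdX
    double F[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          F[i][j] += ue[3 * a + i] * qp[q].dNdX[a][j];
    double J = det3(F);
    if (J <= 0.0) return false;
    double S[3][3] = {{0}};
    if (q < 8) {
      // deviatoric Ogden via spectral decomposition of C
      double C[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          C[i][j] = 0.0;
          for (int k = 0; k < 3; ++k) C[i][j] += F[k][i] * F[k][j];
        }
      double cw[3], V[3][3];
      eig_sym3(C, cw, V);
      double Jm13 = std::pow(J, -1.0 / 3.0);
      double lb[3];
      for (int a = 0; a < 3; ++a) {
        if (cw[a] <= 0.0) return false;
        lb[a] = Jm13 * std::sqrt(cw[a]);
      }
      double tau[3] = {0, 0, 0};
      for (int t = 0; t < nterm; ++t) {
        double p0 = std::pow(lb[0], mat.alpha[t]);
        double p1 = std::pow(lb[1], mat.alpha[t]);
        double p2 = std::pow(lb[2], mat.alpha[t]);
        double mean = (p0 + p1 + p2) / 3.0;
        tau[0] += mat.mu[t] * (p0 - mean);
        tau[1] += mat.mu[t] * (p1 - mean);
        tau[2] += mat.mu[t] * (p2 - mean);
      }
      for (int a = 0; a < 3; ++a) {
        double Sa = tau[a] / cw[a]; // S = sum tau_a / lambda_a^2 m_a m_a^T
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) S[i][j] += Sa * V[i][a] * V[j][a];
      }
    } else {
      // volumetric penalty at the centre point: S = kappa J (J-1) C^{-1}
      double C[3][3], Ci[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          C[i][j] = 0.0;
          for (int k = 0; k < 3; ++k) C[i][j] += F[k][i] * F[k][j];
        }
      if (!inv3(C, Ci)) return false;
      double fac = mat.kappa * J * (J - 1.0);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) S[i][j] = fac * Ci[i][j];
    }
    // P = F S ; f_a += wdet * P dN_a
    double P[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        P[i][j] = 0.0;
        for (int k = 0; k < 3; ++k) P[i][j] += F[i][k] * S[k][j];
      }
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        double v = 0.0;
        for (int j = 0; j < 3; ++j) v += P[i][j] * qp[q].dNdX[a][j];
        fe[3 * a + i] += qp[q].wdet * v;
      }
  }
  return true;
}

// [[Rcpp::export]]
List fem_hex_detj(NumericMatrix nodes, IntegerMatrix elems) {
  int E = elems.nrow();
  NumericVector mind(E), vol(E);
  for (int e = 0; e < E; ++e) {
    double Xe[8][3];
    for (int a = 0; a < 8; ++a)
      for (int j = 0; j < 3; ++j) Xe[a][j] = nodes(elems(e, a) - 1, j);
    QuadPoint qp[9];
    if (!element_geometry(Xe, qp)) {
      mind[e] = -1.0;
      vol[e] = NA_REAL;
      continue;
    }
    double mn = R_PosInf, v = 0.0;
    for (int q = 0; q < 8; ++q) {
      mn = std::min(mn, qp[q].wdet);
      v += qp[q].wdet;
    }
    mind[e] = mn;
    vol[e] = v;
  }
  return List::create(_["min_detj"] = mind, _["volume"] = vol);
}

// [[Rcpp::export]]
List fem_assemble(NumericMatrix nodes, IntegerMatrix elems,
                  IntegerVector region, NumericVector u, List materials,
                  IntegerMatrix pfacets, double pressure,
                  IntegerMatrix pairs, NumericMatrix pair_normals,
                  NumericVector pair_k, int contact_mode, bool want_tangent,
                  double fd_h) {
  const int N = nodes.nrow();
  const int E = elems.nrow();
  const int ndof = 3 * N;

  std::vector<Material> mats(materials.size());
  for (int m = 0; m < materials.size(); ++m) {
    List mm = materials[m];
    NumericVector mu = mm["mu"], al = mm["alpha"];
    mats[m].mu.assign(mu.begin(), mu.end());
    mats[m].alpha.assign(al.begin(), al.end());
    mats[m].kappa = as<double>(mm["kappa"]);
  }

  NumericVector fint(ndof), fext(ndof);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve((size_t)E * 576 + pairs.nrow() * 36);
    tj.reserve((size_t)E * 576 + pairs.nrow() * 36);
    tx.reserve((size_t)E * 576 + pairs.nrow() * 36);
  }

  double Xe[8][3], ue[24], fe[24], fp[24], up[24];
  QuadPoint qp[9];
  for (int e = 0; e < E; ++e) {
    int conn[8];
    for (int a = 0; a < 8; ++a) {
      conn[a] = elems(e, a) - 1;
      for (int j = 0; j < 3; ++j) {
        Xe[a][j] = nodes(conn[a], j);
        ue[3 * a + j] = u[3 * conn[a] + j];
      }
    }
    if (!element_geometry(Xe, qp))
      stop("element %d has a non-positive reference Jacobian", e + 1);
    const Material& mat = mats[region[e] - 1];
    if (!hex_internal_force(qp, ue, mat, fe))
      stop("element %d inverted during the solve", e + 1);
    for (int a = 0; a < 8; ++a)
      for (int j = 0; j < 3; ++j) fint[3 * conn[a] + j] += fe[3 * a + j];
    if (want_tangent) {
      // central differences: the tangent asymmetry must stay far below the
      // reciprocal condition number of the global matrix for the symmetric
      // factorisation to deliver accurate Newton directions
      double fm[24];
      for (int k = 0; k < 24; ++k) {
        for (int i = 0; i < 24; ++i) up[i] = ue[i];
        up[k] += fd_h;
        if (!hex_internal_force(qp, up, mat, fp))
          stop("element %d inverted during tangent evaluation", e + 1);
        up[k] = ue[k] - fd_h;
        if (!hex_internal_force(qp, up, mat, fm))
          stop("element %d inverted during tangent evaluation", e + 1);
        int gk = 3 * conn[k / 3] + (k % 3);
        for (int i = 0; i < 24; ++i) {
          double kij = (fp[i] - fm[i]) / (2.0 * fd_h);
          if (kij != 0.0) {
            ti.push_back(3 * conn[i / 3] + (i % 3) + 1);
            tj.push_back(gk + 1);
            tx.push_back(kij);
          }
        }
      }
    }
  }

  // follower pressure on oriented quad facets of the deformed surface
  if (pressure != 0.0 && pfacets.nrow() > 0) {
    const double g2[2] = {-GP, GP};
    for (int f = 0; f < pfacets.nrow(); ++f) {
      int cn[4];
      double x[4][3];
      for (int a = 0; a < 4; ++a) {
        cn[a] = pfacets(f, a) - 1;
        for (int j = 0; j < 3; ++j) x[a][j] = nodes(cn[a], j) + u[3 * cn[a] + j];
      }
      for (int gi = 0; gi < 2; ++gi)
        for (int gj = 0; gj < 2; ++gj) {
          double xi = g2[gi], eta = g2[gj];
          double Nv[4] = {0.25 * (1 - xi) * (1 - eta),
                          0.25 * (1 + xi) * (1 - eta),
                          0.25 * (1 + xi) * (1 + eta),
                          0.25 * (1 - xi) * (1 + eta)};
          double dxi[3] = {0, 0, 0}, det_[3] = {0, 0, 0};
          double dN_xi[4] = {-0.25 * (1 - eta), 0.25 * (1 - eta),
                             0.25 * (1 + eta), -0.25 * (1 + eta)};
          double dN_eta[4] = {-0.25 * (1 - xi), -0.25 * (1 + xi),
                              0.25 * (1 + xi), 0.25 * (1 - xi)};
          for (int a = 0; a < 4; ++a)
            for (int j = 0; j < 3; ++j) {
              dxi[j] += dN_xi[a] * x[a][j];
              det_[j] += dN_eta[a] * x[a][j];
            }
          double nrm[3] = {dxi[1] * det_[2] - dxi[2] * det_[1],
                           dxi[2] * det_[0] - dxi[0] * det_[2],
                           dxi[0] * det_[1] - dxi[1] * det_[0]};
          for (int a = 0; a < 4; ++a)
            for (int j = 0; j < 3; ++j)
              fext[3 * cn[a] + j] += pressure * Nv[a] * nrm[j];
          if (want_tangent) {
            // follower-load stiffness: dn_i/dx_{b,j} = eps_{ijk}
            // (dN_xi_b x_eta - dN_eta_b x_xi)_k; enters the tangent as
            // -dfext/du
            for (int b = 0; b < 4; ++b) {
              double w[3];
              for (int k = 0; k < 3; ++k)
                w[k] = dN_xi[b] * det_[k] - dN_eta[b] * dxi[k];
              for (int a = 0; a < 4; ++a) {
                double fac = pressure * Nv[a];
                // K[(a,i),(b,j)] -= fac * eps_{ijk} w_k
                // explicit Levi-Civita expansion
                double Ke[3][3] = {{0, fac * w[2], -fac * w[1]},
                                   {-fac * w[2], 0, fac * w[0]},
                                   {fac * w[1], -fac * w[0], 0}};
                for (int i = 0; i < 3; ++i)
                  for (int j = 0; j < 3; ++j) {
                    if (Ke[i][j] == 0.0) continue;
                    ti.push_back(3 * cn[a] + i + 1);
                    tj.push_back(3 * cn[b] + j + 1);
                    tx.push_back(-Ke[i][j]);
                  }
              }
            }
          }
        }
    }
  }

  // crack-face node pairs: 0 free, 1 unilateral contact, 2 bonded,
  // 3 bilateral normal tie with free tangential slip (no separation)
  if (contact_mode > 0 && pairs.nrow() > 0) {
    for (int p = 0; p < pairs.nrow(); ++p) {
      int a = pairs(p, 0) - 1, b = pairs(p, 1) - 1;
      double k = pair_k[p];
      double n[3] = {pair_normals(p, 0), pair_normals(p, 1),
                     pair_normals(p, 2)};
      if (contact_mode == 1 || contact_mode == 3) {
        double g = 0.0;
        for (int j = 0; j < 3; ++j) g += (u[3 * b + j] - u[3 * a + j]) * n[j];
        if (g > 0.0 || contact_mode == 3) {
          for (int j = 0; j < 3; ++j) {
            fint[3 * b + j] += k * g * n[j];
            fint[3 * a + j] -= k * g * n[j];
          }
          if (want_tangent) {
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j) {
                double kij = k * n[i] * n[j];
                if (kij == 0.0) continue;
                ti.push_back(3 * b + i + 1); tj.push_back(3 * b + j + 1); tx.push_back(kij);
                ti.push_back(3 * a + i + 1); tj.push_back(3 * a + j + 1); tx.push_back(kij);
                ti.push_back(3 * b + i + 1); tj.push_back(3 * a + j + 1); tx.push_back(-kij);
                ti.push_back(3 * a + i + 1); tj.push_back(3 * b + j + 1); tx.push_back(-kij);
              }
          }
        }
      } else { // bonded: tie all components
        for (int j = 0; j < 3; ++j) {
          double g = u[3 * b + j] - u[3 * a + j];
          fint[3 * b + j] += k * g;
          fint[3 * a + j] -= k * g;
          if (want_tangent) {
            ti.push_back(3 * b + j + 1); tj.push_back(3 * b + j + 1); tx.push_back(k);
            ti.push_back(3 * a + j + 1); tj.push_back(3 * a + j + 1); tx.push_back(k);
            ti.push_back(3 * b + j + 1); tj.push_back(3 * a + j + 1); tx.push_back(-k);
            ti.push_back(3 * a + j + 1); tj.push_back(3 * b + j + 1); tx.push_back(-k);
          }
        }
      }
    }
  }

  List out = List::create(_["fint"] = fint, _["fext"] = fext);
  if (want_tangent) {
    out["ti"] = IntegerVector(ti.begin(), ti.end());
    out["tj"] = IntegerVector(tj.begin(), tj.end());
    out["tx"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}
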