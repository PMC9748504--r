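#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Periodic minimum-image coordinate difference on [0, L)
static inline double min_image(double d, double L) {
  d -= L * std::nearbyint(d / L);
  return d;
}

struct CellGrid {
  int nc;          // cells per direction
  double edge;     // cell edge (= L / nc)
  double L;
  std::vector<int> head;   // first particle index per cell, -1 if empty
  std::vector<int> next;   // linked list

  CellGrid(const NumericMatrix& P, double L_, double cutoff) : L(L_) {
    nc = (int)std::floor(L / cutoff);
    if (nc < 1) nc = 1;
    edge = L / nc;
    head.assign(nc * nc, -1);
    next.assign(P.nrow(), -1);
    for (int i = 0; i < P.nrow(); ++i) {
      int cx = cell_of(P(i, 0));
      int cy = cell_of(P(i, 1));
      int c = cx + nc * cy;
      next[i] = head[c];
      head[c] = i;
    }
  }
  inline int cell_of(double x) const {
    int c = (int)std::floor(x / edge);
    c %= nc; if (c < 0) c += nc;
    return c;
  }
};

// Interaction sums of the discrete system.  For each agent k:
//   J[k]        = sum_{j : |Z_k - Z_j| <= rA} alpha_j   (j = k included)
//   gradPsi[k]  = sum_{l != k} grad psi(Z_k - Z_l)
//   gradPhiA[k] = sum_i grad phi(Z_k - X_i)
// and for each obstacle i:
//   gradPhiO[i] = sum_k grad phi(X_i - Z_k)  ( = -grad phi(Z_k - X_i) ).
// use_cells = false forces the O(M^2 + NM) all-pairs reference path.
// [[Rcpp::export]]
List interaction_sums_cpp(NumericMatrix Z, NumericVector theta,
                          NumericMatrix X, double L, double rA, double rR,
                          double tau, double mu, double Cphi,
                          bool use_cells) {
  const int M = Z.nrow(), N = X.nrow();
  NumericMatrix J(M, 2), gradPsi(M, 2), gradPhiA(M, 2), gradPhiO(N, 2);
  const double psi_c = -12.0 * mu / (M_PI * rR * rR * rR);
  const double phi_c = -3.0 * Cphi / (M_PI * tau * tau);
  const double cutAA = std::max(rA, rR);
  const double cutAO = tau;

  std::vector<double> ax(M), ay(M);
  for (int k = 0; k < M; ++k) {
    ax[k] = std::cos(theta[k]);
    ay[k] = std::sin(theta[k]);
    J(k, 0) = ax[k];           // self-inclusion in the mean flux
    J(k, 1) = ay[k];
  }

  // decide whether the cell grid is usable (needs >= 4 cells per direction
  // so the 3x3 neighbourhood never wraps onto itself)
  bool cells_aa = use_cells && (int)std::floor(L / cutAA) >= 4;
  bool cells_ao = use_cells && (int)std::floor(L / cutAO) >= 4 && N > 0;

  // --- agent-agent ---------------------------------------------------
  if (M > 0) {
    if (cells_aa) {
      CellGrid g(Z, L, cutAA);
      for (int k = 0; k < M; ++k) {
        int cx = g.cell_of(Z(k, 0)), cy = g.cell_of(Z(k, 1));
        for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) {
          int ncx = (cx + dx + g.nc) % g.nc, ncy = (cy + dy + g.nc) % g.nc;
          for (int l = g.head[ncx + g.nc * ncy]; l >= 0; l = g.next[l]) {
            if (l == k) continue;
            double ddx = min_image(Z(k, 0) - Z(l, 0), L);
            double ddy = min_image(Z(k, 1) - Z(l, 1), L);
            double r2 = ddx * ddx + ddy * ddy;
            if (r2 <= rA * rA) { J(k, 0) += ax[l]; J(k, 1) += ay[l]; }
            if (r2 < rR * rR && r2 > 0.0) {
              double r = std::sqrt(r2);
              double s = psi_c * (1.0 - r / rR) / r;
              gradPsi(k, 0) += s * ddx; gradPsi(k, 1) += s * ddy;
            }
          }
        }
      }
    } else {
      for (int k = 0; k < M; ++k) for (int l = 0; l < M; ++l) {
        if (l == k) continue;
        double ddx = min_image(Z(k, 0) - Z(l, 0), L);
        double ddy = min_image(Z(k, 1) - Z(l, 1), L);
        double r2 = ddx * ddx + ddy * ddy;
        if (r2 <= rA * rA) { J(k, 0) += ax[l]; J(k, 1) += ay[l]; }
        if (r2 < rR * rR && r2 > 0.0) {
          double r = std::sqrt(r2);
          double s = psi_c * (1.0 - r / rR) / r;
          gradPsi(k, 0) += s * ddx; gradPsi(k, 1) += s * ddy;
        }
      }
    }
  }

  // --- agent-obstacle ------------------------------------------------
  if (N > 0 && M > 0) {
    if (cells_ao) {
      CellGrid g(X, L, cutAO);
      for (int k = 0; k < M; ++k) {
        int cx = g.cell_of(Z(k, 0)), cy = g.cell_of(Z(k, 1));
        for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) {
          int ncx = (cx + dx + g.nc) % g.nc, ncy = (cy + dy + g.nc) % g.nc;
          for (int i = g.head[ncx + g.nc * ncy]; i >= 0; i = g.next[i]) {
            double ddx = min_image(Z(k, 0) - X(i, 0), L);
            double ddy = min_image(Z(k, 1) - X(i, 1), L);
            double r2 = ddx * ddx + ddy * ddy;
            if (r2 < tau * tau && r2 > 0.0) {
              double r = std::sqrt(r2);
              double s = phi_c * (1.0 - r / tau) / r;
              gradPhiA(k, 0) += s * ddx; gradPhiA(k, 1) += s * ddy;
              gradPhiO(i, 0) -= s * ddx; gradPhiO(i, 1) -= s * ddy;
            }
          }
        }
      }
    } else {
      for (int k = 0; k < M; ++k) for (int i = 0; i < N; ++i) {
        double ddx = min_image(Z(k, 0) - X(i, 0), L);
        double ddy = min_image(Z(k, 1) - X(i, 1), L);
        double r2 = ddx * ddx + ddy * ddy;
        if (r2 < tau * tau && r2 > 0.0) {
          double r = std::sqrt(r2);
          double s = phi_c * (1.0 - r / tau) / r;
          gradPhiA(k, 0) += s * ddx; gradPhiA(k, 1) += s * ddy;
          gradPhiO(i, 0) -= s * ddx; gradPhiO(i, 1) -= s * ddy;
        }
      }
    }
  }

  return List::create(_["J"] = J, _["grad_psi"] = gradPsi,
                      _["grad_phi_agents"] = gradPhiA,
                      _["grad_phi_obstacles"] = gradPhiO);
}

// Bilinear (cloud-in-cell) deposition of unit-mass points onto a periodic
// grid of nh x nh cell centers; returns a density (integral = 1).
// [[Rcpp::export]]
NumericMatrix pic_deposit_cpp(NumericMatrix pts, int nh, double L) {
  NumericMatrix rho(nh, nh);
  const double h = L / nh;
  const int n = pts.nrow();
  for (int p = 0; p < n; ++p) {
    double ux = pts(p, 0) / h - 0.5, uy = pts(p, 1) / h - 0.5;
    int i0 = (int)std::floor(ux), j0 = (int)std::floor(uy);
    double fx = ux - i0, fy = uy - j0;
    int i1 = i0 + 1, j1 = j0 + 1;
    auto wrap = [nh](int i) { i %= nh; return i < 0 ? i + nh : i; };
    int I0 = wrap(i0), I1 = wrap(i1), J0 = wrap(j0), J1 = wrap(j1);
    rho(I0, J0) += (1 - fx) * (1 - fy);
    rho(I1, J0) += fx * (1 - fy);
    rho(I0, J1) += (1 - fx) * fy;
    rho(I1, J1) += fx * fy;
  }
  double scale = 1.0 / (n * h * h);
  for (int i = 0; i < nh; ++i)
    for (int j = 0; j < nh; ++j) rho(i, j) *= scale;
  return rho;
}

// Bilinear periodic interpolation of a field given on nh x nh cell centers
// onto query points (used to project a PIC density back onto the reference
// grid).
// [[Rcpp::export]]
NumericVector bilinear_interp_cpp(NumericMatrix field, NumericMatrix pts,
                                  double L) {
  const int nh = field.nrow();
  const double h = L / nh;
  const int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double ux = pts(p, 0) / h - 0.5, uy = pts(p, 1) / h - 0.5;
    int i0 = (int)std::floor(ux), j0 = (int)std::floor(uy);
    double fx = ux - i0, fy = uy - j0;
    auto wrap = [nh](int i) { i %= nh; return i < 0 ? i + nh : i; };
    int I0 = wrap(i0), I1 = wrap(i0 + 1), J0 = wrap(j0), J1 = wrap(j0 + 1);
    out[p] = field(I0, J0) * (1 - fx) * (1 - fy) +
             field(I1, J0) * fx * (1 - fy) +
             field(I0, J1) * (1 - fx) * fy +
             field(I1, J1) * fx * fy;
  }
  return out;
}
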