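#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 6-connected component labelling of a 3-D logical mask.
// Returns an integer array: 0 outside the mask, component id (1-based)
// inside. Iterative stack-based flood fill; components numbered in
// first-encounter order.
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int ix = (int)(v % nx), iy = (int)((v / nx) % ny), iz = (int)(v / sz);
      R_xlen_t nb[6];
      int nn = 0;
      if (ix > 0) nb[nn++] = v - sx;
      if (ix < nx - 1) nb[nn++] = v + sx;
      if (iy > 0) nb[nn++] = v - sy;
      if (iy < ny - 1) nb[nn++] = v + sy;
      if (iz > 0) nb[nn++] = v - sz;
      if (iz < nz - 1) nb[nn++] = v + sz;
      for (int k = 0; k < nn; ++k) {
        R_xlen_t w = nb[k];
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// y += K * u for the voxel hexahedral mesh: every element shares the unit
// stiffness ke0 (24x24, unit modulus, unit edge) scaled by escale[e].
static void matvec(const int *en, int ne, const double *escale,
                   const double *ke0, const double *u, double *y,
                   R_xlen_t ndof) {
  for (R_xlen_t i = 0; i < ndof; ++i) y[i] = 0.0;
  double ue[24], ye[24];
  int idx[24];
  for (int e = 0; e < ne; ++e) {
    const double s = escale[e];
    for (int m = 0; m < 8; ++m) {
      // enodes stored column-major: en[e + m*ne]
      const int node = en[e + (R_xlen_t)m * ne];
      idx[3 * m] = 3 * node;
      idx[3 * m + 1] = 3 * node + 1;
      idx[3 * m + 2] = 3 * node + 2;
    }
    for (int a = 0; a < 24; ++a) ue[a] = u[idx[a]];
    for (int a = 0; a < 24; ++a) {
      double acc = 0.0;
      const double *col = ke0 + (R_xlen_t)a * 24;  // ke0 symmetric
      for (int b = 0; b < 24; ++b) acc += col[b] * ue[b];
      ye[a] = s * acc;
    }
    for (int a = 0; a < 24; ++a) y[idx[a]] += ye[a];
  }
}

// K * u for reaction-force recovery.
// [[Rcpp::export]]
NumericVector fe_apply(IntegerMatrix enodes, NumericVector escale,
                       NumericMatrix ke0, int nnodes, NumericVector u) {
  const R_xlen_t ndof = 3 * (R_xlen_t)nnodes;
  NumericVector y(ndof);
  matvec(enodes.begin(), enodes.nrow(), escale.begin(), ke0.begin(),
         u.begin(), y.begin(), ndof);
  return y;
}

// Jacobi-preconditioned conjugate gradients for K_ff u_f = -K_fc u_c,
// matrix-free over the element loop. u0 carries the prescribed values at
// constrained dofs and the initial guess at free dofs. Returns the full
// displacement vector, iteration count and relative residual.
// [[Rcpp::export]]
List fe_solve_pcg(IntegerMatrix enodes, NumericVector escale,
                  NumericMatrix ke0, int nnodes, LogicalVector is_free,
                  NumericVector u0, double tol = 1e-8, int maxit = 20000) {
  const int ne = enodes.nrow();
  const R_xlen_t ndof = 3 * (R_xlen_t)nnodes;
  if ((R_xlen_t)is_free.size() != ndof || (R_xlen_t)u0.size() != ndof)
    stop("dof vector length mismatch");
  const int *en = enodes.begin();
  const double *es = escale.begin();
  const double *k0 = ke0.begin();

  std::vector<double> diag(ndof, 0.0);
  for (int e = 0; e < ne; ++e) {
    const double s = es[e];
    for (int m = 0; m < 8; ++m) {
      const int node = en[e + (R_xlen_t)m * ne];
      for (int d = 0; d < 3; ++d) {
        const int a = 3 * m + d;
        diag[3 * (R_xlen_t)node + d] += s * k0[a * 24 + a];
      }
    }
  }

  std::vector<double> uc(ndof), x(ndof), tmp(ndof), r(ndof), z(ndof),
      p(ndof), Ap(ndof);
  for (R_xlen_t i = 0; i < ndof; ++i) {
    uc[i] = is_free[i] ? 0.0 : u0[i];
    x[i] = is_free[i] ? u0[i] : 0.0;
  }
  // b = -(K uc) on free dofs
  matvec(en, ne, es, k0, uc.data(), tmp.data(), ndof);
  std::vector<double> b(ndof, 0.0);
  double bnorm2 = 0.0;
  for (R_xlen_t i = 0; i < ndof; ++i)
    if (is_free[i]) { b[i] = -tmp[i]; bnorm2 += b[i] * b[i]; }
  const double bnorm = std::sqrt(bnorm2);
  if (bnorm == 0.0) {
    NumericVector u(ndof);
    for (R_xlen_t i = 0; i < ndof; ++i) u[i] = is_free[i] ? 0.0 : u0[i];
    return List::create(_["u"] = u, _["iterations"] = 0,
                        _["rel_residual"] = 0.0, _["converged"] = true);
  }
  // r = b - A x  (A x = (K x)|free with x zero at constrained dofs)
  matvec(en, ne, es, k0, x.data(), tmp.data(), ndof);
  double rnorm2 = 0.0;
  for (R_xlen_t i = 0; i < ndof; ++i) {
    r[i] = is_free[i] ? b[i] - tmp[i] : 0.0;
    rnorm2 += r[i] * r[i];
  }
  double rho_prev = 0.0;
  int it = 0;
  for (; it < maxit && std::sqrt(rnorm2) > tol * bnorm; ++it) {
    double rho = 0.0;
    for (R_xlen_t i = 0; i < ndof; ++i) {
      z[i] = (is_free[i] && diag[i] > 0.0) ? r[i] / diag[i] : 0.0;
      rho += r[i] * z[i];
    }
    if (it == 0) {
      for (R_xlen_t i = 0; i < ndof; ++i) p[i] = z[i];
    } else {
      const double beta = rho / rho_prev;
      for (R_xlen_t i = 0; i < ndof; ++i) p[i] = z[i] + beta * p[i];
    }
    matvec(en, ne, es, k0, p.data(), Ap.data(), ndof);
    double pAp = 0.0;
    for (R_xlen_t i = 0; i < ndof; ++i)
      if (is_free[i]) pAp += p[i] * Ap[i];
    if (pAp <= 0.0)
      stop("singular or indefinite system: unconstrained component?");
    const double alpha = rho / pAp;
    rnorm2 = 0.0;
    for (R_xlen_t i = 0; i < ndof; ++i) {
      if (!is_free[i]) continue;
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rnorm2 += r[i] * r[i];
    }
    rho_prev = rho;
    if (it % 200 == 199) Rcpp::checkUserInterrupt();
  }
  NumericVector u(ndof);
  for (R_xlen_t i = 0; i < ndof; ++i) u[i] = is_free[i] ? x[i] : u0[i];
  return List::create(_["u"] = u, _["iterations"] = it,
                      _["rel_residual"] = std::sqrt(rnorm2) / bnorm,
                      _["converged"] = std::sqrt(rnorm2) <= tol * bnorm);
}
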