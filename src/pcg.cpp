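#include <Rcpp.h>
using namespace Rcpp;

// Jacobi-preconditioned conjugate gradient on a 7-point voxel stencil.
//
// The operator is  (A x)_i = diag_i * x_i - sum_f gcond(i,f) * x_{nbr(i,f)},
// with nbr holding 1-based neighbour row indices (0 = no neighbour on that
// face).  The matrix is symmetric positive definite by construction: diag
// contains the full sum of face conductances plus boundary and perfusion
// terms, so it strictly dominates the off-diagonals whenever any boundary
// or perfusion coupling is present.
//
// [[Rcpp::export]]
List pcg_stencil(const IntegerMatrix& nbr, const NumericMatrix& gcond,
                 const NumericVector& diag, const NumericVector& b,
                 const NumericVector& x0, const double tol,
                 const int maxit) {
  const int n = diag.size();
  const int nf = nbr.ncol();
  NumericVector x = clone(x0);
  std::vector<double> r(n), z(n), p(n), ap(n);

  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    std::fill(x.begin(), x.end(), 0.0);
    return List::create(_["x"] = x, _["iterations"] = 0,
                        _["relres"] = 0.0, _["converged"] = true);
  }

  // r = b - A x
  for (int i = 0; i < n; ++i) {
    double s = diag[i] * x[i];
    for (int f = 0; f < nf; ++f) {
      const int j = nbr(i, f);
      if (j > 0) s -= gcond(i, f) * x[j - 1];
    }
    r[i] = b[i] - s;
  }

  double rz = 0.0, rnorm2 = 0.0;
  for (int i = 0; i < n; ++i) {
    z[i] = r[i] / diag[i];
    p[i] = z[i];
    rz += r[i] * z[i];
    rnorm2 += r[i] * r[i];
  }

  int it = 0;
  double relres = std::sqrt(rnorm2) / bnorm;
  while (relres > tol && it < maxit) {
    double pap = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = diag[i] * p[i];
      for (int f = 0; f < nf; ++f) {
        const int j = nbr(i, f);
        if (j > 0) s -= gcond(i, f) * p[j - 1];
      }
      ap[i] = s;
      pap += p[i] * s;
    }
    if (pap <= 0.0) break;  // loss of positive definiteness: bail out
    const double alpha = rz / pap;
    rnorm2 = 0.0;
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * ap[i];
      z[i] = r[i] / diag[i];
      rz_new += r[i] * z[i];
      rnorm2 += r[i] * r[i];
    }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    relres = std::sqrt(rnorm2) / bnorm;
    ++it;
  }

  return List::create(_["x"] = x, _["iterations"] = it,
                      _["relres"] = relres,
                      _["converged"] = (relres <= tol));
}
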