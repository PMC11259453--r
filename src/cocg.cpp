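// Conjugate-orthogonal CG for the complex-symmetric frequency-domain
// diffusion system (K + i*sigma*I) X = B.  K is the real SPD part (CSC
// sparse); the preconditioner application is delegated to an R closure
// (typically a cached supernodal Cholesky solve).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cocg_core(S4 Ks, double sigma, ComplexMatrix Bin, Function msolve,
               double tol, int maxit) {
  IntegerVector dims = Ks.slot("Dim");
  const int n = dims[0];
  IntegerVector pI = Ks.slot("p"), iI = Ks.slot("i");
  NumericVector xI = Ks.slot("x");
  const int *Kp = pI.begin(), *Ki = iI.begin();
  const double *Kx = xI.begin();
  arma::cx_mat B(reinterpret_cast<arma::cx_double*>(Bin.begin()), n,
                 Bin.ncol(), true, true);
  const arma::uword k = B.n_cols;
  arma::cx_mat X(n, k, arma::fill::zeros), R = B, Z, P, Q(n, k);
  arma::vec bnorm2(k);
  for (arma::uword c = 0; c < k; ++c) {
    double s = arma::accu(arma::square(arma::real(B.col(c)))) +
               arma::accu(arma::square(arma::imag(B.col(c))));
    bnorm2[c] = (s == 0.0) ? 1.0 : s;
  }
  const arma::cx_double ish(0.0, sigma);
  auto amul = [&](const arma::cx_mat& V, arma::cx_mat& out) {
    out.zeros();
    for (arma::uword c = 0; c < k; ++c) {
      const arma::cx_double* v = V.colptr(c);
      arma::cx_double* o = out.colptr(c);
      for (int col = 0; col < n; ++col) {
        const arma::cx_double vc = v[col];
        if (vc == arma::cx_double(0.0, 0.0)) continue;
        for (int idx = Kp[col]; idx < Kp[col + 1]; ++idx)
          o[Ki[idx]] += Kx[idx] * vc;
      }
      for (int row = 0; row < n; ++row) o[row] += ish * v[row];
    }
  };
  auto precond = [&](const arma::cx_mat& V) -> arma::cx_mat {
    ComplexMatrix vr(n, k);
    std::memcpy(vr.begin(), V.memptr(), sizeof(Rcomplex) * n * k);
    ComplexMatrix zr = msolve(vr);
    arma::cx_mat out(reinterpret_cast<arma::cx_double*>(zr.begin()), n, k,
                     true, true);
    return out;
  };
  Z = precond(R);
  P = Z;
  arma::cx_rowvec rz = arma::sum(R % Z, 0);   // unconjugated inner products
  int it;
  for (it = 1; it <= maxit; ++it) {
    amul(P, Q);
    arma::cx_rowvec alpha = rz / arma::sum(P % Q, 0);
    X += P.each_row() % alpha;
    R -= Q.each_row() % alpha;
    bool done = true;
    double worst = 0.0;
    for (arma::uword c = 0; c < k; ++c) {
      double s = arma::accu(arma::square(arma::real(R.col(c)))) +
                 arma::accu(arma::square(arma::imag(R.col(c))));
      double rel = s / bnorm2[c];
      worst = std::max(worst, rel);
      if (rel > tol * tol) done = false;
    }
    if (done) {
      ComplexMatrix out(n, k);
      std::memcpy(out.begin(), X.memptr(), sizeof(Rcomplex) * n * k);
      return List::create(_["x"] = out, _["iterations"] = it,
                          _["residual"] = std::sqrt(worst));
    }
    Z = precond(R);
    arma::cx_rowvec rz_new = arma::sum(R % Z, 0);
    arma::cx_rowvec beta = rz_new / rz;
    rz = rz_new;
    P = Z + (P.each_row() % beta);
  }
  stop("FD diffusion solver did not converge within %d iterations", maxit);
}
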